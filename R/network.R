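#' Specification of the PTSD circuit
#'
#' Describes the full circuit: three pairs of mutually inhibiting sensory
#' units (V1/V2 visual, A1/A2 auditory, S1/S2 somatosensory), a bank of
#' hippocampal units under all-to-all lateral inhibition (winner-take-all), a
#' single amygdala unit and a single PFC unit. Sensory and hippocampal units
#' are reciprocally connected with plastic weights drawn uniformly at random;
#' the hippocampus excites the amygdala through a plastic weight, the
#' amygdala feeds back to the hippocampus with a fixed excitatory weight, the
#' sensory cortices project plastically onto the PFC (the connections
#' modulated by the slow-wave gain `psi`), and the PFC inhibits the amygdala
#' with the fixed weight `-phi`.
#'
#' Default values reproduce the qualitative regimes of the model: a naive
#' network is silent under a single cue, a full sensory pattern recruits one
#' hippocampal winner, the trauma input tags the memory through the
#' amygdala, and therapy protocols extinguish the amygdala response. See the
#' package vignette for the rationale behind each default.
#'
#' @param n_hippocampal_units number of hippocampal units (`>= 2`).
#' @param phi magnitude of the inhibitory PFC-to-amygdala weight; stored as a
#'   positive number and applied as the weight `-phi`.
#' @param seed RNG seed for the random initial weights.
#' @param init_weight_range `(low, high)` of the uniform distribution for the
#'   initial sensory-to-hippocampus and hippocampus-to-sensory weights.
#' @param sensory_pfc_range `(low, high)` for the initial sensory-to-PFC
#'   weights.
#' @param hipp_amyg_init initial hippocampus-to-amygdala weight (small).
#' @param amyg_hipp_weight fixed excitatory amygdala-to-hippocampus weight.
#' @param lateral_sensory_inhibition,lateral_hippocampal_inhibition
#'   magnitudes of the fixed inhibitory weights inside a sensory pair and
#'   between hippocampal units (applied with a negative sign).
#' @param tau membrane time constant (steps), shared by all units.
#' @param theta named firing thresholds per region:
#'   `sensory`, `hippocampus`, `amygdala`, `pfc`.
#' @param rho BCM threshold of the fast (hippocampal-side) connections.
#' @param rho_amyg BCM threshold of the hippocampus-to-amygdala connection
#'   (lower than `rho`, so that even a weak amygdala response can tag a
#'   memory).
#' @param rho_cortex BCM threshold of the sensory-to-PFC connections.
#' @param alpha learning rate of the plastic sensory-hippocampus
#'   connections.
#' @param alpha_amyg learning rate of the hippocampus-to-amygdala
#'   connection (fear conditioning; faster than associative learning).
#' @param cortical_rate_factor the cortical learning rate is
#'   `alpha * cortical_rate_factor` (cortex learns 10 times more slowly by
#'   default).
#' @param w_max named upper clip bounds per plastic pathway: `sens_hipp`
#'   (sensory to hippocampus; a low ceiling makes a non-emotional trace
#'   saturate at a level whose cue-evoked recall stays below `rho`, so it
#'   fades), `hipp_sens` (hippocampus back to sensory cortex; high, so a
#'   recalled engram reinstates the sensory pattern strongly), `hipp_amyg`,
#'   and `sens_pfc`.
#' @param w_min named lower clip bounds for the same pathways. Excitatory
#'   plastic weights cannot change sign (all floors `>= 0`); the
#'   `sens_hipp` floor is positive by default, so that the depression
#'   caused by a cue playing onto a silent hippocampus (baseline and
#'   control trials) cannot erase the substrate needed to encode a pattern
#'   later.
#' @param dt Euler step size (time steps).
#' @param activity_floor rate below which a unit counts as silent when
#'   electing a winner.
#' @return a list of class `network_spec`.
#' @export
network_spec <- function(n_hippocampal_units = 4,
                         phi = 1,
                         seed = 1,
                         init_weight_range = c(0.2, 0.33),
                         sensory_pfc_range = c(0.168, 0.168),
                         hipp_amyg_init = 0.05,
                         amyg_hipp_weight = 1.2,
                         lateral_sensory_inhibition = 1,
                         lateral_hippocampal_inhibition = 2.2,
                         tau = 10,
                         theta = c(sensory = 0.05, hippocampus = 0.26,
                                   amygdala = 0.045, pfc = 0.68),
                         rho = 0.15,
                         rho_amyg = 0.003,
                         rho_cortex = 0.005,
                         alpha = 5e-5,
                         alpha_amyg = 2.5e-3,
                         cortical_rate_factor = 0.1,
                         w_max = c(sens_hipp = 0.45, hipp_sens = 0.8,
                                   hipp_amyg = 1.2, sens_pfc = 1.5),
                         w_min = c(sens_hipp = 0.15, hipp_sens = 0,
                                   hipp_amyg = 0, sens_pfc = 0),
                         dt = 1,
                         activity_floor = 0.05) {
  theta <- check_named(theta, c("sensory", "hippocampus", "amygdala", "pfc"))
  w_max <- check_named(w_max, c("sens_hipp", "hipp_sens", "hipp_amyg",
                                "sens_pfc"))
  w_min <- check_named(w_min, c("sens_hipp", "hipp_sens", "hipp_amyg",
                                "sens_pfc"))
  if (n_hippocampal_units < 2) {
    stop("network_spec: need at least 2 hippocampal units")
  }
  if (length(init_weight_range) != 2 ||
      diff(init_weight_range) < 0 || any(init_weight_range < 0)) {
    stop("network_spec: init_weight_range must be a non-empty (low, high)")
  }
  stopifnot(phi >= 0, tau > 0, dt > 0, dt <= tau,
            rho >= 0, rho < 1, rho_amyg >= 0, rho_amyg < 1,
            rho_cortex >= 0, rho_cortex < 1,
            alpha >= 0, alpha_amyg >= 0, cortical_rate_factor > 0,
            all(theta >= 0), all(w_max > 0), all(w_min >= 0),
            all(w_min <= w_max),
            lateral_sensory_inhibition >= 0,
            lateral_hippocampal_inhibition >= 0,
            amyg_hipp_weight >= 0, hipp_amyg_init >= 0,
            activity_floor >= 0)
  structure(as.list(environment()), class = "network_spec")
}

check_named <- function(x, want) {
  if (is.null(names(x)) || !all(want %in% names(x))) {
    stop("expected a named vector with entries: ", paste(want, collapse = ", "))
  }
  x[want]
}

sensory_names <- c("V1", "V2", "A1", "A2", "S1", "S2")

unit_table <- function(spec) {
  nh <- spec$n_hippocampal_units
  data.frame(
    id = c(sensory_names, paste0("H", seq_len(nh)), "AMY", "PFC"),
    region = c(rep("sensory", 6), rep("hippocampus", nh), "amygdala", "pfc"),
    stringsAsFactors = FALSE)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a network from its specification
#'
#' Draws the random initial weights (reproducibly, from `spec$seed`) and
#' assembles the weight matrix together with the per-connection plasticity
#' tables. The caller's RNG state is left untouched.
#'
#' @param spec a [network_spec()].
#' @return a list of class `ptsd_network` holding the unit table, the weight
#'   matrix `W` (indexed `[post, pre]`), membrane potentials `V`, firing
#'   rates `F`, the plastic-connection tables, and a step counter.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  units <- unit_table(spec)
  n <- nrow(units)
  nh <- spec$n_hippocampal_units
  sens <- which(units$region == "sensory")
  hipp <- which(units$region == "hippocampus")
  amy <- which(units$region == "amygdala")
  pfc <- which(units$region == "pfc")

  W <- matrix(0, n, n, dimnames = list(units$id, units$id))

  # fixed inhibition inside each sensory pair
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    W[p[1], p[2]] <- -spec$lateral_sensory_inhibition
    W[p[2], p[1]] <- -spec$lateral_sensory_inhibition
  }
  # hippocampal winner-take-all lateral inhibition
  W[hipp, hipp] <- -spec$lateral_hippocampal_inhibition
  for (h in hipp) W[h, h] <- 0

  # random plastic associative weights
  r <- spec$init_weight_range
  rp <- spec$sensory_pfc_range
  with_seed(spec$seed, {
    W[hipp, sens] <- matrix(runif(nh * 6, r[1], r[2]), nh, 6)
    W[sens, hipp] <- matrix(runif(6 * nh, r[1], r[2]), 6, nh)
    W[pfc, sens] <- runif(6, rp[1], rp[2])
  })
  W[amy, hipp] <- spec$hipp_amyg_init
  W[hipp, amy] <- spec$amyg_hipp_weight
  W[amy, pfc] <- -spec$phi

  # plastic-connection table (row/col indices into W)
  a_fast <- spec$alpha
  a_cort <- spec$alpha * spec$cortical_rate_factor
  plastic <- rbind(
    expand.grid(i = hipp, j = sens, alpha = a_fast, rho = spec$rho,
                wmin = spec$w_min[["sens_hipp"]],
                wmax = spec$w_max[["sens_hipp"]], psi = 0),
    expand.grid(i = sens, j = hipp, alpha = a_fast, rho = spec$rho,
                wmin = spec$w_min[["hipp_sens"]],
                wmax = spec$w_max[["hipp_sens"]], psi = 0),
    expand.grid(i = amy, j = hipp, alpha = spec$alpha_amyg,
                rho = spec$rho_amyg,
                wmin = spec$w_min[["hipp_amyg"]],
                wmax = spec$w_max[["hipp_amyg"]], psi = 0),
    expand.grid(i = pfc, j = sens, alpha = a_cort, rho = spec$rho_cortex,
                wmin = spec$w_min[["sens_pfc"]],
                wmax = spec$w_max[["sens_pfc"]], psi = 1))

  theta_u <- spec$theta[units$region]
  net <- structure(list(
    spec = spec, units = units,
    sensory = sens, hippocampus = hipp, amygdala = amy, pfc = pfc,
    W = W,
    V = setNames(numeric(n), units$id),
    F = setNames(numeric(n), units$id),
    theta = setNames(as.numeric(theta_u), units$id),
    tau = setNames(rep(spec$tau, n), units$id),
    plastic = plastic,
    step = 0L), class = "ptsd_network")
  net
}

#' @export
print.ptsd_network <- function(x, ...) {
  cat("<ptsd_network> ", nrow(x$units), " units (",
      length(x$hippocampus), " hippocampal), step ", x$step, "\n", sep = "")
  cat("  phi = ", -x$W[x$amygdala, x$pfc],
      ", seed = ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' External input vector
#'
#' Assembles the per-unit external drive `I` from named binary (or graded)
#' input channels: the six sensory inputs, the trauma input to the amygdala,
#' the safety / eye-movement input to the PFC, and the recall input targeting
#' one hippocampal unit. An "on" channel delivers its stated amplitude; all
#' other units receive 0.
#'
#' @param net a [build_network()] result (fixes the unit layout).
#' @param V1,V2,A1,A2,S1,S2 sensory input amplitudes (`>= 0`).
#' @param trauma input amplitude to the amygdala.
#' @param safety input amplitude to the PFC (safety signal in PE, eye
#'   movement in EMDR).
#' @param recall index of the hippocampal unit receiving the recall input
#'   (`NA` for none), or the unit id such as `"H3"`.
#' @param recall_amplitude amplitude of the recall input.
#' @return a named numeric vector of per-unit external inputs.
#' @export
input_vector <- function(net, V1 = 0, V2 = 0, A1 = 0, A2 = 0, S1 = 0, S2 = 0,
                         trauma = 0, safety = 0, recall = NA,
                         recall_amplitude = 1) {
  amps <- c(V1 = V1, V2 = V2, A1 = A1, A2 = A2, S1 = S1, S2 = S2,
            trauma = trauma, safety = safety, recall_amplitude)
  if (any(amps < 0)) stop("input amplitudes must be >= 0")
  I <- setNames(numeric(nrow(net$units)), net$units$id)
  I[sensory_names] <- c(V1, V2, A1, A2, S1, S2)
  I[net$amygdala] <- trauma
  I[net$pfc] <- safety
  if (!is.na(recall)) {
    h <- if (is.character(recall)) which(net$units$id == recall)
         else net$hippocampus[recall]
    if (length(h) != 1 || !(h %in% net$hippocampus)) {
      stop("recall must name a hippocampal unit")
    }
    I[h] <- recall_amplitude
  }
  I
}

#' Advance the network
#'
#' Integrates the whole circuit for `n_steps` Euler steps under a constant
#' external input, optionally with plasticity. With `learning = FALSE` the
#' weight matrix is guaranteed untouched (the frozen-learning contract used
#' by test trials). Summary activations over the run (final, mean, peak, and
#' mean over the final fraction of steps) are stored in `net$last_run`.
#'
#' @param net a `ptsd_network`.
#' @param inputs an [input_vector()] (or any named per-unit input vector).
#' @param n_steps number of steps (`>= 1`).
#' @param learning apply the BCM updates?
#' @param psi cortical plasticity gain applied to psi-modulated connections.
#' @param record_stride record every `record_stride`-th step of every unit's
#'   rate in `net$last_run$trace` (0 disables recording).
#' @param late_frac fraction of final steps averaged into `F_late`.
#' @return the updated network (step counter advanced, `last_run` replaced).
#' @export
run_steps <- function(net, inputs, n_steps, learning = TRUE, psi = 1,
                      record_stride = 0L, late_frac = 0.2) {
  stopifnot(inherits(net, "ptsd_network"), n_steps >= 1, psi > 0)
  I <- setNames(numeric(nrow(net$units)), net$units$id)
  I[names(inputs)] <- inputs
  pl <- net$plastic
  alpha_eff <- pl$alpha * ifelse(pl$psi > 0, psi, 1)
  out <- .sim_run(net$V, net$F, net$W, as.numeric(I),
                  net$tau, net$theta, net$spec$dt, as.integer(n_steps),
                  learning, as.integer(pl$i - 1L), as.integer(pl$j - 1L),
                  alpha_eff, pl$rho, pl$wmin, pl$wmax,
                  as.integer(record_stride), late_frac)
  ids <- net$units$id
  net$V <- setNames(out$V, ids)
  net$F <- setNames(out$F, ids)
  net$W <- out$W
  dimnames(net$W) <- list(ids, ids)
  net$step <- net$step + as.integer(n_steps)
  tr <- NULL
  if (record_stride > 0) {
    tr <- out$trace
    colnames(tr) <- ids
  }
  net$last_run <- list(
    F_final = setNames(out$F, ids),
    F_mean = setNames(out$F_mean, ids),
    F_peak = setNames(out$F_peak, ids),
    F_late = setNames(out$F_late, ids),
    trace = tr, trace_step = if (record_stride > 0) out$trace_step else NULL)
  net
}

#' Hippocampal winner
#'
#' Returns the id of the hippocampal unit with the highest summary firing
#' rate, provided it exceeds the activity floor `eps`; otherwise `NA`. Ties
#' are broken in favour of the lowest-numbered unit (with a message).
#'
#' @param net a `ptsd_network` that has been run at least once.
#' @param eps activity floor; defaults to the spec's `activity_floor`.
#' @param mode which summary of the last run to use (see [run_steps()]).
#' @return the winning unit id (e.g. `"H3"`) or `NA_character_`.
#' @export
winner_unit <- function(net, eps = net$spec$activity_floor,
                        mode = c("late_mean", "final", "mean", "peak")) {
  mode <- match.arg(mode)
  Fh <- summary_rates(net, mode)[net$hippocampus]
  m <- max(Fh)
  if (m <= eps) return(NA_character_)
  k <- which(Fh == m)
  if (length(k) > 1) {
    message("winner_unit: tie between ",
            paste(names(Fh)[k], collapse = ", "),
            "; picking the lowest-numbered unit")
    k <- k[1]
  }
  names(Fh)[k]
}

summary_rates <- function(net, mode = "late_mean") {
  if (is.null(net$last_run)) return(net$F)
  switch(mode,
         late_mean = net$last_run$F_late,
         final = net$last_run$F_final,
         mean = net$last_run$F_mean,
         peak = net$last_run$F_peak,
         stop("unknown summary mode: ", mode))
}

#' Save / load a network checkpoint
#'
#' Serializes the full dynamical state (potentials, rates, weights, step
#' counter and spec) as JSON, so that a reloaded network continues with an
#' identical trajectory.
#'
#' @param net a `ptsd_network`.
#' @param path file path for the JSON checkpoint.
#' @return `save_network` returns `path` invisibly; `load_network` returns
#'   the restored `ptsd_network`.
#' @export
save_network <- function(net, path) {
  spec <- unclass(net$spec)
  # named vectors must go out as JSON objects, not bare arrays
  for (f in c("theta", "w_max", "w_min")) spec[[f]] <- as.list(spec[[f]])
  payload <- list(
    spec = spec,
    V = net$V, F = net$F, W = net$W, step = net$step)
  # 17 significant digits guarantee bit-exact double round-trips
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec_args <- p$spec
  for (f in c("theta", "w_max", "w_min")) {
    spec_args[[f]] <- unlist(spec_args[[f]])
  }
  spec <- do.call(network_spec, spec_args)
  net <- build_network(spec)
  ids <- net$units$id
  net$V <- setNames(as.numeric(p$V), ids)
  net$F <- setNames(as.numeric(p$F), ids)
  W <- as.matrix(p$W)
  dimnames(W) <- list(ids, ids)
  net$W <- W
  net$step <- as.integer(p$step)
  net
}
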