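#' Normalize a symptom curve
#'
#' Applies the transform used for the clinical symptom scores: divide by the
#' maximum value, then subtract the final (post-therapy baseline) value. A
#' curve that ends at its own baseline therefore ends at exactly 0, and a
#' constant curve maps to all zeros. An all-zero (or non-positive) curve is
#' returned as zeros.
#'
#' @param values numeric vector of raw symptom values (session-ordered).
#' @return the normalized values.
#' @export
normalize_curve <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  m <- max(values)
  if (m <= 0) return(rep(0, length(values)))
  v <- values / m
  v - v[length(v)]
}

#' Symptom curve container
#'
#' @param session integer session indices (ordered).
#' @param value normalized symptom score per session.
#' @return a data frame of class `symptom_curve`.
#' @export
symptom_curve <- function(session, value) {
  stopifnot(length(session) == length(value), !is.unsorted(session))
  structure(data.frame(session = as.integer(session), value = value),
            class = c("symptom_curve", "data.frame"))
}

#' Extract the model symptom index from a therapy run
#'
#' The clinical proxy is the cue-evoked amygdala activation at the
#' frozen-learning test trials. Test-trial activations are grouped into
#' sessions (averaging `trials_per_session` consecutive test trials, or
#' resampling the whole curve to `n_sessions` points by linear
#' interpolation), then normalized with [normalize_curve()].
#'
#' @param result a `protocol_result` from [therapy_protocol()].
#' @param trials_per_session how many consecutive test trials form one
#'   session (used by `method = "mean"`).
#' @param method `"mean"` (default) or `"interp"`.
#' @param n_sessions number of output sessions for `method = "interp"`.
#' @return a [symptom_curve()].
#' @export
symptom_index <- function(result, trials_per_session = 4,
                          method = c("mean", "interp"), n_sessions = 5) {
  method <- match.arg(method)
  stopifnot(inherits(result, "protocol_result"))
  x <- result$amygdala_F[result$label == "test"]
  if (length(x) == 0) stop("symptom_index: result contains no test trials")
  if (method == "mean") {
    stopifnot(trials_per_session >= 1,
              length(x) %% trials_per_session == 0)
    v <- colMeans(matrix(x, nrow = trials_per_session))
  } else {
    stopifnot(n_sessions >= 2)
    v <- approx(seq_along(x), x, n = n_sessions)$y
  }
  out <- symptom_curve(seq_along(v), normalize_curve(as.numeric(v)))
  attr(out, "raw") <- as.numeric(v)  # pre-normalization session means
  out
}

#' Root-mean-squared error between two symptom curves
#'
#' @param model,target [symptom_curve()]s (or plain numeric vectors) on the
#'   same session grid.
#' @return `sqrt(mean((model - target)^2))`.
#' @export
curve_rmse <- function(model, target) {
  a <- if (is.data.frame(model)) model$value else model
  b <- if (is.data.frame(target)) target$value else target
  if (length(a) != length(b)) {
    stop("curve_rmse: curves have different lengths (",
         length(a), " vs ", length(b), "); resample first")
  }
  sqrt(mean((a - b)^2))
}

#' Grid search over the PFC inhibition (phi) and cortical gain (psi)
#'
#' Evaluates every point of the `(phi, psi)` lattice by running the therapy
#' protocol (averaged over the given network seeds), extracting the model
#' symptom curve, and scoring it against the target with [curve_rmse()].
#' The default lattice is phi from 0.5 to 2.0 in steps of 0.05 and psi from
#' 0.5 to 8.5 in steps of 0.5 (527 points). Evaluations are independent
#' across lattice points (each point re-simulates from the same fixed
#' seeds), so results do not depend on evaluation order.
#'
#' @param target a [symptom_curve()] to fit.
#' @param spec base [network_spec()]; its seed is replaced by `seeds`.
#' @param phi_range,phi_step,psi_range,psi_step lattice geometry.
#' @param seeds one or more network seeds; curves are averaged across them.
#' @param n_sessions therapy sessions per run; must map onto the target grid
#'   through `trials_per_session` or `method = "interp"`.
#' @param trials_per_session,method passed to [symptom_index()].
#' @param ... further arguments passed to [therapy_protocol()] (e.g.
#'   `trial_steps`).
#' @return a list with `grid` (data frame `phi`, `psi`, `rmse` over the full
#'   lattice), `best` (the argmin row; ties broken towards smaller psi, then
#'   smaller phi, with a message), and `best_curve` (the winning model
#'   curve).
#' @export
grid_search <- function(target, spec = network_spec(),
                        phi_range = c(0.5, 2), phi_step = 0.05,
                        psi_range = c(0.5, 8.5), psi_step = 0.5,
                        seeds = spec$seed, n_sessions = 20,
                        trials_per_session = 4,
                        method = c("mean", "interp"), ...) {
  method <- match.arg(method)
  lattice <- grid_lattice(phi_range, phi_step, psi_range, psi_step)

  eval_point <- function(phi, psi) {
    curves <- lapply(seeds, function(s) {
      sp <- spec
      sp$seed <- s
      run <- therapy_protocol(build_network(sp), phi = phi, psi = psi,
                              n_sessions = n_sessions, ...)
      symptom_index(run, trials_per_session = trials_per_session,
                    method = method,
                    n_sessions = nrow(target))$value
    })
    v <- Reduce(`+`, curves) / length(curves)
    # re-normalize only a multi-seed average; a single curve is already
    # normalized and passes through unchanged
    if (length(curves) > 1) v <- normalize_curve(v)
    list(rmse = curve_rmse(v, target), curve = v)
  }

  pts <- Map(eval_point, lattice$phi, lattice$psi)
  grid <- data.frame(phi = lattice$phi, psi = lattice$psi,
                     rmse = vapply(pts, `[[`, numeric(1), "rmse"))
  ord <- order(grid$rmse, grid$psi, grid$phi)
  if (nrow(grid) > 1 && grid$rmse[ord[1]] == grid$rmse[ord[2]]) {
    message("grid_search: tied minima; picking the smallest psi, then phi")
  }
  best <- grid[ord[1], ]
  rownames(best) <- NULL
  list(grid = grid, best = best,
       best_curve = symptom_curve(seq_len(nrow(target)),
                                  pts[[ord[1]]]$curve))
}

#' Enumerate the (phi, psi) search lattice
#'
#' @param phi_range,phi_step,psi_range,psi_step lattice geometry; the
#'   default is the standard fitting lattice: phi from 0.5 to 2.0 in
#'   steps of 0.05 and psi from 0.5 to 8.5 in steps of 0.5, 527 points.
#' @return a data frame with one row per lattice point (`phi`, `psi`).
#' @export
grid_lattice <- function(phi_range = c(0.5, 2), phi_step = 0.05,
                         psi_range = c(0.5, 8.5), psi_step = 0.5) {
  stopifnot(phi_step > 0, psi_step > 0,
            diff(phi_range) >= 0, diff(psi_range) >= 0)
  phis <- seq(phi_range[1], phi_range[2], by = phi_step)
  psis <- seq(psi_range[1], psi_range[2], by = psi_step)
  expand.grid(phi = phis, psi = psis)
}

#' Generate a synthetic symptom curve with known ground truth
#'
#' Runs the therapy protocol at known `(phi_true, psi_true)`, extracts the
#' symptom index, optionally adds i.i.d. Gaussian observation noise, and
#' re-applies the normalization. The result stands in for a patient symptom
#' curve whose generating parameters are known, for parameter-recovery
#' studies; it is synthetic and carries its ground truth in attribute
#' `"truth"`.
#'
#' @param phi_true,psi_true generating parameter values.
#' @param seed network seed (also seeds the observation noise).
#' @param noise_sd standard deviation of the additive noise (`>= 0`).
#' @param spec base [network_spec()]; its seed is replaced by `seed`.
#' @param n_sessions,trials_per_session,method as in [grid_search()].
#' @param n_out output grid size when `method = "interp"`.
#' @param ... passed to [therapy_protocol()].
#' @return a [symptom_curve()] with attribute `"truth"`.
#' @export
generate_synthetic_curve <- function(phi_true, psi_true, seed = 1,
                                     noise_sd = 0, spec = network_spec(),
                                     n_sessions = 20, trials_per_session = 4,
                                     method = c("mean", "interp"),
                                     n_out = 5, ...) {
  method <- match.arg(method)
  stopifnot(noise_sd >= 0)
  spec$seed <- seed
  run <- therapy_protocol(build_network(spec), phi = phi_true,
                          psi = psi_true, n_sessions = n_sessions, ...)
  curve <- symptom_index(run, trials_per_session = trials_per_session,
                         method = method, n_sessions = n_out)
  if (noise_sd > 0) {
    # observation noise acts on the raw session means; the normalization
    # is then applied once, exactly as for a measured symptom score
    raw <- attr(curve, "raw")
    noisy <- with_seed(seed, pmax(0, raw + rnorm(length(raw), 0, noise_sd)))
    curve$value <- normalize_curve(noisy)
  }
  attr(curve, "truth") <- list(phi = phi_true, psi = psi_true, seed = seed,
                               noise_sd = noise_sd)
  curve
}
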