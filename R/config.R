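#' Default run configuration
#'
#' The complete configuration schema with its default values. Sections:
#' `network` (circuit geometry and initial weights), `dynamics` (time
#' constants, thresholds, plasticity), `protocol` (which schedule to run and
#' its trial structure), `fitting` (grid-search lattice and session
#' mapping), plus the top-level `seed` and `out_dir`.
#'
#' @return a nested named list.
#' @export
default_config <- function() {
  sp <- network_spec()
  list(
    seed = 1,
    out_dir = ".",
    network = list(
      n_hippocampal_units = sp$n_hippocampal_units,
      phi = sp$phi,
      init_weight_range = sp$init_weight_range,
      sensory_pfc_range = sp$sensory_pfc_range,
      hipp_amyg_init = sp$hipp_amyg_init,
      amyg_hipp_weight = sp$amyg_hipp_weight,
      lateral_sensory_inhibition = sp$lateral_sensory_inhibition,
      lateral_hippocampal_inhibition = sp$lateral_hippocampal_inhibition,
      activity_floor = sp$activity_floor),
    dynamics = list(
      dt = sp$dt,
      tau = sp$tau,
      theta = as.list(sp$theta),
      rho = sp$rho,
      rho_cortex = sp$rho_cortex,
      alpha = sp$alpha,
      alpha_amyg = sp$alpha_amyg,
      cortical_rate_factor = sp$cortical_rate_factor,
      w_max = as.list(sp$w_max),
      w_min = as.list(sp$w_min)),
    protocol = list(
      name = "trauma",
      n_trials = 35,
      trial_steps = 1e4,
      trauma_trial_steps = 3e4,
      interval_steps = 1e4,
      trauma_amplitude = 1,
      therapy = "PE",
      phi = NULL,
      psi = NULL,
      n_sessions = 20,
      establishment_trials = 10,
      summary = "late_mean"),
    fitting = list(
      phi_range = c(0.5, 2.0),
      phi_step = 0.05,
      psi_range = c(0.5, 8.5),
      psi_step = 0.5,
      trials_per_session = 4,
      method = "mean",
      noise_sd = 0,
      seeds = NULL,
      target_csv = NULL))
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, checks every key against the
#' schema of [default_config()] (unknown keys are an error, with the
#' offending field named), and fills unspecified fields with their
#' defaults.
#'
#' @param path path to the configuration file.
#' @return the fully resolved configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("load_config: ", path, " is not a key-value file")
  defaults <- default_config()
  check_keys(cfg, defaults, "")
  cfg <- merge_config(defaults, cfg)
  validate_config(cfg)
  cfg
}

check_keys <- function(cfg, ref, prefix) {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad) > 0) {
    stop("load_config: unknown field(s): ",
         paste0(prefix, bad, collapse = ", "))
  }
  for (k in names(cfg)) {
    # recurse only into schema sections (named sublists), not value lists
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
        k %in% c("network", "dynamics", "protocol", "fitting", "theta",
                 "w_max", "w_min")) {
      if (!is.list(cfg[[k]])) {
        stop("load_config: field ", prefix, k, " must be a section")
      }
      check_keys(cfg[[k]], ref[[k]], paste0(prefix, k, "."))
    }
  }
}

merge_config <- function(defaults, cfg) {
  out <- defaults
  for (k in names(cfg)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(cfg[[k]])) {
      out[[k]] <- merge_config(defaults[[k]], cfg[[k]])
    } else {
      out[[k]] <- cfg[[k]]
    }
  }
  out
}

validate_config <- function(cfg) {
  p <- cfg$protocol
  if (p$trial_steps <= 0 || p$trauma_trial_steps <= 0) {
    stop("config: protocol trial durations must be > 0 ",
         "(protocol.trial_steps = ", p$trial_steps, ")")
  }
  if (p$interval_steps < 0) stop("config: protocol.interval_steps < 0")
  if (!p$name %in% c("trauma", "control", "resilient", "mild", "pe",
                     "emdr")) {
    stop("config: unknown protocol.name: ", p$name)
  }
  if (cfg$dynamics$dt <= 0 || cfg$dynamics$dt > cfg$dynamics$tau) {
    stop("config: need 0 < dynamics.dt <= dynamics.tau")
  }
  invisible(cfg)
}

#' Build a network spec from a configuration
#'
#' @param cfg a configuration list as returned by [load_config()].
#' @return a [network_spec()].
#' @export
spec_from_config <- function(cfg) {
  n <- cfg$network
  d <- cfg$dynamics
  network_spec(
    n_hippocampal_units = n$n_hippocampal_units,
    phi = n$phi,
    seed = cfg$seed,
    init_weight_range = as.numeric(n$init_weight_range),
    sensory_pfc_range = as.numeric(n$sensory_pfc_range),
    hipp_amyg_init = n$hipp_amyg_init,
    amyg_hipp_weight = n$amyg_hipp_weight,
    lateral_sensory_inhibition = n$lateral_sensory_inhibition,
    lateral_hippocampal_inhibition = n$lateral_hippocampal_inhibition,
    tau = d$tau,
    theta = unlist(d$theta),
    rho = d$rho,
    rho_cortex = d$rho_cortex,
    alpha = d$alpha,
    alpha_amyg = d$alpha_amyg,
    cortical_rate_factor = d$cortical_rate_factor,
    w_max = unlist(d$w_max),
    w_min = unlist(d$w_min),
    dt = d$dt,
    activity_floor = n$activity_floor)
}

#' Run the protocol named in a configuration
#'
#' @param cfg a configuration list.
#' @return a `protocol_result`.
#' @export
run_protocol <- function(cfg) {
  p <- cfg$protocol
  net <- build_network(spec_from_config(cfg))
  common <- list(trial_steps = p$trial_steps,
                 trauma_trial_steps = p$trauma_trial_steps,
                 interval_steps = p$interval_steps,
                 summary = p$summary)
  switch(p$name,
    trauma = do.call(trauma_protocol,
                     c(list(net, variant = "trauma", n_trials = p$n_trials,
                            trauma_amplitude = p$trauma_amplitude), common)),
    control = do.call(trauma_protocol,
                      c(list(net, variant = "control",
                             n_trials = p$n_trials), common)),
    resilient = do.call(resilience_variant,
                        c(list(net, n_trials = p$n_trials), common)),
    mild = do.call(mild_emotion_variant,
                   c(list(net, trauma_amplitude = p$trauma_amplitude,
                          n_trials = p$n_trials), common)),
    pe = do.call(therapy_protocol,
                 c(list(net, therapy = "PE", phi = p$phi, psi = p$psi,
                        n_sessions = p$n_sessions,
                        establishment_trials = p$establishment_trials),
                   common)),
    emdr = do.call(therapy_protocol,
                   c(list(net, therapy = "EMDR", phi = p$phi, psi = p$psi,
                          n_sessions = p$n_sessions,
                          establishment_trials = p$establishment_trials),
                     common)))
}

#' Write protocol results and a run manifest to disk
#'
#' Writes the per-trial result table as `result.csv` (deterministic column
#' order), optionally the same content as `result.json`, and a
#' `manifest.json` holding the full configuration, its hash, the seed and
#' the package version. Identical configuration and seed produce
#' byte-identical result files.
#'
#' @param result a `protocol_result` (or any data frame).
#' @param cfg the configuration that produced it.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (default) or `"json"` for the result table.
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, cfg, dir = cfg$out_dir, format = "csv") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results: cannot create directory: ", dir)
  }
  cols <- c("trial", "label", "session", "winner", "hippocampus_F",
            "amygdala_F", "pfc_F", "w_hipp_amyg", "w_sens_pfc")
  df <- as.data.frame(result)[, intersect(cols, names(result)), drop = FALSE]
  paths <- character()
  if (format == "csv") {
    f <- file.path(dir, "result.csv")
    write.csv(df, f, row.names = FALSE)
    paths <- c(paths, f)
  } else if (format == "json") {
    f <- file.path(dir, "result.json")
    jsonlite::write_json(df, f, digits = NA)
    paths <- c(paths, f)
  } else stop("write_results: unknown format: ", format)
  manifest <- list(seed = cfg$seed,
                   config = cfg,
                   config_hash = config_hash(cfg),
                   package = "traumanet",
                   version = as.character(packageVersion("traumanet")))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(c(paths, mf))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, digits = NA, auto_unbox = TRUE,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Write a step-resolved firing-rate trace as tidy CSV
#'
#' Columns: `step`, `unit_id`, `region`, `F`.
#'
#' @param net a network whose last [run_steps()] recorded a trace.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trace <- function(net, path) {
  tr <- net$last_run$trace
  if (is.null(tr)) stop("write_trace: no recorded trace; rerun run_steps ",
                        "with record_stride > 0")
  steps <- net$last_run$trace_step
  df <- data.frame(
    step = rep(steps, times = ncol(tr)),
    unit_id = rep(colnames(tr), each = nrow(tr)),
    region = rep(net$units$region, each = nrow(tr)),
    F = as.vector(tr))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the weight matrix as JSON keyed by (pre, post)
#'
#' @param net a `ptsd_network`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_weights <- function(net, path) {
  idx <- which(net$W != 0, arr.ind = TRUE)
  ids <- net$units$id
  entries <- lapply(seq_len(nrow(idx)), function(k) {
    list(pre = ids[idx[k, 2]], post = ids[idx[k, 1]],
         weight = net$W[idx[k, 1], idx[k, 2]])
  })
  jsonlite::write_json(entries, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
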