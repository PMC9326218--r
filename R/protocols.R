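# Trial bookkeeping shared by all protocols.
#
# A "trial" is a constant-input phase of the stated duration followed by an
# all-inputs-off interval of interval_steps. Potentials are not reset between
# trials: the interval is much longer than tau, so the network relaxes to
# rest on its own. Plasticity stays enabled during intervals, where it is
# inert because all presynaptic rates are zero.

new_result <- function() {
  data.frame(trial = integer(), label = character(), session = integer(),
             winner = character(), hippocampus_F = numeric(),
             amygdala_F = numeric(), pfc_F = numeric(),
             w_hipp_amyg = numeric(), w_sens_pfc = numeric(),
             stringsAsFactors = FALSE)
}

record_trial <- function(res, net, trial, label, session = NA_integer_,
                         mode = "late_mean") {
  Fm <- summary_rates(net, mode)
  w <- winner_unit(net, mode = mode)
  res[nrow(res) + 1L, ] <- list(
    trial = as.integer(trial), label = label, session = as.integer(session),
    winner = w,
    hippocampus_F = max(Fm[net$hippocampus]),
    amygdala_F = unname(Fm[net$amygdala]),
    pfc_F = unname(Fm[net$pfc]),
    w_hipp_amyg = max(net$W[net$amygdala, net$hippocampus]),
    w_sens_pfc = mean(net$W[net$pfc, net$sensory]))
  res
}

run_trial <- function(net, inputs, steps, interval_steps, learning = TRUE,
                      psi = 1) {
  net <- run_steps(net, inputs, steps, learning = learning, psi = psi)
  keep <- net$last_run
  if (interval_steps > 0) {
    net <- run_steps(net, input_vector(net), interval_steps,
                     learning = learning, psi = psi)
    net$last_run <- keep  # summaries describe the trial, not the interval
  }
  net
}

finish_result <- function(res, net, mode, params) {
  structure(res, class = c("protocol_result", "data.frame"),
            network = net, summary_mode = mode, params = params)
}

#' Final network state of a protocol
#'
#' @param result a `protocol_result`.
#' @return the `ptsd_network` at the end of the protocol.
#' @export
result_network <- function(result) attr(result, "network")

#' Trauma-establishment protocol
#'
#' The 35-trial schedule that turns a neutral cue into a trauma reminder.
#' Trial 1 measures the baseline response to the cue alone (V1 in the trauma
#' variant, V2 in the control). Trial 2 presents the full three-cue sensory
#' pattern, together with the trauma input to the amygdala in the trauma
#' variant, for three times the standard duration. Trials 3 onward present
#' the single cue again, tracking whether it keeps reactivating the
#' hippocampal memory trace and the amygdala. Learning is on throughout.
#'
#' @param net a freshly built `ptsd_network`.
#' @param variant `"trauma"` (pattern V1-A1-S1 plus the trauma input) or
#'   `"control"` (pattern V2-A2-S2, no trauma input).
#' @param n_trials total number of trials.
#' @param trial_steps duration of a standard trial, in steps.
#' @param trauma_trial_steps duration of the pattern/trauma trial (trial 2).
#' @param interval_steps length of the all-off interval between trials.
#' @param trauma_amplitude amplitude of the trauma input during trial 2
#'   (ignored in the control variant).
#' @param summary how per-trial activation is summarized: mean over the
#'   final 20\% of steps (`"late_mean"`, default), last step (`"final"`),
#'   whole-trial mean, or peak.
#' @return a `protocol_result` data frame with one row per trial: the trial
#'   label, the hippocampal winner and its summary rate, the amygdala and
#'   PFC summary rates, and snapshots of the hippocampus-to-amygdala weight
#'   and the mean sensory-to-PFC weight. The final network is attached as
#'   attribute `"network"` (see [result_network()]).
#' @export
trauma_protocol <- function(net, variant = c("trauma", "control"),
                            n_trials = 35,
                            trial_steps = 1e4, trauma_trial_steps = 3e4,
                            interval_steps = 1e4, trauma_amplitude = 1,
                            summary = c("late_mean", "final", "mean",
                                        "peak")) {
  variant <- match.arg(variant)
  mode <- match.arg(summary)
  stopifnot(inherits(net, "ptsd_network"), n_trials >= 2,
            trial_steps > 0, trauma_trial_steps > 0, interval_steps >= 0)

  cue <- if (variant == "trauma") input_vector(net, V1 = 1)
         else input_vector(net, V2 = 1)
  pattern <- if (variant == "trauma") {
    input_vector(net, V1 = 1, A1 = 1, S1 = 1, trauma = trauma_amplitude)
  } else {
    input_vector(net, V2 = 1, A2 = 1, S2 = 1)
  }

  res <- new_result()
  for (k in seq_len(n_trials)) {
    if (k == 2) {
      net <- run_trial(net, pattern, trauma_trial_steps, interval_steps)
      lab <- if (variant == "trauma") "pattern+trauma" else "pattern"
    } else {
      net <- run_trial(net, cue, trial_steps, interval_steps)
      lab <- if (k == 1) "baseline" else "cue"
    }
    res <- record_trial(res, net, k, lab, mode = mode)
  }
  finish_result(res, net, mode,
                list(variant = variant, n_trials = n_trials,
                     trial_steps = trial_steps,
                     trauma_trial_steps = trauma_trial_steps,
                     interval_steps = interval_steps,
                     trauma_amplitude = trauma_amplitude))
}

#' Cue-evoked pattern completion readout
#'
#' Presents a single sensory cue with learning frozen and reports the
#' summary firing rate of every sensory unit, to quantify how much of the
#' full sensory pattern the hippocampal hub reinstates (the model's account
#' of a flashback). The passed network is not modified.
#'
#' @param net a `ptsd_network` (naive or trained).
#' @param cue name of the cued sensory unit (e.g. `"V1"`).
#' @param duration trial length in steps.
#' @param amplitude cue input amplitude.
#' @param summary summary mode, as in [trauma_protocol()].
#' @return named vector of sensory-unit summary rates, with the full-network
#'   rates in attribute `"all_units"`.
#' @export
pattern_completion_readout <- function(net, cue = "V1", duration = 1e4,
                                       amplitude = 1,
                                       summary = c("late_mean", "final",
                                                   "mean", "peak")) {
  mode <- match.arg(summary)
  stopifnot(cue %in% sensory_names)
  args <- setNames(list(net, amplitude), c("net", cue))
  inputs <- do.call(input_vector, args)
  probe <- run_steps(net, inputs, duration, learning = FALSE)
  Fm <- summary_rates(probe, mode)
  structure(Fm[probe$sensory], all_units = Fm)
}

#' Resilient-PFC variant of the trauma protocol
#'
#' Halves the PFC firing threshold (a more excitable ventromedial PFC) and
#' runs the trauma variant of [trauma_protocol()]. With the lower threshold
#' the PFC is recruited by the sensory cortices during cue re-exposure,
#' progressively inhibits the amygdala, and the model extinguishes the fear
#' response on its own while retaining the hippocampal memory.
#'
#' @param net a freshly built `ptsd_network`.
#' @param ... passed on to [trauma_protocol()].
#' @return a `protocol_result`, as for [trauma_protocol()].
#' @export
resilience_variant <- function(net, ...) {
  net <- halve_pfc_threshold(net)
  trauma_protocol(net, variant = "trauma", ...)
}

halve_pfc_threshold <- function(net) {
  net$theta[net$pfc] <- net$theta[net$pfc] / 2
  net$spec$theta[["pfc"]] <- net$spec$theta[["pfc"]] / 2
  net
}

#' Mild-emotion variant of the trauma protocol
#'
#' Runs the trauma schedule on the resilient (halved PFC threshold) model
#' with a weak trauma input during the pattern trial, emulating an
#' emotionally mild rather than traumatic experience. The weak amygdala
#' activation tags the memory for retention: the hippocampal trace persists
#' across the cue-only trials even though the amygdala itself stays quiet,
#' whereas with no emotional engagement at all the trace fades.
#'
#' @param net a freshly built `ptsd_network`.
#' @param trauma_amplitude trauma-input amplitude in `[0, 1)`; the values
#'   reported for this regime are 0.1 and 0.3 (0 reduces to the no-emotion
#'   control).
#' @param halve_threshold halve the PFC threshold first (the resilient
#'   model, which is the regime this variant is defined in)?
#' @param ... passed on to [trauma_protocol()].
#' @return a `protocol_result`.
#' @export
mild_emotion_variant <- function(net, trauma_amplitude = 0.1,
                                 halve_threshold = TRUE, ...) {
  if (trauma_amplitude < 0 || trauma_amplitude >= 1) {
    stop("mild_emotion_variant: trauma_amplitude must lie in [0, 1)")
  }
  if (halve_threshold) net <- halve_pfc_threshold(net)
  trauma_protocol(net, variant = "trauma",
                  trauma_amplitude = trauma_amplitude, ...)
}

#' Therapy protocol (prolonged exposure or EMDR)
#'
#' Establishes PTSD with the first `establishment_trials` trials of the
#' trauma schedule (baseline, trauma, then cue re-exposure), identifies the
#' hippocampal engram unit, then delivers `n_sessions` therapy sessions.
#' Each session is one therapy trial — the recall input drives the engram
#' unit while the safety / eye-movement input drives the PFC, with learning
#' on and the cortical gain `psi` applied to the sensory-to-PFC updates —
#' followed by one frozen-learning test trial with the V1 cue alone, which
#' measures the cue-evoked symptom state without altering any weight.
#'
#' From the start of therapy the PFC-to-amygdala weight is set to `-phi`,
#' reflecting the inhibition efficacy of the PFC region the therapy
#' recruits (ventromedial PFC in PE, dorsolateral PFC in EMDR).
#'
#' @param net a freshly built `ptsd_network`.
#' @param therapy `"PE"` or `"EMDR"`; sets the default `(phi, psi)` to the
#'   fitted values (PE: 1 and 1.5; EMDR: 1.3 and 5).
#' @param phi PFC-to-amygdala inhibition magnitude during therapy.
#' @param psi cortical plasticity gain during therapy trials.
#' @param n_sessions number of therapy sessions.
#' @param establishment_trials trials of the trauma schedule run first.
#' @param trial_steps,trauma_trial_steps,interval_steps as in
#'   [trauma_protocol()]; therapy and test trials last `trial_steps`.
#' @param summary summary mode, as in [trauma_protocol()].
#' @return a `protocol_result` with the establishment rows followed by two
#'   rows per session (labels `"therapy"` and `"test"`, with the session
#'   index in column `session`). The symptom curve of interest is the
#'   `amygdala_F` column of the `"test"` rows.
#' @export
therapy_protocol <- function(net, therapy = c("PE", "EMDR"),
                             phi = NULL, psi = NULL, n_sessions = 20,
                             establishment_trials = 10,
                             trial_steps = 1e4, trauma_trial_steps = 3e4,
                             interval_steps = 1e4,
                             summary = c("late_mean", "final", "mean",
                                         "peak")) {
  therapy <- match.arg(therapy)
  mode <- match.arg(summary)
  if (is.null(phi)) phi <- if (therapy == "PE") 1 else 1.3
  if (is.null(psi)) psi <- if (therapy == "PE") 1.5 else 5
  stopifnot(phi >= 0, psi > 0, n_sessions >= 1, establishment_trials >= 2)

  est <- trauma_protocol(net, variant = "trauma",
                         n_trials = establishment_trials,
                         trial_steps = trial_steps,
                         trauma_trial_steps = trauma_trial_steps,
                         interval_steps = interval_steps, summary = mode)
  net <- result_network(est)
  engram <- est$winner[nrow(est)]
  if (is.na(engram)) {
    stop("therapy_protocol: no identifiable hippocampal engram after ",
         "establishment")
  }

  net$W[net$amygdala, net$pfc] <- -phi
  net$spec$phi <- phi

  recall <- input_vector(net, safety = 1, recall = engram)
  cue <- input_vector(net, V1 = 1)
  res <- as.data.frame(est)
  trial <- establishment_trials
  for (s in seq_len(n_sessions)) {
    net <- run_trial(net, recall, trial_steps, interval_steps,
                     learning = TRUE, psi = psi)
    trial <- trial + 1L
    res <- record_trial(res, net, trial, "therapy", session = s, mode = mode)
    net <- run_trial(net, cue, trial_steps, interval_steps, learning = FALSE)
    trial <- trial + 1L
    res <- record_trial(res, net, trial, "test", session = s, mode = mode)
  }
  finish_result(res, net, mode,
                list(therapy = therapy, phi = phi, psi = psi,
                     n_sessions = n_sessions,
                     establishment_trials = establishment_trials,
                     engram = engram, trial_steps = trial_steps,
                     interval_steps = interval_steps))
}
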