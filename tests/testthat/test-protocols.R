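# Full-length protocol runs are exercised in test-acceptance.R; here the
# schedules run with shortened trials (helper short_trials) to verify the
# trial mechanics, bookkeeping and weight contracts.

test_that("trauma establishment: nullity, persistence, and incubation", {
  net <- default_net(seed = 1)
  res <- do.call(trauma_protocol,
                 c(list(net, "trauma", n_trials = 12), short_trials))
  expect_equal(nrow(res), 12)
  expect_identical(res$label[1:3], c("baseline", "pattern+trauma", "cue"))
  # baseline: a lone cue moves nothing
  expect_identical(res$hippocampus_F[1], 0)
  expect_identical(res$amygdala_F[1], 0)
  # the pattern + trauma trial recruits one engram unit and the amygdala
  expect_false(is.na(res$winner[2]))
  expect_gt(res$amygdala_F[2], 0.5)
  # the cue alone keeps reactivating both (the PTSD state)
  expect_gt(res$hippocampus_F[12], net$spec$activity_floor)
  expect_gt(res$amygdala_F[12], net$spec$activity_floor)
  expect_identical(res$winner[12], res$winner[2])
  # fear incubation: hippocampus-amygdala weight never decreases under
  # repeated cue re-exposure
  expect_false(is.unsorted(res$w_hipp_amyg[3:12]))
  # PFC is never recruited in the default (PTSD-prone) model
  expect_true(all(res$pfc_F == 0))
})

test_that("the control pattern encodes, then loses its trace", {
  res <- do.call(trauma_protocol,
                 c(list(default_net(seed = 2), "control", n_trials = 35),
                   short_trials))
  eps <- 0.05
  expect_gt(res$hippocampus_F[2], eps)   # pattern encodes
  expect_gt(res$hippocampus_F[3], eps)   # cue still retrieves at trial 3
  expect_lt(res$hippocampus_F[35], eps)  # trace lost by trial 35
  expect_true(all(res$amygdala_F == 0))  # never emotionally loaded
})

test_that("cue-evoked pattern completion reinstates the stored pattern", {
  net <- default_net(seed = 1)
  eps <- net$spec$activity_floor
  naive <- pattern_completion_readout(net, "V1", duration = 3000)
  expect_lt(max(naive[c("S1", "A1")]), eps)  # nothing to complete yet

  res <- do.call(trauma_protocol,
                 c(list(net, "trauma", n_trials = 5), short_trials))
  trained <- pattern_completion_readout(result_network(res), "V1",
                                        duration = 3000)
  expect_gt(trained[["S1"]], eps)
  expect_gt(trained[["A1"]], eps)
  expect_lt(max(trained[c("V2", "A2", "S2")]), eps)  # the other pattern
  # readout does not mutate the network it probes
  expect_identical(result_network(res)$W, result_network(res)$W)
})

test_that("mild_emotion_variant validates its amplitude", {
  net <- default_net()
  expect_error(mild_emotion_variant(net, trauma_amplitude = 1), "\\[0, 1\\)")
  expect_error(mild_emotion_variant(net, trauma_amplitude = -0.1), "\\[0, 1\\)")
})

test_that("therapy sessions alternate therapy and frozen test trials", {
  res <- do.call(therapy_protocol,
                 c(list(default_net(seed = 1), "PE", n_sessions = 4,
                        establishment_trials = 5), short_trials))
  expect_equal(sum(res$label == "therapy"), 4)
  expect_equal(sum(res$label == "test"), 4)
  expect_equal(res$session[res$label == "test"], 1:4)
  prm <- attr(res, "params")
  expect_equal(prm$phi, 1)
  expect_equal(prm$psi, 1.5)
  expect_match(prm$engram, "^H[0-9]+$")
  # EMDR defaults differ
  res2 <- do.call(therapy_protocol,
                  c(list(default_net(seed = 1), "EMDR", n_sessions = 1,
                         establishment_trials = 5), short_trials))
  expect_equal(attr(res2, "params")$phi, 1.3)
  expect_equal(attr(res2, "params")$psi, 5)
  # the therapy inhibition magnitude is installed as -phi
  expect_equal(result_network(res2)$W[
    result_network(res2)$amygdala, result_network(res2)$pfc], -1.3)
})

test_that("test trials leave every weight bit-identical", {
  net <- default_net(seed = 3)
  res <- do.call(trauma_protocol,
                 c(list(net, "trauma", n_trials = 5), short_trials))
  trained <- result_network(res)
  before <- trained$W
  probe <- run_steps(trained, input_vector(trained, V1 = 1), 4000,
                     learning = FALSE)
  expect_identical(probe$W, before)
})

test_that("therapy weight trajectories move in the therapeutic direction", {
  res <- do.call(therapy_protocol,
                 c(list(default_net(seed = 1), "PE", n_sessions = 6,
                        establishment_trials = 5), short_trials))
  tst <- res[res$label == "test", ]
  # sensory-to-PFC connections potentiate across sessions (LTP)
  expect_false(is.unsorted(tst$w_sens_pfc))
  expect_gt(tst$w_sens_pfc[6], tst$w_sens_pfc[1])
  # hippocampus-to-amygdala never strengthens during therapy
  expect_true(all(diff(tst$w_hipp_amyg) <= 1e-12))
})

test_that("a network without an identifiable engram refuses therapy", {
  # an all-off establishment cannot happen, but a network whose trauma trial
  # is replaced by a sub-threshold input leaves no winner: simulate by using
  # a control-like spec with no trauma and tiny weights
  sp <- network_spec(seed = 1, init_weight_range = c(0, 0.01),
                     w_min = c(sens_hipp = 0, hipp_sens = 0, hipp_amyg = 0,
                               sens_pfc = 0))
  expect_error(
    do.call(therapy_protocol,
            c(list(build_network(sp), "PE", n_sessions = 1,
                   establishment_trials = 3), short_trials)),
    "engram")
})
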