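test_that("network construction is reproducible and honours the spec", {
  n1 <- default_net(seed = 7)
  n2 <- default_net(seed = 7)
  expect_identical(n1$W, n2$W)
  expect_false(identical(n1$W, default_net(seed = 8)$W))

  # the PFC-to-amygdala weight is -phi
  expect_equal(n1$W[n1$amygdala, n1$pfc], -n1$spec$phi)
  n13 <- build_network(network_spec(seed = 7, phi = 1.3))
  expect_equal(n13$W[n13$amygdala, n13$pfc], -1.3)

  # random associative weights lie within the declared support
  r <- n1$spec$init_weight_range
  assoc <- c(n1$W[n1$hippocampus, n1$sensory],
             n1$W[n1$sensory, n1$hippocampus])
  expect_true(all(assoc >= r[1] & assoc <= r[2]))

  # building does not disturb the caller's RNG stream
  set.seed(123); x <- runif(1)
  set.seed(123); invisible(default_net(seed = 99)); y <- runif(1)
  expect_identical(x, y)

  expect_error(network_spec(n_hippocampal_units = 1), "hippocampal")
  expect_error(network_spec(init_weight_range = c(0.4, 0.1)), "range")
})

test_that("rest is a fixed point and frozen learning never touches weights", {
  net <- default_net()
  quiet <- run_steps(net, input_vector(net), 500)
  expect_true(all(quiet$F == 0))
  expect_true(all(quiet$V == 0))
  expect_identical(quiet$W, net$W)  # plasticity inert without activity

  driven <- run_steps(net, full_pattern(net, 1, trauma = 1), 2000,
                      learning = FALSE)
  expect_identical(driven$W, net$W)
  expect_false(all(driven$F == 0))
})

test_that("a sensory pattern elects one winner; patterns separate", {
  # separation probability of a naive winner-take-all bank is 1 - 1/n by
  # symmetry of the i.i.d. weight draws, so the 95% level is assessed at a
  # pattern-separation capacity of n >= 20 units (dentate-like expansion);
  # the protocol-scale 4-unit default is checked separately below
  seeds <- 1:20
  exclusive <- logical(length(seeds))
  separated <- logical(length(seeds))
  for (k in seq_along(seeds)) {
    net <- default_net(seed = seeds[k], n_hippocampal_units = 24)
    eps <- net$spec$activity_floor
    a <- run_steps(net, full_pattern(net, 1), 3000, learning = FALSE)
    b <- run_steps(net, full_pattern(net, 2), 3000, learning = FALSE)
    Fa <- a$last_run$F_late[a$hippocampus]
    wa <- winner_unit(a)
    wb <- winner_unit(b)
    # winner-take-all exclusivity: at most one unit above the floor
    exclusive[k] <- sum(Fa > eps) <= 1 && sum(
      b$last_run$F_late[b$hippocampus] > eps) <= 1
    # the winner dominates every other hippocampal unit
    if (!is.na(wa)) {
      expect_true(all(Fa[setdiff(names(Fa), wa)] < Fa[wa]))
    }
    separated[k] <- !is.na(wa) && !is.na(wb) && wa != wb
  }
  expect_true(all(exclusive))
  # pattern separation in at least 95% of seeds
  expect_gte(mean(separated), 0.95)

  # the 4-unit default assigns the two patterns to different engram units
  net <- default_net(seed = 1)
  a <- run_steps(net, full_pattern(net, 1), 3000, learning = FALSE)
  b <- run_steps(net, full_pattern(net, 2), 3000, learning = FALSE)
  expect_false(winner_unit(a) == winner_unit(b))
})

test_that("winner_unit applies the floor and breaks ties to the lowest id", {
  net <- default_net()
  net <- run_steps(net, input_vector(net), 10)
  expect_identical(winner_unit(net), NA_character_)  # all silent
  # forge summaries to probe the floor and the tie-break
  net$last_run$F_late[net$hippocampus] <- c(0.04, 0, 0, 0)
  expect_identical(winner_unit(net), NA_character_)  # below the floor
  net$last_run$F_late[net$hippocampus] <- c(0, 0.8, 0, 0)
  expect_identical(winner_unit(net), "H2")
  net$last_run$F_late[net$hippocampus] <- c(0, 0.8, 0.8, 0)
  expect_message(w <- winner_unit(net), "tie")
  expect_identical(w, "H2")
})

test_that("checkpoints round-trip and trajectories continue identically", {
  net <- default_net(seed = 5)
  net <- run_steps(net, full_pattern(net, 1, trauma = 1), 1500)
  path <- tempfile(fileext = ".json")
  save_network(net, path)
  back <- load_network(path)
  expect_equal(back$W, net$W, tolerance = 0)
  expect_equal(back$V, net$V, tolerance = 0)
  expect_equal(back$step, net$step)
  a <- run_steps(net, input_vector(net, V1 = 1), 800)
  b <- run_steps(back, input_vector(back, V1 = 1), 800)
  expect_identical(a$F, b$F)
  expect_identical(a$W, b$W)
})

test_that("inhibitory connections stay inhibitory through a full protocol", {
  net <- default_net(seed = 3)
  res <- trauma_protocol(net, "trauma")
  W <- result_network(res)$W
  h <- net$hippocampus
  off_diag <- W[h, h][row(W[h, h]) != col(W[h, h])]
  expect_true(all(off_diag ==
                    -net$spec$lateral_hippocampal_inhibition))
  expect_equal(W["V1", "V2"], -net$spec$lateral_sensory_inhibition)
  expect_equal(W["V2", "V1"], -net$spec$lateral_sensory_inhibition)
  expect_equal(W[net$amygdala, net$pfc], -net$spec$phi)
})

test_that("input_vector validates amplitudes and recall targets", {
  net <- default_net()
  expect_error(input_vector(net, V1 = -1), "amplitudes")
  expect_error(input_vector(net, recall = "V1"), "hippocampal")
  I <- input_vector(net, V1 = 1, trauma = 0.3, safety = 1, recall = 2)
  expect_equal(unname(I["V1"]), 1)
  expect_equal(unname(I["AMY"]), 0.3)
  expect_equal(unname(I["PFC"]), 1)
  expect_equal(unname(I["H2"]), 1)
  expect_equal(sum(I > 0), 4)
})
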