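test_that("generators are deterministic in the master seed", {
  sc <- nma_scenario(seed = 99)
  expect_identical(simulate_contrast_network(sc),
                   simulate_contrast_network(sc))
  expect_identical(simulate_binary_network(sc), simulate_binary_network(sc))
  expect_identical(simulate_ae_network(sc), simulate_ae_network(sc))
  expect_identical(simulate_km_trial(seed = 99), simulate_km_trial(seed = 99))
  sc2 <- nma_scenario(seed = 100)
  expect_false(identical(simulate_contrast_network(sc)$records,
                         simulate_contrast_network(sc2)$records))
})

test_that("substreams keep components independent of one another", {
  # the contrast stream does not depend on whether other generators ran
  sc <- nma_scenario(seed = 7)
  a <- simulate_contrast_network(sc)
  invisible(simulate_ae_network(sc))
  b <- simulate_contrast_network(sc)
  expect_identical(a, b)
  expect_true(substream_seed(7, "contrast-effects") !=
                substream_seed(7, "ae-arms"))
  expect_lt(substream_seed(7, "anything"), 2^31)
})

test_that("noise-free contrasts reproduce the true effects", {
  sc <- nma_scenario(n_treatments = 5, n_trials = 12, tau = 0,
                     se_range = c(1e-8, 1e-8), seed = 21)
  sim <- simulate_contrast_network(sc)
  d_diff <- sim$truth$d[sim$records$treatment] -
    sim$truth$d[sim$records$baseline_treatment]
  expect_equal(unname(sim$records$log_effect), unname(d_diff),
               tolerance = 1e-6)
})

test_that("contrast noise has the declared second moment", {
  sc <- nma_scenario(n_treatments = 5, n_trials = 10000, tau = 0.2,
                     se_range = c(0.2, 0.2), seed = 33)
  sim <- simulate_contrast_network(sc)
  resid <- sim$records$log_effect -
    (sim$truth$d[sim$records$treatment] -
       sim$truth$d[sim$records$baseline_treatment])
  expect_equal(sd(resid), sqrt(0.2^2 + 0.2^2), tolerance = 0.02)
})

test_that("binary arms have the declared response model", {
  sc <- nma_scenario(n_treatments = 4, n_trials = 5000, tau = 0,
                     arm_n_range = c(400, 400),
                     baseline_logit_range = c(-1, -1), seed = 44)
  sim <- simulate_binary_network(sc)
  # each trial's baseline arm is its lower-indexed treatment by design
  min_trt <- tapply(sim$records$treatment, sim$records$trial_id, min)
  base <- sim$records[sim$records$treatment ==
                        min_trt[sim$records$trial_id], ]
  p_hat <- sum(base$events) / sum(base$n)
  expect_equal(p_hat, plogis(-1), tolerance = 0.02)
})

test_that("rare-event mode keeps every arm probability at or below 2%", {
  sc <- nma_scenario(n_treatments = 5, n_trials = 500,
                     ae_rate_range = c(0.001, 0.01),
                     follow_up_range = c(6, 36), seed = 55)
  sim <- simulate_ae_network(sc, rare = TRUE)
  expect_true(all(sim$truth$p <= 0.02 + 1e-12))
  # and the realized event proportions stay rare
  expect_lt(max(sim$records$events / sim$records$n), 0.06)
})

test_that("impossible designs error before simulation", {
  expect_error(nma_scenario(n_treatments = 10, n_trials = 5),
               "impossible design")
})

test_that("null survival trials are exchangeable across arms", {
  est <- vapply(1:20, function(s) {
    tr <- simulate_km_trial(n_per_arm = 150, true_hr = 1, base_rate = 0.08,
                            censor_time = 24, seed = 200 + s)
    tr$true_loghr
  }, numeric(1L))
  expect_lt(abs(mean(est)), 0.06)
})

test_that("generated truth records are sufficient to score recovery", {
  sim <- simulate_contrast_network(nma_scenario(seed = 1))
  expect_named(sim$truth, c("treatments", "d", "tau", "delta", "topology"))
  simb <- simulate_binary_network(nma_scenario(seed = 1))
  expect_true(all(c("d", "mu", "delta") %in% names(simb$truth)))
  sime <- simulate_ae_network(nma_scenario(seed = 1))
  expect_true(all(c("d", "base_rate", "p") %in% names(sime$truth)))
})
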