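test_that("a flat curve reconstructs to all-censored records", {
  cv <- km_curve(times = c(0, 12), surv = c(1, 1),
                 risk_times = c(0, 12), n_risk = c(100, 100))
  ipd <- reconstruct_ipd(cv)
  expect_equal(nrow(ipd), 100L)
  expect_true(all(ipd$status == 0L))
  expect_true(all(ipd$time == 12))
})

test_that("a two-patient drop reconstructs to exactly one event", {
  cv <- km_curve(times = c(0, 1), surv = c(1, 0.5),
                 risk_times = c(0, 1), n_risk = c(2, 1))
  ipd <- reconstruct_ipd(cv)
  expect_equal(nrow(ipd), 2L)
  expect_equal(sum(ipd$status), 1L)
  expect_equal(ipd$time[ipd$status == 1L], 1)
})

test_that("invalid digitizations are rejected before iteration", {
  expect_error(km_curve(times = c(0, 1), surv = c(0.5, 1),
                        risk_times = c(0, 1), n_risk = c(2, 1)),
               "increases")
  expect_error(km_curve(times = c(0, 1), surv = c(1, 0.5),
                        risk_times = c(0, 1), n_risk = c(2, 5)),
               "increase")
  expect_error(km_curve(times = 0, surv = 1, risk_times = 0, n_risk = 2))
})

test_that("reconstruction recovers event counts from a digitized exponential arm", {
  tr <- simulate_km_trial(n_per_arm = 200, true_hr = 0.7, base_rate = 0.1,
                          censor_time = 24, click_points = 100,
                          risk_interval = 6, seed = 11)
  for (arm in c("a", "b")) {
    truth <- sum(tr[[paste0("ipd_", arm)]]$status)
    recon <- sum(reconstruct_ipd(tr[[paste0("curve_", arm)]])$status)
    expect_lt(abs(recon - truth) / truth, 0.05)
  }
})

test_that("KM of reconstructed IPD reproduces the curve at click points", {
  tr <- simulate_km_trial(n_per_arm = 200, true_hr = 0.7, base_rate = 0.1,
                          censor_time = 24, click_points = 100,
                          risk_interval = 6, seed = 11)
  for (arm in c("a", "b")) {
    cv <- tr[[paste0("curve_", arm)]]
    km <- km_from_ipd(reconstruct_ipd(cv))
    expect_lte(max(abs(km_surv_at(km, cv$times) - cv$surv)), 0.02)
  }
})

test_that("the constrained variant matches a reported total event count", {
  tr <- simulate_km_trial(n_per_arm = 150, true_hr = 1, base_rate = 0.08,
                          censor_time = 24, click_points = 80,
                          risk_interval = 6, seed = 3)
  true_events <- sum(tr$ipd_a$status)
  cv <- tr$curve_a
  cv$total_events <- true_events
  ipd <- reconstruct_ipd(cv)
  expect_equal(sum(ipd$status), true_events)
})

test_that("product-limit estimator handles single and all-censored inputs", {
  single <- data.frame(time = 5, status = 1L)
  km <- km_from_ipd(single)
  expect_equal(km_surv_at(km, c(4.9, 5)), c(1, 0))
  cens <- data.frame(time = c(2, 4, 6), status = 0L)
  kmc <- km_from_ipd(cens)
  expect_true(all(kmc$surv == 1))
  # ties: events processed before censorings
  tied <- data.frame(time = c(3, 3), status = c(1L, 0L))
  kmt <- km_from_ipd(tied)
  expect_equal(km_surv_at(kmt, 3), 0.5)
})

test_that("digitized curves load from the CSV schema", {
  dir <- withr::local_tempdir()
  tr <- simulate_km_trial(n_per_arm = 60, seed = 4, click_points = 30)
  pts <- rbind(
    data.frame(trial_id = "T1", arm = "a", time = tr$curve_a$times,
               survival = tr$curve_a$surv),
    data.frame(trial_id = "T1", arm = "b", time = tr$curve_b$times,
               survival = tr$curve_b$surv))
  rsk <- rbind(
    data.frame(trial_id = "T1", arm = "a", time = tr$curve_a$risk_times,
               n_at_risk = tr$curve_a$n_risk),
    data.frame(trial_id = "T1", arm = "b", time = tr$curve_b$risk_times,
               n_at_risk = tr$curve_b$n_risk))
  write.csv(pts, file.path(dir, "km_points.csv"), row.names = FALSE)
  write.csv(rsk, file.path(dir, "km_risk.csv"), row.names = FALSE)
  curves <- read_km_curves(file.path(dir, "km_points.csv"),
                           file.path(dir, "km_risk.csv"))
  expect_named(curves, c("T1:a", "T1:b"))
  expect_equal(curves[["T1:a"]]$surv, tr$curve_a$surv)
  expect_equal(curves[["T1:b"]]$n_risk, tr$curve_b$n_risk)
})

test_that("digitization-noise survival blips are clamped flat", {
  cv <- km_curve(times = c(0, 1, 2), surv = c(1, 0.8, 0.8 + 5e-7),
                 risk_times = c(0, 2), n_risk = c(10, 8))
  expect_equal(cv$surv[3L], cv$surv[2L])
})
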