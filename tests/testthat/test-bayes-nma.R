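test_that("a single-trial fixed-effect posterior tracks its likelihood", {
  rec <- data.frame(trial_id = "T1", outcome = "os", treatment = "B",
                    baseline_treatment = "A", log_effect = 0.2, se = 0.1)
  net <- build_network(rec, "os", reference = "A")
  post <- fit_contrast_nma(net, model = "fixed", mcmc = quick_mcmc())
  s <- post$summaries[post$summaries$parameter == "d[B]", ]
  expect_equal(s$mean, 0.2, tolerance = 0.01)
  flat <- as.vector(post$samples[, , "d[B]"])
  expect_equal(sd(flat), 0.1, tolerance = 0.01)
})

test_that("fixed-effect pooling reproduces the inverse-variance closed form", {
  net <- build_network(two_trial_records(), "os", reference = "A")
  post <- fit_contrast_nma(net, model = "fixed", mcmc = quick_mcmc())
  flat <- as.vector(post$samples[, , "d[B]"])
  mc_se <- sd(flat) / sqrt(post$diagnostics$ess_bulk[1L])
  expect_lt(abs(mean(flat) - 0.24), 3 * mc_se + 1e-9)
  expect_equal(sd(flat), sqrt(1 / 125), tolerance = 0.01)
  # relative effects vs reference exponentiate the pooled estimate
  re <- relative_effects(post, comparator = "A")
  hr <- re[re$treatment == "B", ]
  expect_equal(hr$median, exp(0.24), tolerance = 0.02)
})

test_that("fixed-effect posteriors match GLS on a tree-shaped network", {
  sim <- simulate_contrast_network(nma_scenario(n_treatments = 5,
                                                n_trials = 4, tau = 0.15,
                                                seed = 31))
  net <- build_network(sim$records, "os", reference = "t01")
  post <- fit_contrast_nma(net, model = "fixed", mcmc = quick_mcmc())
  ids <- paste0("t0", 2:5)
  X <- matrix(0, 4, 4, dimnames = list(NULL, ids))
  for (i in seq_len(4)) {
    t <- sim$records$treatment[i]; b <- sim$records$baseline_treatment[i]
    if (t %in% ids) X[i, t] <- 1
    if (b %in% ids) X[i, b] <- -1
  }
  w <- 1 / sim$records$se^2
  gls <- drop(solve(t(X * w) %*% X, t(X) %*% (w * sim$records$log_effect)))
  for (t in ids) {
    flat <- as.vector(post$samples[, , paste0("d[", t, "]")])
    dg <- post$diagnostics
    mc_se <- sd(flat) / sqrt(dg$ess_bulk[dg$parameter == paste0("d[", t, "]")])
    expect_lt(abs(mean(flat) - gls[t]), 3 * mc_se + 1e-6)
  }
})

test_that("a null triangle centres every effect at zero", {
  sim <- simulate_contrast_network(nma_scenario(
    n_treatments = 3, n_trials = 3, true_d = c(0, 0, 0), tau = 0,
    se_range = c(0.05, 0.05), seed = 12))
  sim$records$log_effect <- 0           # exact null data
  net <- build_network(sim$records, "os", reference = "t01")
  post <- fit_contrast_nma(net, model = "random", mcmc = quick_mcmc())
  meds <- post$summaries$median[grepl("^d", post$summaries$parameter)]
  expect_true(all(abs(meds) < 0.05))
})

test_that("binomial-logit NMA recovers symmetric and lopsided single trials", {
  rec <- data.frame(trial_id = "T1", outcome = "resp",
                    treatment = c("A", "B"), n = 20, events = c(10, 10))
  net <- build_network(rec, "resp", reference = "A")
  post <- fit_binary_nma(net, model = "fixed", mcmc = quick_mcmc())
  expect_lt(abs(post$summaries$median[post$summaries$parameter == "d[B]"]),
            0.1)
  rec2 <- data.frame(trial_id = "T1", outcome = "resp",
                     treatment = c("A", "B"), n = 20, events = c(5, 15))
  net2 <- build_network(rec2, "resp", reference = "A")
  post2 <- fit_binary_nma(net2, model = "fixed",
                          mcmc = quick_mcmc(sample = 8000))
  expect_lt(abs(post2$summaries$median[post2$summaries$parameter == "d[B]"] -
                  log(9)), 0.15)
})

test_that("binomial random-effects NMA covers simulated log odds ratios", {
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    sim <- simulate_binary_network(nma_scenario(
      n_treatments = 4, n_trials = 10, tau = 0.15,
      arm_n_range = c(200, 500), seed = 40 + s))
    net <- build_network(sim$records, "os", reference = "t01")
    post <- fit_binary_nma(net, model = "random",
                           mcmc = quick_mcmc(burn = 3000, sample = 4000))
    for (t in paste0("t0", 2:4)) {
      s_row <- post$summaries[post$summaries$parameter ==
                                paste0("d[", t, "]"), ]
      total <- total + 1L
      truth <- sim$truth$d[t]
      hits <- hits + as.integer(truth >= s_row$lo95 & truth <= s_row$hi95)
    }
  }
  expect_gte(hits / total, 0.7)    # 95% nominal over 9 intervals
})

test_that("deviance statistics behave like residual deviance and DIC", {
  net <- build_network(two_trial_records(), "os", reference = "A")
  post_f <- fit_contrast_nma(net, model = "fixed", mcmc = quick_mcmc())
  fit <- model_fit(post_f)
  expect_equal(fit$n_datapoints, 2L)
  expect_gt(fit$pd, 0)
  expect_equal(fit$dic, fit$resdev + fit$pd, tolerance = 1e-9)
  # well-specified fixed-effect data: ResDev per datapoint near 1, and
  # the fixed model not materially beaten by random effects
  sim <- simulate_contrast_network(nma_scenario(
    n_treatments = 4, n_trials = 10, tau = 0, seed = 77))
  netf <- build_network(sim$records, "os", reference = "t01")
  pf <- fit_contrast_nma(netf, model = "fixed", mcmc = quick_mcmc())
  pr <- fit_contrast_nma(netf, model = "random", mcmc = quick_mcmc())
  expect_gt(pf$fit$resdev / pf$fit$n_datapoints, 0.3)
  expect_lt(pf$fit$resdev / pf$fit$n_datapoints, 2.0)
  expect_lte(pf$fit$dic, pr$fit$dic + 3)
})

test_that("multi-arm contrast trials fit with correlated random effects", {
  rec <- rbind(triangle_records(),
               data.frame(trial_id = "T4", outcome = "os",
                          treatment = c("B", "C"),
                          baseline_treatment = "A",
                          log_effect = c(0.15, 0.25), se = 0.12))
  net <- build_network(rec, "os", reference = "A")
  expect_equal(nrow(net$edges), 5L)
  post <- suppressMessages(
    fit_contrast_nma(net, model = "random", mcmc = quick_mcmc()))
  expect_true(all(c("d[B]", "d[C]", "tau") %in%
                    post$summaries$parameter))
  expect_true(post$converged)
})

test_that("prior-only runs reproduce the heterogeneity prior", {
  design <- list(X = matrix(0, 0, 1, dimnames = list(NULL, "d[B]")),
                 y = numeric(0), se = numeric(0), blocks = list(),
                 treatments = c("A", "B"))
  raw <- nmakit:::.normal_gibbs(design, "random", nma_priors(),
                                nma_mcmc(burn = 2000, sample = 20000,
                                         chains = 2, seed = 5))
  log_tau2 <- 2 * log(as.vector(raw$samples[, , "tau"]))
  expect_equal(mean(log_tau2), -3.95, tolerance = 0.12)
  expect_equal(sd(log_tau2), 1.79, tolerance = 0.1)
  # and the vague effect prior passes through
  expect_equal(sd(as.vector(raw$samples[, , "d[B]"])), 100, tolerance = 3)
})

test_that("results are bit-reproducible for a fixed seed and config", {
  net <- build_network(triangle_records(), "os", reference = "A")
  p1 <- fit_contrast_nma(net, model = "random",
                         mcmc = quick_mcmc(burn = 500, sample = 1000))
  p2 <- fit_contrast_nma(net, model = "random",
                         mcmc = quick_mcmc(burn = 500, sample = 1000))
  expect_identical(p1$samples, p2$samples)
  p3 <- fit_contrast_nma(net, model = "random",
                         mcmc = quick_mcmc(burn = 500, sample = 1000,
                                           seed = 43))
  expect_false(identical(p1$samples, p3$samples))
})

test_that("rank-normalized diagnostics separate healthy and broken chains", {
  set.seed(1)
  iid <- matrix(rnorm(4000), 1000, 4)
  d_iid <- mcmc_diagnostics(iid)
  expect_gt(d_iid$rhat, 0.99)
  expect_lt(d_iid$rhat, 1.01)
  expect_lt(abs(d_iid$ess_bulk - 4000) / 4000, 0.2)
  expect_true(d_iid$pass)
  # two chains offset by +5: clear non-convergence
  off <- cbind(matrix(rnorm(2000), 1000, 2),
               matrix(rnorm(2000, 5), 1000, 2))
  expect_gt(mcmc_diagnostics(off)$rhat, 1.05)
  expect_error(mcmc_diagnostics(matrix(rnorm(100), 100, 1)), "2 chains")
})
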