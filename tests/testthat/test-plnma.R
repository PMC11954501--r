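test_that("the complementary log-log link is the stated increasing map", {
  eta <- seq(-6, 3, by = 0.1)
  p <- 1 - exp(-exp(eta))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  # inverse identity
  expect_equal(log(-log(1 - p)), eta, tolerance = 1e-9)
})

test_that("equal event proportions with equal follow-up give a null effect", {
  rec <- data.frame(trial_id = "T1", outcome = "ae",
                    treatment = c("A", "B"), n = 200, events = c(10, 10),
                    follow_up = 12)
  net <- build_network(rec, "ae", reference = "A")
  fit <- fit_pl_cloglog(net, penalty = "none")
  expect_true(fit$converged)
  expect_equal(unname(fit$d_hat["B"]), 0, tolerance = 1e-6)
})

test_that("without penalty the fit matches an independent cloglog GLM", {
  sim <- simulate_ae_network(nma_scenario(
    n_treatments = 4, n_trials = 6, tau = 0, seed = 5,
    ae_rate_range = c(0.002, 0.004), arm_n_range = c(300, 500)),
    rare = FALSE)
  net <- build_network(sim$records, "os", reference = "t01")
  fit <- fit_pl_cloglog(net, penalty = "none")
  rec <- sim$records
  rec$trt <- factor(rec$treatment, levels = paste0("t0", 1:4))
  g <- glm(cbind(events, n - events) ~ trial_id + trt, data = rec,
           family = binomial("cloglog"), offset = log(rec$follow_up))
  oracle <- coef(g)[grep("^trt", names(coef(g)))]
  expect_equal(unname(fit$d_hat), unname(oracle), tolerance = 1e-4)
  se_oracle <- sqrt(diag(vcov(g)))[grep("^trt", names(coef(g)))]
  expect_equal(unname(sqrt(diag(fit$cov))), unname(se_oracle),
               tolerance = 1e-3)
})

test_that("the discrete hazard ratio recovers a known rate ratio", {
  # monthly rates 0.1 vs 0.2 over 12 months; d = ln(rate ratio) = ln 2
  set.seed(8)
  n <- 10000
  p <- 1 - exp(-12 * c(0.1, 0.2))
  rec <- data.frame(trial_id = "T1", outcome = "ae",
                    treatment = c("A", "B"), n = n,
                    events = rbinom(2, n, p), follow_up = 12)
  net <- build_network(rec, "ae", reference = "A")
  fit <- fit_pl_cloglog(net, penalty = "none")
  expect_equal(exp(unname(fit$d_hat["B"])), 2, tolerance = 0.05)
})

test_that("doubling follow-up while halving rates leaves effects unchanged", {
  sim <- simulate_ae_network(nma_scenario(
    n_treatments = 4, n_trials = 6, seed = 13,
    ae_rate_range = c(0.001, 0.003)), rare = FALSE)
  net1 <- build_network(sim$records, "os", reference = "t01")
  fit1 <- fit_pl_cloglog(net1, penalty = "none")
  rec2 <- sim$records
  rec2$follow_up <- rec2$follow_up * 2    # same counts, doubled exposure
  net2 <- build_network(rec2, "os", reference = "t01")
  fit2 <- fit_pl_cloglog(net2, penalty = "none")
  expect_equal(fit1$d_hat, fit2$d_hat, tolerance = 1e-6)
  expect_equal(fit1$mu_hat, fit2$mu_hat + log(2), tolerance = 1e-6)
})

test_that("Firth keeps zero-event arms finite where the MLE diverges", {
  rec <- data.frame(trial_id = rep(c("T1", "T2", "T3"), each = 2),
                    outcome = "ae", treatment = rep(c("A", "B"), 3),
                    n = 300, events = c(3, 0, 2, 0, 4, 0), follow_up = 12)
  net <- build_network(rec, "ae", reference = "A")
  firth <- fit_pl_cloglog(net, penalty = "firth")
  expect_true(firth$converged)
  expect_true(abs(firth$d_hat["B"]) < 10)
  mle <- suppressMessages(fit_pl_cloglog(net, penalty = "none"))
  expect_true(!mle$converged || abs(mle$d_hat["B"]) > abs(firth$d_hat["B"]))
})

test_that("missing follow-up is imputed from the trial median, with a message", {
  rec <- data.frame(trial_id = rep(c("T1", "T2"), each = 2), outcome = "ae",
                    treatment = rep(c("A", "B"), 2), n = 200,
                    events = c(4, 6, 3, 5),
                    follow_up = c(12, 12, NA, NA))
  net <- build_network(rec, "ae", reference = "A")
  expect_message(fit <- fit_pl_cloglog(net), "imputing")
  expect_true(fit$converged)
})

test_that("pairwise discrete hazards are reciprocal and self-identical", {
  sim <- simulate_ae_network(nma_scenario(
    n_treatments = 4, n_trials = 6, seed = 5,
    ae_rate_range = c(0.002, 0.004), arm_n_range = c(300, 500)),
    rare = FALSE)
  net <- build_network(sim$records, "os", reference = "t01")
  fit <- fit_pl_cloglog(net)
  tab <- relative_discrete_hazards(fit)
  self <- tab[tab$treatment == tab$comparator, ]
  expect_true(all(self$dhr == 1))
  ab <- tab[tab$treatment == "t02" & tab$comparator == "t03", ]
  ba <- tab[tab$treatment == "t03" & tab$comparator == "t02", ]
  expect_equal(ab$dhr * ba$dhr, 1, tolerance = 1e-9)
  expect_equal(ab$lo95 * ba$hi95, 1, tolerance = 1e-9)
})
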