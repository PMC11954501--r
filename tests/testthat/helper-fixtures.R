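# small fixtures shared across tests; all built in code

triangle_records <- function(y = c(0.1, 0.2, 0.3), se = rep(0.1, 3)) {
  data.frame(trial_id = c("T1", "T2", "T3"), outcome = "os",
             treatment = c("B", "C", "C"),
             baseline_treatment = c("A", "A", "B"),
             log_effect = y, se = se,
             stringsAsFactors = FALSE)
}

two_trial_records <- function() {
  data.frame(trial_id = c("T1", "T2"), outcome = "os",
             treatment = "B", baseline_treatment = "A",
             log_effect = c(0.2, 0.4), se = c(0.1, 0.2),
             stringsAsFactors = FALSE)
}

quick_mcmc <- function(burn = 1000, sample = 4000, chains = 4, seed = 42) {
  nma_mcmc(burn = burn, sample = sample, chains = chains, seed = seed)
}

# exponential two-arm IPD, administratively censored
sim_exp_arms <- function(n, rate_a, rate_b, censor, seed) {
  set.seed(seed)
  mk <- function(rate) {
    te <- rexp(n, rate)
    data.frame(time = pmin(te, censor), status = as.integer(te <= censor))
  }
  list(a = mk(rate_a), b = mk(rate_b))
}
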