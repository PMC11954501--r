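#' Simulation scenario for synthetic evidence networks
#'
#' Defines the conditions under which synthetic multi-trial evidence is
#' generated: network size, true basic parameters, between-trial
#' heterogeneity, contrast precision, arm sizes, baseline response rates,
#' adverse-event rates and follow-up spread. One master seed controls every
#' draw through deterministic per-component substreams, so adding a new
#' generator never perturbs existing output.
#'
#' @param n_treatments number of treatments (>= 2); treatment 1 is the
#'   reference.
#' @param n_trials number of two-arm trials (>= n_treatments - 1 so a
#'   connected design exists).
#' @param true_d true basic parameters versus the reference (length
#'   `n_treatments`, first entry 0). Default: drawn once from
#'   Normal(0, 0.3^2) under the scenario seed.
#' @param tau between-trial SD of true relative effects.
#' @param se_range range of contrast standard errors.
#' @param arm_n_range range of per-arm sample sizes.
#' @param baseline_logit_range range of trial baseline log-odds.
#' @param ae_rate_range range of baseline adverse-event rates
#'   (events/person-month).
#' @param follow_up_range range of trial follow-up (months).
#' @param outcome outcome label stamped on generated records.
#' @param seed master seed.
#' @return list of class `nma_scenario`.
#' @export
nma_scenario <- function(n_treatments = 5, n_trials = 12, true_d = NULL,
                         tau = 0.2, se_range = c(0.1, 0.3),
                         arm_n_range = c(100, 600),
                         baseline_logit_range = c(-1.5, -0.5),
                         ae_rate_range = c(5e-4, 2e-3),
                         follow_up_range = c(6, 36),
                         outcome = "os", seed = 1L) {
  stopifnot(n_treatments >= 2, tau >= 0,
            diff(se_range) >= 0, se_range[1L] > 0,
            diff(arm_n_range) >= 0, arm_n_range[1L] >= 1,
            diff(ae_rate_range) >= 0, ae_rate_range[1L] > 0,
            diff(follow_up_range) >= 0, follow_up_range[1L] > 0)
  if (n_trials < n_treatments - 1L) {
    stop("impossible design: ", n_trials, " trials cannot connect ",
         n_treatments, " treatments")
  }
  if (is.null(true_d)) {
    set.seed(substream_seed(seed, "true-d"))
    true_d <- c(0, rnorm(n_treatments - 1L, 0, 0.3))
  }
  stopifnot(length(true_d) == n_treatments, true_d[1L] == 0)
  structure(list(n_treatments = as.integer(n_treatments),
                 n_trials = as.integer(n_trials),
                 true_d = true_d, tau = tau, se_range = se_range,
                 arm_n_range = arm_n_range,
                 baseline_logit_range = baseline_logit_range,
                 ae_rate_range = ae_rate_range,
                 follow_up_range = follow_up_range,
                 outcome = outcome, seed = as.integer(seed)),
            class = "nma_scenario")
}

.trt_ids <- function(K) sprintf("t%02d", seq_len(K))

# sparse star-plus-chords topology: a spanning tree biased towards the
# reference hub, plus extra trials on random pairs. The last treatment is
# always a leaf served by a single trial (chords avoid it), giving every
# scenario a built-in single-trial node for sensitivity analyses.
.topology <- function(scenario) {
  K <- scenario$n_treatments
  set.seed(substream_seed(scenario$seed, "topology"))
  base <- integer(K - 1L)
  for (k in 2L:K) {
    base[k - 1L] <- if (k == 2L || runif(1L) < 0.6) {
      1L
    } else sample.int(k - 1L, 1L)
  }
  edges <- cbind(base, 2L:K)
  extra <- scenario$n_trials - (K - 1L)
  if (extra > 0L) {
    pool <- if (K > 2L) K - 1L else K    # chords never touch the last node
    for (i in seq_len(extra)) {
      pr <- sample.int(pool, 2L)
      edges <- rbind(edges, sort(pr))
    }
  }
  data.frame(trial_id = sprintf("T%02d", seq_len(nrow(edges))),
             baseline = edges[, 1L], treatment = edges[, 2L])
}

#' Simulate a contrast-level evidence network with known truth
#'
#' Trial-specific effects are Normal(d_k - d_b, tau^2); observed contrasts
#' add Normal(0, se^2) sampling noise with se drawn from the scenario
#' range.
#'
#' @param scenario an [nma_scenario()].
#' @return list with `records` (contrast records ready for
#'   [build_network()]) and `truth` (true d, tau, per-trial effects,
#'   topology).
#' @export
simulate_contrast_network <- function(scenario) {
  stopifnot(inherits(scenario, "nma_scenario"))
  topo <- .topology(scenario)
  ids <- .trt_ids(scenario$n_treatments)
  set.seed(substream_seed(scenario$seed, "contrast-effects"))
  d_diff <- scenario$true_d[topo$treatment] - scenario$true_d[topo$baseline]
  delta <- rnorm(nrow(topo), d_diff, scenario$tau)
  se <- runif(nrow(topo), scenario$se_range[1L], scenario$se_range[2L])
  y <- rnorm(nrow(topo), delta, se)
  records <- data.frame(trial_id = topo$trial_id,
                        outcome = scenario$outcome,
                        treatment = ids[topo$treatment],
                        baseline_treatment = ids[topo$baseline],
                        log_effect = y, se = se,
                        effect_scale = "log_hr",
                        stringsAsFactors = FALSE)
  list(records = records,
       truth = list(treatments = ids, d = setNames(scenario$true_d, ids),
                    tau = scenario$tau, delta = delta, topology = topo))
}

#' Simulate an arm-level binary-outcome network with known truth
#'
#' Baseline log-odds are uniform on the scenario range; the non-baseline
#' arm adds the trial-specific log odds ratio Normal(d_k - d_b, tau^2);
#' responder counts are binomial.
#'
#' @param scenario an [nma_scenario()].
#' @return list with `records` (arm records) and `truth`.
#' @export
simulate_binary_network <- function(scenario) {
  stopifnot(inherits(scenario, "nma_scenario"))
  topo <- .topology(scenario)
  ids <- .trt_ids(scenario$n_treatments)
  set.seed(substream_seed(scenario$seed, "binary-arms"))
  mu <- runif(nrow(topo), scenario$baseline_logit_range[1L],
              scenario$baseline_logit_range[2L])
  d_diff <- scenario$true_d[topo$treatment] - scenario$true_d[topo$baseline]
  delta <- rnorm(nrow(topo), d_diff, scenario$tau)
  n1 <- round(runif(nrow(topo), scenario$arm_n_range[1L],
                    scenario$arm_n_range[2L]))
  n2 <- round(runif(nrow(topo), scenario$arm_n_range[1L],
                    scenario$arm_n_range[2L]))
  r1 <- rbinom(nrow(topo), n1, plogis(mu))
  r2 <- rbinom(nrow(topo), n2, plogis(mu + delta))
  records <- rbind(
    data.frame(trial_id = topo$trial_id, outcome = scenario$outcome,
               treatment = ids[topo$baseline], n = n1, events = r1,
               stringsAsFactors = FALSE),
    data.frame(trial_id = topo$trial_id, outcome = scenario$outcome,
               treatment = ids[topo$treatment], n = n2, events = r2,
               stringsAsFactors = FALSE))
  records <- records[order(records$trial_id, records$treatment), ]
  rownames(records) <- NULL
  list(records = records,
       truth = list(treatments = ids, d = setNames(scenario$true_d, ids),
                    tau = scenario$tau, mu = mu, delta = delta,
                    topology = topo))
}

#' Simulate an adverse-event network with heterogeneous follow-up
#'
#' Each arm's event probability over its trial follow-up f is
#' `p = 1 - exp(-f * rate_k)` with `rate_k = base_rate * exp(d_k)`; event
#' counts are binomial. In rare-event mode the base rate is capped so that
#' every achievable p stays at or below 2%.
#'
#' @param scenario an [nma_scenario()].
#' @param rare force rare events (all p <= 0.02). Default TRUE.
#' @return list with `records` (AE arm records incl. `follow_up`) and
#'   `truth`.
#' @export
simulate_ae_network <- function(scenario, rare = TRUE) {
  stopifnot(inherits(scenario, "nma_scenario"))
  topo <- .topology(scenario)
  ids <- .trt_ids(scenario$n_treatments)
  set.seed(substream_seed(scenario$seed, "ae-arms"))
  base_rate <- runif(1L, scenario$ae_rate_range[1L],
                     scenario$ae_rate_range[2L])
  if (rare) {
    cap <- -log(1 - 0.02) /
      (scenario$follow_up_range[2L] * max(exp(scenario$true_d)))
    base_rate <- min(base_rate, cap)
  }
  f <- runif(nrow(topo), scenario$follow_up_range[1L],
             scenario$follow_up_range[2L])
  rate_b <- base_rate * exp(scenario$true_d[topo$baseline])
  rate_t <- base_rate * exp(scenario$true_d[topo$treatment])
  n1 <- round(runif(nrow(topo), scenario$arm_n_range[1L],
                    scenario$arm_n_range[2L]))
  n2 <- round(runif(nrow(topo), scenario$arm_n_range[1L],
                    scenario$arm_n_range[2L]))
  p1 <- 1 - exp(-f * rate_b)
  p2 <- 1 - exp(-f * rate_t)
  records <- rbind(
    data.frame(trial_id = topo$trial_id, outcome = scenario$outcome,
               treatment = ids[topo$baseline], n = n1,
               events = rbinom(nrow(topo), n1, p1), follow_up = f,
               stringsAsFactors = FALSE),
    data.frame(trial_id = topo$trial_id, outcome = scenario$outcome,
               treatment = ids[topo$treatment], n = n2,
               events = rbinom(nrow(topo), n2, p2), follow_up = f,
               stringsAsFactors = FALSE))
  records <- records[order(records$trial_id, records$treatment), ]
  rownames(records) <- NULL
  list(records = records,
       truth = list(treatments = ids, d = setNames(scenario$true_d, ids),
                    base_rate = base_rate, follow_up = f,
                    p = cbind(baseline = p1, treatment = p2),
                    topology = topo))
}

#' Simulate a two-arm survival trial and its digitized KM curves
#'
#' Exponential event times with administrative censoring; the "digitized"
#' curve is the trial's product-limit estimate sampled at an even grid of
#' click points, with a number-at-risk table on a coarser grid — the input
#' that curve digitization of a published figure would yield.
#'
#' @param n_per_arm patients per arm.
#' @param true_hr hazard ratio of arm B versus arm A.
#' @param base_rate event rate of arm A (events/month).
#' @param censor_time administrative censoring time (months).
#' @param click_points number of digitized points per curve.
#' @param risk_interval spacing of the number-at-risk table (months).
#' @param seed seed.
#' @return list with `curve_a`, `curve_b` ([km_curve()]s), `ipd_a`,
#'   `ipd_b` (true pseudo-IPD), `true_loghr` (Cox estimate on the true
#'   IPD, arm B vs arm A) and `true_hr`.
#' @export
simulate_km_trial <- function(n_per_arm = 200, true_hr = 0.7,
                              base_rate = 0.1, censor_time = 24,
                              click_points = 100, risk_interval = 6,
                              seed = 1L) {
  stopifnot(n_per_arm >= 2, true_hr > 0, base_rate > 0, censor_time > 0)
  set.seed(substream_seed(seed, "km-trial"))
  draw_arm <- function(rate) {
    t_ev <- rexp(n_per_arm, rate)
    data.frame(time = pmin(t_ev, censor_time),
               status = as.integer(t_ev <= censor_time))
  }
  ipd_a <- draw_arm(base_rate)
  ipd_b <- draw_arm(base_rate * true_hr)
  digitize <- function(ipd) {
    km <- km_from_ipd(ipd)
    clicks <- seq(0, censor_time, length.out = click_points)
    risk_times <- seq(0, censor_time, by = risk_interval)
    km_curve(times = clicks, surv = km_surv_at(km, clicks),
             risk_times = risk_times,
             n_risk = vapply(risk_times, function(u) sum(ipd$time >= u),
                             numeric(1L)))
  }
  cox <- cox_loghr(ipd_b, ipd_a)
  list(curve_a = digitize(ipd_a), curve_b = digitize(ipd_b),
       ipd_a = ipd_a, ipd_b = ipd_b,
       true_loghr = cox$log_hr, true_hr = true_hr)
}

#' Scenarios matching the published evidence-network dimensions
#'
#' Fixture factory for regression testing against the analysis's network
#' sizes: 13 trials/14 treatments (rPFS-like), 20/18 (OS-like), 26/25
#' (PSA-response-like), 7/6 (chemo-initiation-like) and 12/11
#' (anemia-like).
#'
#' @param shape one of `"rpfs"`, `"os"`, `"psa_response"`, `"tt_chemo"`,
#'   `"ae_anemia"`.
#' @param seed master seed.
#' @param ... further arguments to [nma_scenario()].
#' @return an [nma_scenario()] of the corresponding dimensions.
#' @export
published_network_scenario <- function(shape = c("os", "rpfs", "psa_response",
                                            "tt_chemo", "ae_anemia"),
                                  seed = 1L, ...) {
  shape <- match.arg(shape)
  dims <- switch(shape,
                 rpfs = c(trials = 13L, treatments = 14L),
                 os = c(trials = 20L, treatments = 18L),
                 psa_response = c(trials = 26L, treatments = 25L),
                 tt_chemo = c(trials = 7L, treatments = 6L),
                 ae_anemia = c(trials = 12L, treatments = 11L))
  nma_scenario(n_treatments = dims["treatments"], n_trials = dims["trials"],
               outcome = shape, seed = seed, ...)
}
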