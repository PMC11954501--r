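#!/usr/bin/env Rscript
# Build the synthetic evidence base for the whole analysis: one
# contrast-level network per time-to-event outcome shape, one arm-level
# binary-response network, one rare-event safety network, and one
# digitized two-arm survival trial. Every generator writes its ground
# truth next to the data so later steps can score recovery.
#
# Outputs: results/synthetic/<outcome>_{contrasts,arms}.csv, truth.json,
#          km_points.csv / km_risk.csv.

suppressMessages(library(nmakit))
seed <- 20
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- list(seed = seed)

for (shape in c("os", "rpfs", "tt_chemo")) {
  sim <- simulate_contrast_network(published_network_scenario(shape, seed = seed))
  write.csv(data.frame(sim$records[c("trial_id", "outcome", "treatment",
                                     "baseline_treatment")],
                       log_hr = sim$records$log_effect,
                       se = sim$records$se),
            file.path(out, paste0(shape, "_contrasts.csv")),
            row.names = FALSE)
  truth[[shape]] <- list(d = as.list(sim$truth$d), tau = sim$truth$tau)
  cat(sprintf("%-12s %2d trials, %2d treatments\n", shape,
              length(unique(sim$records$trial_id)),
              length(sim$truth$treatments)))
}

simb <- simulate_binary_network(published_network_scenario("psa_response",
                                                      seed = seed))
write.csv(simb$records, file.path(out, "psa_response_arms.csv"),
          row.names = FALSE)
truth$psa_response <- list(d = as.list(simb$truth$d), tau = simb$truth$tau)
cat(sprintf("%-12s %2d trials, %2d treatments (binary arms)\n",
            "psa_response", length(unique(simb$records$trial_id)),
            length(simb$truth$treatments)))

sae <- simulate_ae_network(published_network_scenario(
  "ae_anemia", seed = seed, arm_n_range = c(200, 600)), rare = TRUE)
names(sae$records)[names(sae$records) == "follow_up"] <- "follow_up_months"
write.csv(sae$records, file.path(out, "ae_anemia_arms.csv"),
          row.names = FALSE)
truth$ae_anemia <- list(d = as.list(sae$truth$d),
                        base_rate = sae$truth$base_rate)
cat(sprintf("%-12s %2d trials, %2d treatments (AE arms, max p %.3f)\n",
            "ae_anemia", length(unique(sae$records$trial_id)),
            length(sae$truth$treatments), max(sae$truth$p)))

tr <- simulate_km_trial(n_per_arm = 200, true_hr = 0.7, base_rate = 0.1,
                        censor_time = 24, click_points = 100,
                        risk_interval = 6, seed = seed)
pts <- rbind(
  data.frame(trial_id = "KM1", arm = "control", time = tr$curve_a$times,
             survival = tr$curve_a$surv),
  data.frame(trial_id = "KM1", arm = "active", time = tr$curve_b$times,
             survival = tr$curve_b$surv))
rsk <- rbind(
  data.frame(trial_id = "KM1", arm = "control",
             time = tr$curve_a$risk_times, n_at_risk = tr$curve_a$n_risk),
  data.frame(trial_id = "KM1", arm = "active",
             time = tr$curve_b$risk_times, n_at_risk = tr$curve_b$n_risk))
write.csv(pts, file.path(out, "km_points.csv"), row.names = FALSE)
write.csv(rsk, file.path(out, "km_risk.csv"), row.names = FALSE)
truth$km_trial <- list(true_hr = tr$true_hr,
                       true_ipd_loghr = tr$true_loghr)
cat(sprintf("KM trial: true HR %.2f, true-IPD Cox log-HR %.4f\n",
            tr$true_hr, tr$true_loghr))

jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", file.path(out, "truth.json"), "\n")
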