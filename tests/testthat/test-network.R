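test_that("a triangle of two-arm trials builds a fully connected network", {
  net <- build_network(triangle_records(), "os", reference = "A")
  expect_s3_class(net, "evidence_network")
  expect_equal(nrow(net$treatments), 3L)
  expect_equal(nrow(net$edges), 3L)
  cc <- connected_component(net)
  expect_setequal(cc$component, c("A", "B", "C"))
  expect_length(cc$excluded, 0L)
})

test_that("published-dimension fixtures reproduce the published network sizes", {
  dims <- list(rpfs = c(13L, 14L), os = c(20L, 18L),
               psa_response = c(26L, 25L), tt_chemo = c(7L, 6L),
               ae_anemia = c(12L, 11L))
  for (shape in names(dims)) {
    sim <- simulate_contrast_network(published_network_scenario(shape, seed = 20))
    net <- build_network(sim$records, shape, reference = "t01")
    expect_equal(length(net$trials), dims[[shape]][1L], info = shape)
    expect_equal(nrow(net$treatments), dims[[shape]][2L], info = shape)
    expect_equal(nrow(net$edges), dims[[shape]][1L], info = shape)
    expect_equal(length(connected_component(net)$excluded), 0L,
                 info = shape)
  }
})

test_that("degenerate inputs are rejected with informative errors", {
  rec <- triangle_records()
  dup <- rbind(rec, rec[1L, ])
  expect_error(build_network(dup, "os", reference = "A"), "T1")
  expect_error(build_network(rec, "os", reference = "Z"), "reference")
  expect_error(build_network(rec, "other"), "outcome")
  single <- data.frame(trial_id = "T1", outcome = "resp", treatment = "A",
                       n = 10, events = 2)
  expect_error(build_network(single, "resp"), "single arm")
})

test_that("edge multiset reflects the trial-by-pair structure", {
  # arm-level 3-arm trial contributes all C(3,2) = 3 pairs
  arms <- data.frame(trial_id = "T1", outcome = "resp",
                     treatment = c("A", "B", "C"), n = 50,
                     events = c(10, 12, 8))
  net <- build_network(arms, "resp", reference = "A")
  expect_equal(nrow(net$edges), 3L)
  # contrast-level multi-arm trial: one edge per contrast
  con <- data.frame(trial_id = "T1", outcome = "os",
                    treatment = c("B", "C"), baseline_treatment = "A",
                    log_effect = c(0.1, 0.2), se = 0.1)
  expect_equal(nrow(build_network(con, "os", reference = "A")$edges), 2L)
})

test_that("node merging pools placebo arms, is idempotent, drops degenerate trials", {
  rec <- data.frame(trial_id = c("S1", "S2"), outcome = "os",
                    treatment = "drugX",
                    baseline_treatment = c("placebo_oral", "placebo_iv"),
                    log_effect = 0.1, se = 0.1)
  net <- build_network(rec, "os")
  mm <- c(placebo_oral = "pbo", placebo_iv = "pbo")
  merged <- merge_nodes(net, mm)
  expect_setequal(merged$treatments$id, c("drugX", "pbo"))
  expect_equal(length(merged$trials), 2L)
  expect_equal(merged$reference, "pbo")
  # idempotent: re-applying the surviving part of the map changes nothing
  again <- merge_nodes(merged, mm[names(mm) %in% merged$treatments$id])
  expect_identical(merged$edges, again$edges)
  # empty map is the identity
  expect_identical(merge_nodes(net, character(0L))$edges, net$edges)
  # merging both arms of a trial drops it with a warning
  rec2 <- data.frame(trial_id = c("S1", "S2"), outcome = "os",
                     treatment = c("pred", "drugX"),
                     baseline_treatment = "placebo",
                     log_effect = 0.1, se = 0.1)
  expect_warning(
    m2 <- merge_nodes(build_network(rec2, "os"),
                      c(pred = "pbo", placebo = "pbo")),
    "S1")
  expect_equal(length(m2$trials), 1L)
})

test_that("disconnected treatments are reported and excluded", {
  rec <- rbind(triangle_records(),
               data.frame(trial_id = "T4", outcome = "os", treatment = "E",
                          baseline_treatment = "D", log_effect = 0, se = 0.1))
  net <- build_network(rec, "os", reference = "A")
  cc <- connected_component(net)
  expect_setequal(cc$excluded, c("D", "E"))
  expect_setequal(cc$component, c("A", "B", "C"))
})

test_that("trial removal re-checks connectivity and reports orphans", {
  rec <- data.frame(trial_id = c("T1", "T2"), outcome = "os",
                    treatment = c("B", "C"), baseline_treatment = "A",
                    log_effect = 0.1, se = 0.1)
  net <- build_network(rec, "os", reference = "A")
  out <- suppressMessages(remove_trial(net, "T2"))
  expect_equal(attr(out, "orphaned"), "C")
  expect_error(remove_trial(net, "nope"), "unknown trial")
  # removing a duplicated comparison leaves the node set unchanged
  rec2 <- rbind(rec, data.frame(trial_id = "T3", outcome = "os",
                                treatment = "B", baseline_treatment = "A",
                                log_effect = 0.2, se = 0.1))
  net2 <- build_network(rec2, "os", reference = "A")
  out2 <- remove_trial(net2, "T3")
  expect_setequal(out2$treatments$id, net2$treatments$id)
  expect_length(attr(out2, "orphaned"), 0L)
  # equals building from the filtered record list
  direct <- build_network(rec2[rec2$trial_id != "T3", ], "os",
                          reference = "A")
  expect_equal(out2$edges, direct$edges)
})

test_that("the OS-shaped fixture survives its sensitivity exclusion", {
  sim <- simulate_contrast_network(published_network_scenario("os", seed = 20))
  net <- build_network(sim$records, "os", reference = "t01")
  # the last treatment is served by exactly one trial by construction
  leaf_trial <- sim$records$trial_id[sim$records$treatment == "t18"]
  expect_length(leaf_trial, 1L)
  out <- suppressMessages(remove_trial(net, leaf_trial))
  expect_equal(nrow(out$treatments), 17L)
  expect_length(connected_component(out)$excluded, 0L)
})

test_that("DOT export names every node and trial edge", {
  net <- build_network(triangle_records(), "os", reference = "A")
  dot <- network_to_dot(net)
  expect_match(dot, "graph \"os\"")
  for (id in c("A", "B", "C", "T1", "T2", "T3")) {
    expect_match(dot, id, fixed = TRUE)
  }
})
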