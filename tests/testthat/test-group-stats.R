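null_records <- function(seed, n_groups = 2, mice = 5, nodes = 20,
                         mouse_sd = 0.05, ratios = rep(1, n_groups),
                         labeled = 0, node_sd = 0) {
  cfg <- sim_config(n_groups = n_groups, n_mice_per_group = mice,
                    n_nodes_per_mouse = nodes, mouse_sd_um = mouse_sd,
                    node_sd_um = node_sd, group_length_ratios = ratios,
                    labeled_axon_fraction = labeled, seed = seed)
  truth_records(sample_geometry(cfg), "paranode_length")
}

test_that("with zero random variance the fit reduces to least squares", {
  rec <- null_records(7, mouse_sd = 0, ratios = c(1, 0.9))
  fit <- fit_mixed(rec, "paranode_length")
  ols <- lm(value_um ~ group + batch, data = fit$data)
  b_mixed <- fit$fixed_effects[, "Estimate"]
  b_ols <- coef(ols)
  expect_equal(unname(b_mixed[names(b_ols)]), unname(b_ols),
               tolerance = 1e-6)
})

test_that("contrast df are fractional and bracketed by the design", {
  rec <- null_records(11, mouse_sd = 0.05, node_sd = 0.03)
  fit <- fit_mixed(rec, "paranode_length")
  ct <- pairwise_contrasts(fit)
  n_mice <- length(unique(rec$mouse_id))
  expect_gt(ct$df, n_mice - 2 - 1)          # ~ between-mouse df
  expect_lt(ct$df, nrow(rec))               # < residual df
  expect_equal(ct$t, ct$estimate / ct$SE, tolerance = 1e-8)
  expect_true(ct$p >= 0 && ct$p <= 1)
})

test_that("contrast reports round-trip the published legend format", {
  s <- format_contrast("Con - Res", -2.356, 13.5, 0.034)
  expect_identical(s, "Con vs. Res, t(13.5) = -2.356, p = 0.034")
  p <- parse_contrast(s)
  expect_identical(p$contrast, "Con vs. Res")
  expect_equal(p$t, -2.356)
  expect_equal(p$df, 13.5)
  expect_equal(p$p, 0.034)

  rec <- null_records(13)
  ct <- pairwise_contrasts(fit_mixed(rec, "paranode_length"))
  rt <- parse_contrast(ct$report[1])
  expect_equal(rt$t, round(ct$t[1], 3), tolerance = 1e-9)

  # a group contrasted with itself is identically zero
  self <- pairwise_contrasts(fit_mixed(rec, "paranode_length"),
                             pairs = "control - control")
  expect_equal(self$estimate, 0)
  expect_equal(self$t, 0)
  expect_error(pairwise_contrasts(fit_mixed(rec, "paranode_length"),
                                  pairs = "control - nothere"), "key error")
})

test_that("aliased batch and group design is reported as a fit error", {
  rec <- null_records(17)
  rec$batch <- ifelse(rec$group == "control", "batchA", "batchB")
  expect_error(fit_mixed(rec, "paranode_length"), "fit error.*batch")
})

test_that("percent differences derive from adjusted means and swap cleanly", {
  set.seed(5)
  base <- data.frame(
    measure = "paranode_length",
    mouse_id = rep(sprintf("m%d", 1:8), each = 40),
    node_id = sprintf("n%03d", rep(1:160, each = 2)),
    group = rep(c("control", "treated"), each = 160),
    batch = "batch1", axon_type = "n/a", stringsAsFactors = FALSE)
  n1 <- rnorm(160); n1 <- n1 - mean(n1)
  n2 <- rnorm(160); n2 <- n2 - mean(n2)
  base$value_um <- c(1.6 + n1 * 0.01, 1.435 + n2 * 0.01)
  fit <- fit_mixed(base, "paranode_length")
  pd <- percent_difference(fit, "control", "treated")
  expect_equal(pd, 100 * (1.435 - 1.6) / 1.6, tolerance = 0.02)
  expect_equal(round(abs(pd), 1), 10.3)
  # swapping reference rescales and flips sign
  pd_sw <- percent_difference(fit, "treated", "control")
  expect_gt(pd_sw, 0)
  expect_equal(pd_sw, 100 * (1.6 - 1.435) / 1.435, tolerance = 0.02)
  # identical groups: zero
  expect_equal(percent_difference(fit, "control", "control"), 0)
  # raw and adjusted agree without batch structure
  expect_equal(percent_difference(fit, "control", "treated", type = "raw"),
               pd, tolerance = 0.05)
})

test_that("injected between-mouse variance is recovered from the fit", {
  cfg <- sim_config(n_groups = 2, n_mice_per_group = 6, n_nodes_per_mouse = 50,
                    mouse_sd_um = 0.05, seed = 29)
  rec <- truth_records(sample_geometry(cfg), "paranode_length")
  fit <- fit_mixed(rec, "paranode_length")
  est <- fit$variance_components[["mouse_id"]]
  expect_lt(abs(est - 0.05) / 0.05, 0.5)
})

test_that("interaction model isolates axon-specific effects", {
  cfg <- sim_config(n_groups = 2, n_mice_per_group = 6, n_nodes_per_mouse = 35,
                    group_names = c("control_virus", "hM3Dq"),
                    labeled_axon_fraction = 0.6,
                    labeled_effect_ratio = c(1, 0.861), seed = 33)
  rec <- truth_records(sample_geometry(cfg), "paranode_length")
  fit <- fit_interaction(rec)
  expect_s3_class(fit, "ranvier_interaction_fit")
  expect_equal(nrow(fit$interaction), 1)
  expect_lt(fit$interaction[1, "Pr(>|t|)"], 0.05)
  pd_lab <- percent_difference(fit, "control_virus", "hM3Dq",
                               axon_type = "labeled")
  pd_unl <- percent_difference(fit, "control_virus", "hM3Dq",
                               axon_type = "non-labeled")
  expect_equal(pd_lab, -13.9, tolerance = 2.5)
  expect_lt(abs(pd_unl), 2.5)

  # swapping the group labels negates the interaction estimate
  rec_sw <- rec
  rec_sw$group <- ifelse(rec$group == "hM3Dq", "control_virus", "hM3Dq")
  fit_sw <- fit_interaction(rec_sw)
  expect_equal(unname(fit_sw$interaction[1, "Estimate"]),
               -unname(fit$interaction[1, "Estimate"]), tolerance = 1e-6)

  no_ax <- rec; no_ax$axon_type <- "labeled"
  expect_error(fit_interaction(no_ax), "contract error")
})

test_that("a null interaction stays null across repeated cohorts", {
  hits <- 0L; reps <- 150L
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_groups = 2, n_mice_per_group = 6,
                      n_nodes_per_mouse = 35,
                      group_names = c("control_virus", "hM3Dq"),
                      labeled_axon_fraction = 0.6,
                      labeled_effect_ratio = 1, seed = 4000 + r)
    rec <- truth_records(sample_geometry(cfg), "paranode_length")
    fit <- suppressWarnings(fit_interaction(rec))   # occasional near-boundary
    if (abs(fit$interaction[1, "t value"]) < 2) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.90)
})
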