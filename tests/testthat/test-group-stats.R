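test_that("compare_measure handles identity, direction and degenerate input", {
  same <- c(1, 2, 3, 4, 5)
  r <- compare_measure(same, same)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  expect_error(
    compare_measure(c(1, 2), c(1, 2, 3)),
    class = "gazenav_insufficient_data_error"
  )

  # swap symmetry: t flips sign, p unchanged
  set.seed(3)
  a <- rnorm(20, 1); b <- rnorm(25, 2)
  r1 <- compare_measure(a, b)
  r2 <- compare_measure(b, a)
  expect_equal(r1$t_statistic, -r2$t_statistic)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$se_mnl, sd(a) / sqrt(20))
})

test_that("groups with table-sized separation are strongly significant", {
  # saccadic amplitude: 2.48 +/- 0.19 SE (n=51) vs 1.45 +/- 0.08 SE (n=77)
  set.seed(8)
  mnl <- rnorm(51, 2.48, 0.19 * sqrt(51))
  non <- rnorm(77, 1.45, 0.08 * sqrt(77))
  r <- compare_measure(mnl, non, "mean_sacamp_deg")
  expect_lt(r$p_value, 0.001)
  expect_gt(r$mean_mnl, r$mean_non)
})

test_that("type-I error under the null is calibrated at alpha = 0.05", {
  set.seed(12345)
  n_rep <- 10000
  hits <- 0L
  for (i in seq_len(n_rep)) {
    r <- compare_measure(rnorm(10), rnorm(10))
    if (r$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.04)
  expect_lte(hits / n_rep, 0.06)
})

test_that("comparison tables cover every measure and need both labels", {
  d <- generate_dataset(n_mnl = 10, n_non = 10, seed = 5)
  m <- phase_metrics(d$recording, d$annotations)
  tab <- build_comparison_tables(m)
  num_cols <- setdiff(
    names(m)[vapply(m, is.numeric, logical(1))], "phase_id"
  )
  expect_setequal(tab$measure, num_cols)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$se_mnl >= 0))

  single <- build_comparison_tables(m, measures = "mean_sacamp_deg")
  expect_equal(nrow(single), 1)

  expect_error(
    build_comparison_tables(dplyr::filter(m, label == "MNL")),
    class = "gazenav_contract_error"
  )
})

test_that("label shuffling destroys the group differences", {
  d <- generate_dataset(n_mnl = 15, n_non = 15, seed = 6)
  m <- phase_metrics(d$recording, d$annotations)
  meas <- c("mean_sacamp_deg", "aps_trial_avg", "fixdis_below_75")
  set.seed(99)
  frac_sig <- replicate(10, {
    ms <- m
    ms$label <- sample(ms$label)
    tab <- build_comparison_tables(ms, measures = meas)
    mean(tab$p_value < 0.05)
  })
  # under shuffled labels significance collapses to around the alpha level
  expect_lt(mean(frac_sig), 0.15)
})

test_that("feature selection reproduces the 12-feature set from printed p-values", {
  # reconstruction of the reported comparison tables: measure, group means, p
  printed <- tibble::tribble(
    ~measure, ~mean_mnl, ~mean_non, ~p_value,
    "phase_duration_s", 12.53, 22.97, 0.0001,
    "saccade_duration_s", 5.49, 10.78, 0.003,
    "saccade_number", 52.06, 101.19, 0.0001,
    "fixation_number", 23.69, 40.94, 0.0001,
    "saccade_frequency", 4.29, 4.60, 0.329,
    "fixation_frequency", 2.04, 1.95, 0.406,
    "gaze_event_frequency", 6.34, 6.55, 0.530,
    "mean_saccade_duration_s", 0.10, 0.09, 0.474,
    "mean_fixation_duration_s", 0.30, 0.28, 0.490,
    "saccade_duration_pct", 41.19, 44.10, 0.506,
    "saccade_number_pct", 65.36, 68.91, 0.082,
    "fixation_number_pct", 34.64, 31.09, 0.082,
    "fixdis_below_25", 29.05, 43.22, 0.0001,
    "fixdis_below_50", 48.70, 66.67, 0.0001,
    "fixdis_below_75", 63.60, 82.53, 0.0001,
    "fixdis_below_100", 75.80, 90.35, 0.0001,
    "mean_sacamp_deg", 2.48, 1.45, 0.0001,
    "sacamp_above_1.5", 61.38, 44.13, 0.0001,
    "sacamp_above_2.0", 54.22, 34.41, 0.0001,
    "sacamp_above_2.5", 46.60, 25.12, 0.0001,
    "sacamp_above_3.0", 39.26, 19.33, 0.0001,
    "sacamp_above_3.5", 32.17, 14.08, 0.0001,
    "sacamp_above_4.0", 25.33, 11.14, 0.0001,
    "sacamp_above_4.5", 21.66, 8.36, 0.0001,
    "sacamp_above_5.0", 18.78, 6.48, 0.0001,
    "sacamp_above_5.5", 16.17, 5.01, 0.0001,
    "sacamp_above_6.0", 12.99, 4.15, 0.0001,
    "sacamp_above_6.5", 11.91, 3.65, 0.0001,
    "sacamp_above_7.0", 11.03, 2.69, 0.0001,
    "sacamp_above_7.5", 9.84, 2.03, 0.0001,
    "aps_trial_avg", 46.97, 63.45, 0.0001,
    "aps_sac_avg", 46.51, 62.62, 0.0001,
    "aps_fix_avg", 47.44, 64.23, 0.0001,
    "aps_cf55_avg", 26.20, 70.04, 0.0001,
    "aps_modal_bin_avg", 9.99, 13.57, 0.0001
  )
  res <- structure(printed, class = c("mnl_comparison", class(printed)))
  sel <- select_features(res)
  expect_length(sel, 12)
  expect_setequal(sel, c(
    "phase_duration_s", "saccade_duration_s", "saccade_number",
    "fixation_number", "fixdis_below_75", "mean_sacamp_deg",
    "sacamp_above_2.5", "aps_trial_avg", "aps_sac_avg", "aps_fix_avg",
    "aps_cf55_avg", "aps_modal_bin_avg"
  ))

  # boundary behaviour of alpha
  expect_length(select_features(dplyr::mutate(res, p_value = 1)), 0)
  all_sel <- select_features(res, alpha = 1.000001)
  expect_true(all(c("saccade_frequency", "mean_fixation_duration_s") %in% all_sel))
})

test_that("tidy and glance summarize comparison tables", {
  d <- generate_dataset(n_mnl = 8, n_non = 8, seed = 17)
  m <- phase_metrics(d$recording, d$annotations)
  tab <- build_comparison_tables(m, measures = c("mean_sacamp_deg", "aps_trial_avg"))
  td <- tidy(tab)
  expect_s3_class(td, "tbl_df")
  g <- glance(tab)
  expect_equal(g$n_measures, 2)
})
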