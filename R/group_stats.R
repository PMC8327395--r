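#' Compare one measure between MNL and non-MNL phases
#'
#' Group means and standard errors, per-group Shapiro-Wilk normality p-values,
#' and a two-sided independent-samples t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance variant). Each phase counts as
#' one independent observation.
#'
#' @param values_mnl,values_non per-phase values for the two groups (n >= 3
#'   each).
#' @param name measure name carried into the result.
#' @param var_equal pool the variances? Default `FALSE` (Welch).
#' @return One-row tibble: `measure`, `mean_mnl`, `se_mnl`, `mean_non`,
#'   `se_non`, `n_mnl`, `n_non`, `shapiro_p_mnl`, `shapiro_p_non`,
#'   `t_statistic`, `p_value`.
#' @export
compare_measure <- function(values_mnl, values_non, name = "measure",
                            var_equal = FALSE) {
  values_mnl <- values_mnl[is.finite(values_mnl)]
  values_non <- values_non[is.finite(values_non)]
  if (length(values_mnl) < 3 || length(values_non) < 3) {
    stop_insufficient("compare_measure needs at least 3 finite values per group")
  }
  sw <- function(v) {
    # shapiro.test rejects constant input; a constant sample is maximally
    # non-normal for our purposes
    if (sd(v) == 0 || length(v) > 5000) return(NA_real_)
    shapiro.test(v)$p.value
  }
  if (sd(values_mnl) == 0 && sd(values_non) == 0 &&
      mean(values_mnl) == mean(values_non)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(values_mnl, values_non, var.equal = var_equal)
  }
  tibble(
    measure = name,
    mean_mnl = mean(values_mnl),
    se_mnl = sd(values_mnl) / sqrt(length(values_mnl)),
    mean_non = mean(values_non),
    se_non = sd(values_non) / sqrt(length(values_non)),
    n_mnl = length(values_mnl),
    n_non = length(values_non),
    shapiro_p_mnl = sw(values_mnl),
    shapiro_p_non = sw(values_non),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value
  )
}

# canonical panel order mirroring the reporting tables: time/frequency,
# gaze travel, pupil
panel_measure_order <- function(measures) {
  canon <- c(
    "phase_duration_s", "saccade_duration_s", "saccade_number",
    "fixation_number", "saccade_frequency", "fixation_frequency",
    "gaze_event_frequency", "mean_saccade_duration_s",
    "mean_fixation_duration_s", "saccade_duration_pct",
    "saccade_number_pct", "fixation_number_pct",
    sprintf("fixdis_below_%d", fixdis_bounds),
    "mean_sacamp_deg",
    sprintf("sacamp_above_%.1f", sacamp_thresholds),
    paste0("aps_trial_", c("left", "right")),
    paste0("aps_sac_", c("left", "right")),
    paste0("aps_fix_", c("left", "right")),
    paste0("aps_cf55_", c("left", "right")),
    paste0("aps_modal_bin_", c("left", "right")),
    paste0(c("aps_trial", "aps_sac", "aps_fix", "aps_cf55", "aps_modal_bin"), "_avg")
  )
  c(intersect(canon, measures), setdiff(measures, canon))
}

#' Build the MNL vs non-MNL comparison table
#'
#' Runs [compare_measure()] for every measure column of a per-phase metric
#' panel (or any per-phase table with a `label` column), ordered as in the
#' standard reporting tables.
#'
#' @param panels per-phase tibble with a `label` column (MNL/non-MNL) and
#'   numeric measure columns, e.g. from [phase_metrics()].
#' @param measures optional character vector restricting/ordering the measures.
#' @param var_equal see [compare_measure()].
#' @return A tibble of class `mnl_comparison`, one row per measure.
#' @export
build_comparison_tables <- function(panels, measures = NULL, var_equal = FALSE) {
  panels <- as_tibble(panels)
  if (!"label" %in% names(panels)) stop_contract("panels need a 'label' column")
  lab <- as.character(panels$label)
  if (!all(phase_labels %in% lab)) {
    stop_contract("both MNL and non-MNL phases must be present")
  }
  num_cols <- names(panels)[vapply(panels, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "phase_id")
  if (is.null(measures)) measures <- panel_measure_order(num_cols)
  measures <- intersect(measures, num_cols)
  if (length(measures) == 0) stop_contract("no numeric measures to compare")
  out <- purrr::map_dfr(measures, function(m) {
    compare_measure(
      panels[[m]][lab == "MNL"], panels[[m]][lab == "non-MNL"],
      name = m, var_equal = var_equal
    )
  })
  class(out) <- c("mnl_comparison", class(out))
  out
}

# family membership used for feature selection: cumulative-frequency ladders
# contribute a single representative (their largest significant group
# difference), mirroring how the measures were screened
selection_families <- function(measures) {
  fam <- rep("singleton", length(measures))
  fam[grepl("^sacamp_above_", measures)] <- "sacamp_ladder"
  fam[grepl("^fixdis_below_", measures)] <- "fixdis_ladder"
  setNames(fam, measures)
}

# candidate set for the classifier: the eye-averaged pupil measures plus the
# time/frequency and gaze-travel panels (per-eye duplicates are excluded so
# the selected set matches the 12-feature contract)
selection_candidates <- function() {
  c(
    "phase_duration_s", "saccade_duration_s", "saccade_number",
    "fixation_number", "saccade_frequency", "fixation_frequency",
    "gaze_event_frequency", "mean_saccade_duration_s",
    "mean_fixation_duration_s", "saccade_duration_pct",
    "saccade_number_pct", "fixation_number_pct",
    sprintf("fixdis_below_%d", fixdis_bounds),
    "mean_sacamp_deg",
    sprintf("sacamp_above_%.1f", sacamp_thresholds),
    paste0(c("aps_trial", "aps_sac", "aps_fix", "aps_cf55", "aps_modal_bin"), "_avg")
  )
}

#' Significance-driven feature selection
#'
#' Selects classifier features from a comparison table: every candidate
#' measure with `p < alpha`, with each cumulative-frequency ladder (saccadic
#' amplitude thresholds, inter-fixation distance bands) contributing only its
#' single best representative — the significant threshold with the largest
#' absolute group-mean difference. Eye-averaged pupil measures are the pupil
#' candidates. With the canonical panel as input this yields the 12-feature
#' classifier set.
#'
#' @param results an `mnl_comparison` tibble from [build_comparison_tables()].
#' @param alpha significance level (default 0.05).
#' @param candidates candidate measure names; defaults to the canonical panel.
#' @return Character vector of selected measure names, in panel order.
#' @export
select_features <- function(results, alpha = 0.05, candidates = selection_candidates()) {
  if (nrow(results) == 0) stop_contract("empty comparison table")
  res <- filter(results, .data$measure %in% candidates)
  sig <- filter(res, .data$p_value < alpha)
  if (nrow(sig) == 0) return(character(0))
  fam <- selection_families(sig$measure)
  keep <- character(0)
  for (f in unique(fam)) {
    mm <- sig$measure[fam == f]
    if (f == "singleton") {
      keep <- c(keep, mm)
    } else {
      diffs <- abs(sig$mean_mnl[fam == f] - sig$mean_non[fam == f])
      keep <- c(keep, mm[which.max(diffs)])
    }
  }
  intersect(panel_measure_order(res$measure), keep)
}

#' @export
tidy.mnl_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.mnl_comparison <- function(x, ...) {
  tibble(
    n_measures = nrow(x),
    n_significant = sum(x$p_value < 0.05),
    n_mnl = x$n_mnl[1],
    n_non = x$n_non[1]
  )
}
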