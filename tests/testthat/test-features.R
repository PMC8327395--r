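test_that("pupil range tracks valid samples and rejects degenerate data", {
  rec <- make_recording(
    x = rep(100, 3), y = rep(100, 3),
    pupil = c(3.0, 3.5, 4.0)
  )
  pr <- pupil_range(rec)
  expect_equal(pr$ps_min_left, 3.0)
  expect_equal(pr$ps_max_left, 4.0)

  rec_const <- make_recording(x = rep(1, 3), y = rep(1, 3), pupil = rep(3, 3))
  expect_error(pupil_range(rec_const), class = "gazenav_insufficient_data_error")

  rec_gap <- make_recording(
    x = rep(1, 3), y = rep(1, 3), pupil = c(3.0, 9.9, 4.2),
    valid = c(TRUE, FALSE, TRUE)
  )
  pr <- pupil_range(rec_gap)
  expect_equal(c(pr$ps_min_left, pr$ps_max_left), c(3.0, 4.2))
})

test_that("adjusted pupil size hits its anchors and clamps", {
  expect_equal(adjusted_pupil_size(3.0, 3.0, 4.0), 0)
  expect_equal(adjusted_pupil_size(4.0, 3.0, 4.0), 100)
  expect_equal(adjusted_pupil_size(3.5, 3.0, 4.0), 50)
  expect_equal(adjusted_pupil_size(c(2.9, 4.1), 3.0, 4.0), c(0, 100)) # clamp
  expect_error(adjusted_pupil_size(3, 4, 4), class = "gazenav_insufficient_data_error")
})

test_that("saccadic amplitude converts px to visual angle", {
  g <- screen_geometry(width_mm = 300, height_mm = 225)
  expect_equal(saccade_amplitude_deg(10, 20, 10, 20, g), 0)
  # 100 px * (300/1024) mm/px = 29.297 mm; 2*atan(14.648/600) = 2.797 deg
  expect_equal(saccade_amplitude_deg(0, 0, 100, 0, g), 2.797, tolerance = 5e-4)
  expect_equal(
    saccade_amplitude_deg(3, 4, 90, 120, g),
    saccade_amplitude_deg(90, 120, 3, 4, g)
  )
  # generator's inverse conversion round-trips
  expect_equal(gazenav:::px_to_deg(gazenav:::deg_to_px(2.5, g), g), 2.5)
})

test_that("cumulative frequency respects its side conventions", {
  expect_equal(cumulative_frequency(c(1, 2, 3, 4), 2.5, "above"), 50)
  expect_equal(cumulative_frequency(c(10, 30, 60, 80), 25, "below_or_equal"), 25)
  expect_equal(cumulative_frequency(c(1, 5, 9), -Inf, "above"), 100)
  expect_equal(cumulative_frequency(c(2, 2), 2, "above"), 0) # strict
  expect_equal(cumulative_frequency(c(2, 2), 2, "below_or_equal"), 100) # inclusive
  expect_error(cumulative_frequency(numeric(0), 1), class = "gazenav_insufficient_data_error")
})

test_that("modal APS interval uses half-open 5% bins with low tie-break", {
  expect_equal(aps_modal_bin_index(rep(47, 5)), 10)
  expect_equal(aps_modal_bin_index(rep(2, 3)), 1)
  expect_equal(aps_modal_bin_index(c(3, 3, 67)), 1)
  expect_equal(aps_modal_bin_index(c(100, 100, 97)), 20) # [95,100] closed
  expect_equal(aps_modal_bin_index(c(5)), 2) # bin edges belong upward
  expect_equal(aps_modal_bin_index(c(2, 7)), 1) # tie breaks low
  expect_error(aps_modal_bin_index(numeric(0)), class = "gazenav_insufficient_data_error")
  expect_error(aps_modal_bin_index(c(-1, 5)), class = "gazenav_contract_error")
})

# hand-built recording: 1 s phase with fixation-saccade-fixation-saccade-fixation
built_phase <- function() {
  # fixation A (9 samples), saccade (6), fixation B (9), saccade (6), fixation C (30)
  seg <- function(n, x0, step) x0 + cumsum(rep(step, n)) - step
  x <- c(
    rep(100, 9), seg(6, 140, 40), rep(380, 9), seg(6, 420, 40), rep(660, 30)
  )
  y <- rep(300, length(x))
  pupil <- seq(3, 4, length.out = length(x))
  make_recording(x, y, pupil = pupil)
}

test_that("the per-phase metric panel counts, times and normalizes correctly", {
  rec <- built_phase()
  n <- nrow(rec$samples)
  ann <- tibble::tibble(
    phase_id = 1, label = factor("MNL", levels = c("MNL", "non-MNL")),
    start_ms = 0, end_ms = n * dt60
  )
  m <- suppressWarnings(phase_metrics(rec, ann))
  expect_equal(nrow(m), 1)
  expect_equal(m$saccade_number, 2)
  expect_equal(m$fixation_number, 3)
  expect_equal(m$saccade_number_pct + m$fixation_number_pct, 100)
  expect_equal(m$saccade_number_pct, 100 * 2 / 5)
  expect_equal(m$saccade_frequency, 2 / m$phase_duration_s)
  expect_equal(m$gaze_event_frequency, 5 / m$phase_duration_s)
  # saccade duration share of labelled event time
  expect_equal(
    m$saccade_duration_pct,
    100 * m$saccade_duration_s /
      (m$saccade_duration_s + 3 * m$mean_fixation_duration_s),
    tolerance = 1e-9
  )
  # the APS mean over the phase equals the per-sample mean of Eq-normalized
  # pupil values (duration-unweighted)
  pr <- pupil_range(rec)
  aps <- adjusted_pupil_size(rec$samples$pupil_left, pr$ps_min_left, pr$ps_max_left)
  expect_equal(m$aps_trial_left, mean(aps), tolerance = 1e-9)
})

test_that("identical fixation centroids give 100% close inter-fixation distances", {
  # fixation at 100, an out-and-back saccade, fixation at 100 again
  x <- c(rep(100, 9), c(140, 180, 220, 180, 140), rep(100, 9))
  y <- rep(300, length(x))
  rec <- make_recording(x, y, pupil = seq(3, 4, length.out = length(x)))
  ann <- tibble::tibble(
    phase_id = 1, label = factor("MNL", levels = c("MNL", "non-MNL")),
    start_ms = 0, end_ms = length(x) * dt60
  )
  m <- phase_metrics(rec, ann)
  expect_equal(m$fixdis_below_25, 100)
  expect_equal(m$fixdis_below_75, 100)
})

test_that("cumulative-frequency ladders are monotone on generated phases", {
  d <- generate_dataset(n_mnl = 6, n_non = 6, seed = 13)
  m <- phase_metrics(d$recording, d$annotations)
  sac_cols <- sprintf("sacamp_above_%.1f", seq(1.5, 7.5, by = 0.5))
  fix_cols <- sprintf("fixdis_below_%d", c(25, 50, 75, 100))
  for (i in seq_len(nrow(m))) {
    expect_true(all(diff(unlist(m[i, sac_cols])) <= 1e-9))
    expect_true(all(diff(unlist(m[i, fix_cols])) >= -1e-9))
  }
  expect_true(all(m$saccade_number_pct + m$fixation_number_pct == 100))
  aps_cols <- grep("^aps_(trial|sac|fix|cf55)_", names(m), value = TRUE)
  expect_true(all(m[aps_cols] >= 0 & m[aps_cols] <= 100, na.rm = TRUE))
})

test_that("classifier features use a 5 s onset window but full phase duration", {
  d <- generate_dataset(n_mnl = 4, n_non = 4, seed = 21)
  fv <- phase_features(d$recording, d$annotations)
  expect_setequal(
    setdiff(names(fv), c("phase_id", "label")),
    gazenav:::feature_vector_names
  )
  expect_equal(length(gazenav:::feature_vector_names), 12)
  m <- phase_metrics(d$recording, d$annotations)
  # full annotated duration is carried even for long phases
  expect_equal(fv$phase_duration_s, m$phase_duration_s[match(fv$phase_id, m$phase_id)])
  # a phase longer than 5 s cannot contribute more than ~5 s of saccade time
  long <- fv$phase_duration_s > 6
  if (any(long)) expect_true(all(fv$saccade_duration_s[long] <= 5))
  # short phases use the whole phase
  ann3 <- d$annotations[1, ]
  short_end <- min(ann3$start_ms + 3000, ann3$end_ms)
  ann3$end_ms <- short_end
  fv3 <- phase_features(d$recording, ann3)
  expect_equal(fv3$phase_duration_s, (short_end - ann3$start_ms) / 1000)
})

test_that("events are assigned to phases by midpoint without double counting", {
  d <- generate_dataset(n_mnl = 3, n_non = 3, seed = 31)
  ev <- detect_events(d$recording)
  idx <- gazenav:::assign_events_to_phase(ev, d$annotations)
  mid <- (ev$start_ms + ev$end_ms) / 2
  ok <- !is.na(idx)
  expect_true(all(mid[ok] >= d$annotations$start_ms[idx[ok]]))
  expect_true(all(mid[ok] < d$annotations$end_ms[idx[ok]]))
  # each event lands in at most one phase by construction of the intervals
  expect_true(all(table(ev$start_ms[ok]) == 1))
})
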