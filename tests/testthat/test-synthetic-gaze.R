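test_that("planned amplitudes track the preset marginal", {
  set.seed(4)
  preset <- mnl_preset()
  amps <- c()
  while (length(amps) < 10000) {
    plan <- sample_event_plan("MNL", preset)
    amps <- c(amps, plan$events$amp_deg[plan$events$kind == "saccade"])
  }
  # return saccades are mean-preserving, so the pooled mean tracks the preset
  expect_equal(mean(amps), preset$sacamp_mean_deg, tolerance = 0.02 * preset$sacamp_mean_deg)
})

test_that("phase plans fill the drawn duration with alternating events", {
  set.seed(9)
  plan <- sample_event_plan("non-MNL")
  ev <- plan$events
  expect_equal(ev$kind[1], "saccade") # phases open with a saccade
  expect_equal(ev$kind[nrow(ev)], "fixation") # and close with a fixation
  expect_true(all(ev$kind == rep(c("saccade", "fixation"), nrow(ev) / 2)))
  expect_equal(sum(ev$n_samples), plan$n_samples)
  # landing points respect the screen
  g <- screen_geometry()
  expect_true(all(ev$x >= 0 & ev$x <= g$width_px))
  expect_true(all(ev$y >= 0 & ev$y <= g$height_px))
})

test_that("zero-variance presets give deterministic plans under a seed", {
  preset <- mnl_preset(
    phase_duration_sd_s = 0, fix_duration_sd_s = 0, sacc_duration_sd_s = 0,
    p_short_fix = 0, aps_between_sd = 0
  )
  set.seed(31); p1 <- sample_event_plan("MNL", preset)
  set.seed(31); p2 <- sample_event_plan("MNL", preset)
  expect_identical(p1$events, p2$events)
  expect_identical(p1$aps_level, p2$aps_level)
  expect_equal(p1$events$n_samples[!duplicated(p1$events$kind)],
               p2$events$n_samples[!duplicated(p2$events$kind)])
})

test_that("a rendered fixation stays below the velocity threshold", {
  set.seed(2)
  plan <- structure(
    list(
      label = "MNL",
      events = tibble::tibble(
        kind = "fixation", n_samples = 18L, amp_deg = NA_real_, x = 500, y = 400
      ),
      aps_level = 50, n_samples = 18L, preset = mnl_preset()
    ),
    class = "event_plan"
  )
  r <- render_gaze(plan, start_xy = c(500, 400))
  expect_equal(nrow(r$samples), 18) # 300 ms at 60 Hz
  v <- sqrt(diff(r$samples$x_px)^2 + diff(r$samples$y_px)^2) / dt60
  expect_true(all(v < 2.1))
})

test_that("rendering a fixation-saccade-fixation plan is recovered by I-VT", {
  set.seed(6)
  plan <- structure(
    list(
      label = "MNL",
      events = tibble::tibble(
        kind = c("fixation", "saccade", "fixation"),
        n_samples = c(12L, 6L, 12L),
        amp_deg = c(NA, 3, NA),
        x = c(400, 580, 580), y = c(300, 300, 300)
      ),
      aps_level = 50, n_samples = 30L, preset = mnl_preset()
    ),
    class = "event_plan"
  )
  r <- render_gaze(plan, start_xy = c(400, 300))
  rec <- make_recording(r$samples$x_px, r$samples$y_px,
                        pupil = seq(3, 4, length.out = 30))
  ev <- detect_events(rec)
  expect_equal(ev$kind, c("fixation", "saccade", "fixation"))
})

test_that("an empty plan renders an empty segment", {
  plan <- structure(
    list(
      label = "MNL",
      events = tibble::tibble(
        kind = character(), n_samples = integer(), amp_deg = double(),
        x = double(), y = double()
      ),
      aps_level = 50, n_samples = 0L, preset = mnl_preset()
    ),
    class = "event_plan"
  )
  r <- render_gaze(plan)
  expect_equal(nrow(r$samples), 0)
})

test_that("generated datasets carry exact labelled annotations", {
  d <- generate_dataset(n_mnl = 51, n_non = 77, seed = 7)
  expect_equal(sum(d$annotations$label == "MNL"), 51)
  expect_equal(sum(d$annotations$label == "non-MNL"), 77)
  # annotations tile the recording without overlap
  a <- d$annotations
  expect_true(all(utils::head(a$end_ms, -1) == utils::tail(a$start_ms, -1)))
  # all samples on-screen and valid, timestamps strictly increasing
  s <- d$recording$samples
  expect_true(all(s$x_px >= 0 & s$x_px <= 1024))
  expect_true(all(s$y_px >= 0 & s$y_px <= 768))
  expect_true(all(diff(s$t_ms) > 0))
})

test_that("generation is bit-identical under a fixed seed", {
  d1 <- generate_dataset(n_mnl = 2, n_non = 3, seed = 1234)
  d2 <- generate_dataset(n_mnl = 2, n_non = 3, seed = 1234)
  expect_identical(d1$recording$samples, d2$recording$samples)
  expect_identical(d1$annotations, d2$annotations)
  d3 <- generate_dataset(n_mnl = 2, n_non = 3, seed = 1235)
  expect_false(identical(d1$recording$samples, d3$recording$samples))
})

test_that("a minimal two-phase dataset works end to end", {
  d <- generate_dataset(n_mnl = 1, n_non = 1, seed = 3)
  expect_equal(nrow(d$annotations), 2)
  m <- phase_metrics(d$recording, d$annotations)
  expect_equal(nrow(m), 2)
  expect_true(all(is.finite(m$mean_sacamp_deg)))
})

test_that("the trial-wide pupil pre-roll anchors APS normalization exactly", {
  d <- generate_dataset(n_mnl = 2, n_non = 2, seed = 19)
  pr <- pupil_range(d$recording)
  # the pre-roll sweeps APS 0..100 through the fixed affine pupil map
  expect_equal(pr$ps_min_left, 2.5, tolerance = 1e-9)
  expect_equal(pr$ps_max_left, 4.5, tolerance = 1e-9)
})

test_that("presets violating the velocity-threshold geometry are rejected", {
  expect_error(
    sample_event_plan("MNL", mnl_preset(jitter_px = 15)),
    class = "gazenav_config_error"
  )
  expect_error(
    sample_event_plan("MNL", mnl_preset(min_step_px = 10)),
    class = "gazenav_config_error"
  )
  expect_error(class_preset(label = "other"), "arg")
  expect_error(mnl_preset(p_short_fix = 1.2), class = "gazenav_config_error")
})
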