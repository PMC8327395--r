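test_that("point velocities follow the backward-difference convention", {
  rec <- make_recording(x = c(0, 0), y = c(0, 0), t = c(0, 16.67))
  v <- point_velocities(rec)
  expect_equal(v$velocity_px_ms, c(0, 0))

  rec <- make_recording(x = c(0, 35), y = c(0, 0), t = c(0, 16.67))
  v <- point_velocities(rec)
  expect_equal(v$velocity_px_ms[2], 35 / 16.67, tolerance = 1e-12)
  expect_equal(v$velocity_px_ms[1], v$velocity_px_ms[2]) # first mirrors second

  expect_error(
    point_velocities(make_recording(x = 1, y = 1)),
    class = "gazenav_insufficient_data_error"
  )
})

test_that("velocity across an invalid sample is a gap", {
  rec <- make_recording(
    x = c(0, 10, 20, 30), y = rep(0, 4),
    valid = c(TRUE, FALSE, TRUE, TRUE)
  )
  v <- point_velocities(rec)
  expect_true(is.na(v$velocity_px_ms[2])) # the invalid sample
  expect_true(is.na(v$velocity_px_ms[3])) # the step across it
  expect_false(is.na(v$velocity_px_ms[4]))
})

test_that("the velocity threshold is strict: at-threshold samples are saccades", {
  # dt = 10 ms steps of 20 / 21 / 22 px give velocities 2.0 / 2.1 / 2.2 px/ms
  rec <- make_recording(
    x = cumsum(c(0, 20, 21, 22)), y = rep(0, 4), t = c(0, 10, 20, 30)
  )
  lab <- label_samples(rec)
  expect_equal(lab[2], "fixation") # 2.0 < 2.1
  expect_equal(lab[3], "saccade") # exactly 2.1
  expect_equal(lab[4], "saccade") # 2.2
})

test_that("minimum fixation duration keeps 100 ms and discards 66.7 ms runs", {
  # 7 fixation samples span 6 * 16.67 = 100 ms >= 90 ms: retained
  n <- 7
  rec <- make_recording(x = rep(100, n), y = rep(100, n))
  ev <- detect_events(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")
  expect_equal(ev$duration_ms, 6 * dt60, tolerance = 1e-9)

  # 5 fixation samples (66.7 ms) flanked by saccade runs: discarded, and the
  # flanking saccades stay separate
  x <- c(0, 50, 100, 150, rep(200, 5), 250, 300, 350, 400)
  rec <- make_recording(x = x, y = rep(0, length(x)))
  ev <- detect_events(rec)
  expect_equal(attr(ev, "discarded_fixations"), 1)
  expect_equal(ev$kind, c("saccade", "saccade"))
})

test_that("an all-fixation second is one event with the mean centroid", {
  set.seed(1)
  n <- 60
  x <- 300 + rnorm(n, 0, 2)
  y <- 400 + rnorm(n, 0, 2)
  rec <- make_recording(x, y)
  ev <- detect_events(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "fixation")
  expect_equal(ev$centroid_x, mean(x))
  expect_equal(ev$centroid_y, mean(y))
})

test_that("short invalid gaps are bridged and long gaps split events", {
  # 2 invalid samples (~33 ms gap) inside a fixation: bridged to one event
  valid <- rep(TRUE, 20); valid[10:11] <- FALSE
  rec <- make_recording(x = rep(100, 20), y = rep(100, 20), valid = valid)
  ev <- detect_events(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_samples, 18) # invalid samples are not members

  # 6 invalid samples (~117 ms > 75 ms): the fixation splits in two
  valid <- rep(TRUE, 26); valid[11:16] <- FALSE
  rec <- make_recording(x = rep(100, 26), y = rep(100, 26), valid = valid)
  ev <- detect_events(rec, ivt_config())
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$kind == "fixation"))
})

test_that("labels must align with samples", {
  rec <- make_recording(x = rep(1, 5), y = rep(1, 5))
  expect_error(
    segment_events(rep("fixation", 4), rec),
    class = "gazenav_contract_error"
  )
})

test_that("segmentation is invariant under translation and velocity under rotation", {
  set.seed(7)
  rec <- random_stream(40, p_invalid = 0)
  ev0 <- detect_events(rec)
  s <- rec$samples
  shifted <- make_recording(s$x_px + 57, s$y_px - 23, t = s$t_ms)
  ev1 <- detect_events(shifted)
  expect_equal(ev1$kind, ev0$kind)
  expect_equal(ev1$duration_ms, ev0$duration_ms)
  expect_equal(ev1$centroid_x, ev0$centroid_x + 57)

  th <- 0.7
  xr <- cos(th) * s$x_px - sin(th) * s$y_px
  yr <- sin(th) * s$x_px + cos(th) * s$y_px
  rot <- make_recording(xr, yr, t = s$t_ms)
  expect_equal(
    point_velocities(rot)$velocity_px_ms,
    point_velocities(rec)$velocity_px_ms,
    tolerance = 1e-9
  )
})

test_that("streams below threshold everywhere yield a single fixation", {
  set.seed(11)
  for (rep_i in 1:5) {
    n <- 30
    steps <- runif(n - 1, 0, 30) # all < 35 px/sample = 2.1 px/ms
    ang <- runif(n - 1, 0, 2 * pi)
    x <- cumsum(c(400, steps * cos(ang)))
    y <- cumsum(c(400, steps * sin(ang)))
    ev <- detect_events(make_recording(x, y))
    expect_equal(nrow(ev), 1)
    expect_equal(ev$kind, "fixation")
  }
})

test_that("segmentation matches the brute-force oracle on random streams", {
  set.seed(42)
  for (rep_i in 1:30) {
    rec <- random_stream(sample(10:50, 1), p_invalid = 0.12)
    got <- detect_events(rec)
    want <- oracle_ivt(rec)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$kind, want$kind)
    expect_equal(got$start_ms, want$start_ms)
    expect_equal(got$end_ms, want$end_ms)
    expect_equal(got$centroid_x, want$centroid_x)
    expect_equal(got$n_samples, want$n_samples)
    expect_equal(
      attr(got, "discarded_fixations"),
      attr(want, "discarded_fixations")
    )
  }
})

test_that("retained events are disjoint and time-ordered", {
  d <- generate_dataset(n_mnl = 3, n_non = 3, seed = 9)
  ev <- detect_events(d$recording)
  expect_true(all(diff(ev$start_ms) > 0))
  expect_true(all(utils::head(ev$end_ms, -1) < utils::tail(ev$start_ms, -1)))
})
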