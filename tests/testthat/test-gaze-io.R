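test_that("gaze logs parse, infer the rate, and report every row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    t_ms = c(0, dt60, 2 * dt60), x_px = c(100, 105, 110), y_px = c(200, 200, 200),
    pupil_left = 3.1, pupil_right = 3.2,
    valid_left = TRUE, valid_right = TRUE
  ), f)
  rec <- read_gaze_table(f)
  expect_s3_class(rec, "gaze_recording")
  expect_equal(nrow(rec$samples), 3)
  expect_equal(rec$rate_hz, 60, tolerance = 1e-6)
  expect_equal(attr(rec$samples, "n_parsed") + attr(rec$samples, "n_rejected"), 3)
})

test_that("non-monotonic timestamps raise a data error naming the row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    t_ms = c(0, -5, 30), x_px = 1, y_px = 1,
    pupil_left = 3, pupil_right = 3, valid_left = TRUE, valid_right = TRUE
  ), f)
  expect_error(read_gaze_table(f), class = "gazenav_data_error")
  expect_error(read_gaze_table(f), "row 2")
})

test_that("off-screen coordinates invalidate the sample with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    t_ms = c(0, dt60), x_px = c(-50, 10), y_px = c(5, 5),
    pupil_left = 3, pupil_right = 3, valid_left = TRUE, valid_right = TRUE
  ), f)
  expect_warning(rec <- read_gaze_table(f), "off-screen")
  expect_equal(nrow(rec$samples), 2) # kept, not dropped
  expect_false(rec$samples$valid_left[1])
  expect_false(rec$samples$valid_right[1])
  expect_true(rec$samples$valid_left[2])
})

test_that("column remapping works and missing columns are config errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    RecTime = c(0, dt60), GX = c(1, 2), y_px = 1,
    pupil_left = 3, pupil_right = 3, valid_left = TRUE, valid_right = TRUE
  ), f)
  rec <- read_gaze_table(f, column_map = c(t_ms = "RecTime", x_px = "GX"))
  expect_equal(rec$samples$x_px, c(1, 2))
  expect_error(
    read_gaze_table(f, column_map = c(t_ms = "NoSuchColumn")),
    class = "gazenav_config_error"
  )
  expect_error(read_gaze_table(f), class = "gazenav_config_error")
})

test_that("annotation reader enforces ordering, labels and non-overlap", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    phase_id = c(2, 1), label = c("non-MNL", "MNL"),
    start_ms = c(5000, 0), end_ms = c(9000, 5000)
  ), f)
  ann <- read_phase_annotations(f)
  expect_equal(ann$phase_id, c(1, 2)) # sorted by start
  expect_s3_class(ann$label, "factor")

  readr::write_csv(tibble::tibble(
    phase_id = 1:2, label = "MNL", start_ms = c(0, 4000), end_ms = c(5000, 9000)
  ), f)
  expect_error(read_phase_annotations(f), class = "gazenav_data_error")

  readr::write_csv(tibble::tibble(
    phase_id = 1, label = "lost", start_ms = 0, end_ms = 10
  ), f)
  expect_error(read_phase_annotations(f), class = "gazenav_data_error")
})

test_that("a study-sized annotation fixture round-trips with its label counts", {
  n_mnl <- 51; n_non <- 77
  starts <- seq(0, by = 10000, length.out = n_mnl + n_non)
  labels <- rep("non-MNL", n_mnl + n_non)
  labels[seq(1, 2 * n_mnl, by = 2)] <- "MNL" # interleaved until MNLs run out
  ann <- tibble::tibble(
    phase_id = seq_along(starts), label = labels,
    start_ms = starts, end_ms = starts + 9000
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_phase_annotations(ann, f)
  back <- read_phase_annotations(f)
  expect_equal(unname(table(back$label)["MNL"]), n_mnl, ignore_attr = TRUE)
  expect_equal(unname(table(back$label)["non-MNL"]), n_non, ignore_attr = TRUE)
})

test_that("feature tables round-trip losslessly and validate their contract", {
  feats <- tibble::tibble(
    phase_id = 1:3,
    label = factor(c("MNL", "non-MNL", "MNL"), levels = c("MNL", "non-MNL")),
    a = c(pi, exp(1), 1 / 3), b = c(1.23456789012345e-7, 2, 3)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, f)
  back <- read_feature_table(f)
  expect_identical(back$a, feats$a) # exact float equality
  expect_identical(back$b, feats$b)
  expect_equal(as.character(back$label), as.character(feats$label))

  expect_warning(
    write_feature_table(feats[0, ], f),
    "header-only"
  )
  expect_error(
    write_feature_table(dplyr::mutate(feats, a = as.character(a)), f),
    class = "gazenav_contract_error"
  )
})

test_that("gaze recordings round-trip through the TSV writer", {
  d <- generate_dataset(n_mnl = 1, n_non = 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_table(d$recording, f)
  back <- read_gaze_table(f, geometry = d$recording$geometry)
  expect_equal(nrow(back$samples), nrow(d$recording$samples))
  expect_equal(back$samples$x_px, d$recording$samples$x_px, tolerance = 1e-12)
})

test_that("screen geometry validates and warns on inconsistent pixel pitch", {
  g <- screen_geometry()
  expect_equal(g$width_mm / g$width_px, g$height_mm / g$height_px)
  expect_warning(screen_geometry(width_mm = 340, height_mm = 300), "pitch")
  expect_error(screen_geometry(width_px = -1), class = "gazenav_config_error")
})
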