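#' Screen geometry of the eye-tracking display
#'
#' Describes the display on which gaze was recorded: resolution in pixels,
#' physical size in millimetres, and the eye-to-screen viewing distance.
#' The geometry is what turns a pixel displacement into a visual angle, so it
#' is required for saccadic amplitudes in degrees. The default is a typical
#' desktop eye-tracking setup: a 1024x768 px panel of 340x255 mm (a 4:3 panel
#' with identical pixel pitch on both axes) viewed from 600 mm.
#'
#' @param width_px,height_px display resolution in pixels.
#' @param width_mm,height_mm physical display size in millimetres.
#' @param view_dist_mm eye-to-screen distance in millimetres.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' geom$width_px
#' @export
screen_geometry <- function(width_px = 1024, height_px = 768,
                            width_mm = 340, height_mm = 255,
                            view_dist_mm = 600) {
  vals <- c(width_px, height_px, width_mm, height_mm, view_dist_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_config("all screen_geometry dimensions must be positive and finite")
  }
  pitch_x <- width_mm / width_px
  pitch_y <- height_mm / height_px
  if (abs(pitch_x - pitch_y) / pitch_x > 0.05) {
    warn(sprintf(
      "pixel pitch differs between axes by %.1f%% (x: %.4f mm/px, y: %.4f mm/px)",
      100 * abs(pitch_x - pitch_y) / pitch_x, pitch_x, pitch_y
    ))
  }
  structure(
    list(
      width_px = width_px, height_px = height_px,
      width_mm = width_mm, height_mm = height_mm,
      view_dist_mm = view_dist_mm
    ),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %d x %d px on %.0f x %.0f mm, viewed from %.0f mm\n",
    x$width_px, x$height_px, x$width_mm, x$height_mm, x$view_dist_mm
  ))
  invisible(x)
}

gaze_sample_cols <- c(
  "t_ms", "x_px", "y_px", "pupil_left", "pupil_right",
  "valid_left", "valid_right"
)

#' Construct a gaze recording from a sample table
#'
#' A gaze recording bundles a 60 Hz (by default) stream of gaze/pupil samples
#' with its nominal sampling rate and the screen geometry. Samples live in a
#' tibble with columns `t_ms`, `x_px`, `y_px`, `pupil_left`, `pupil_right`,
#' `valid_left`, `valid_right`. Timestamps are milliseconds from trial start
#' and must be strictly increasing.
#'
#' @param samples data frame of gaze samples (see above).
#' @param rate_hz nominal sampling rate; inferred from the median inter-sample
#'   gap when `NULL`.
#' @param geometry a [screen_geometry()].
#'
#' @return An object of class `gaze_recording`: a list with elements
#'   `samples` (tibble), `rate_hz`, `geometry`.
#' @export
gaze_recording <- function(samples, rate_hz = NULL, geometry = screen_geometry()) {
  samples <- as_tibble(samples)
  missing_cols <- setdiff(gaze_sample_cols, names(samples))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "gaze samples lack required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(samples) > 0) {
    if (any(!is.finite(samples$t_ms))) stop_data("non-numeric or missing timestamps")
    bad <- which(diff(samples$t_ms) <= 0)
    if (length(bad) > 0) {
      stop_data(sprintf(
        "timestamps must be strictly increasing; first violation at row %d",
        bad[1] + 1L
      ))
    }
    if (samples$t_ms[1] < 0) stop_data("timestamps must be >= 0")
  }
  if (is.null(rate_hz)) {
    rate_hz <- if (nrow(samples) >= 2) {
      1000 / median(diff(samples$t_ms))
    } else {
      60
    }
  }
  if (!is.finite(rate_hz) || rate_hz <= 0) stop_config("rate_hz must be positive")
  structure(
    list(samples = samples, rate_hz = rate_hz, geometry = geometry),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  dur <- if (nrow(x$samples) > 0) diff(range(x$samples$t_ms)) / 1000 else 0
  cat(sprintf(
    "<gaze_recording> %d samples, %.1f s at %.1f Hz, %d x %d px display\n",
    nrow(x$samples), dur, x$rate_hz, x$geometry$width_px, x$geometry$height_px
  ))
  invisible(x)
}

#' Read a gaze sample log
#'
#' Reads a tab-separated gaze log (Tobii-export style) into a
#' [gaze_recording()]. Expected columns are `t_ms`, `x_px`, `y_px`,
#' `pupil_left`, `pupil_right`, `valid_left`, `valid_right`; differently named
#' columns can be remapped through `column_map`. Rows whose gaze coordinates
#' fall outside the screen are kept but have both validity flags forced to
#' `FALSE` (off-screen jitter is expected hardware behaviour, not an error).
#' Rows that fail to parse are dropped, counted, and reported via a warning;
#' the counts are retained in attributes `n_parsed` / `n_rejected` so no row
#' is ever silently lost.
#'
#' @param path path to a TSV gaze log.
#' @param column_map optional named character vector mapping the canonical
#'   names to the file's column names, e.g.
#'   `c(t_ms = "RecTime", x_px = "GazeX")`.
#' @param geometry a [screen_geometry()].
#' @param rate_hz nominal sampling rate; inferred when `NULL`.
#'
#' @return A [gaze_recording()] with attributes `n_parsed` and `n_rejected`
#'   on its `samples` tibble.
#' @export
read_gaze_table <- function(path, column_map = NULL,
                            geometry = screen_geometry(), rate_hz = NULL) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop_config(sprintf("mapped column '%s' (for '%s') not present", src, canon))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(gaze_sample_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop_config(paste0(
      "gaze log lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[gaze_sample_cols]
  n_lines <- nrow(raw)
  num_cols <- c("t_ms", "x_px", "y_px", "pupil_left", "pupil_right")
  for (cc in num_cols) raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  for (cc in c("valid_left", "valid_right")) {
    raw[[cc]] <- as.logical(raw[[cc]])
  }
  ok <- is.finite(raw$t_ms) & !is.na(raw$valid_left) & !is.na(raw$valid_right)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warn(sprintf("%d malformed row(s) rejected while reading %s", n_rejected, path))
  }
  raw <- raw[ok, ]
  # off-screen coordinates invalidate the sample rather than erroring
  off <- !is.na(raw$x_px) & !is.na(raw$y_px) &
    (raw$x_px < 0 | raw$x_px > geometry$width_px |
       raw$y_px < 0 | raw$y_px > geometry$height_px)
  off[is.na(off)] <- FALSE
  no_pos <- is.na(raw$x_px) | is.na(raw$y_px)
  inval <- off | no_pos
  if (any(inval & (raw$valid_left | raw$valid_right))) {
    warn(sprintf(
      "%d sample(s) with off-screen or missing coordinates marked invalid",
      sum(inval & (raw$valid_left | raw$valid_right))
    ))
  }
  raw$valid_left <- raw$valid_left & !inval
  raw$valid_right <- raw$valid_right & !inval
  rec <- gaze_recording(raw, rate_hz = rate_hz, geometry = geometry)
  attr(rec$samples, "n_parsed") <- n_lines - n_rejected
  attr(rec$samples, "n_rejected") <- n_rejected
  rec
}

#' Write a gaze recording to a TSV log
#'
#' @param recording a [gaze_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  readr::write_tsv(recording$samples, path, progress = FALSE)
  invisible(path)
}

phase_labels <- c("MNL", "non-MNL")

#' Read phase annotations
#'
#' Phase annotations label the trial timeline as alternating MNL (moment of
#' navigation loss) and non-MNL intervals, as judged from the scope video.
#' Stored as CSV with columns `phase_id,label,start_ms,end_ms`; intervals are
#' half-open `[start_ms, end_ms)` and must not overlap.
#'
#' @param path path to the annotation CSV.
#' @return A tibble with columns `phase_id`, `label` (factor MNL/non-MNL),
#'   `start_ms`, `end_ms`, sorted by `start_ms`.
#' @export
read_phase_annotations <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  ann <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("phase_id", "label", "start_ms", "end_ms")
  if (!all(req %in% names(ann))) {
    stop_config(paste0("annotation file needs columns: ", paste(req, collapse = ", ")))
  }
  validate_annotations(ann[req])
}

validate_annotations <- function(ann) {
  ann <- as_tibble(ann)
  bad_label <- setdiff(unique(as.character(ann$label)), phase_labels)
  if (length(bad_label) > 0) {
    stop_data(paste0("unknown phase label(s): ", paste(bad_label, collapse = ", ")))
  }
  if (any(!is.finite(ann$start_ms)) || any(!is.finite(ann$end_ms))) {
    stop_data("annotation bounds must be numeric")
  }
  if (any(ann$start_ms >= ann$end_ms)) {
    stop_data("each annotation needs start_ms < end_ms")
  }
  ann <- arrange(ann, .data$start_ms)
  if (nrow(ann) > 1) {
    overlap <- which(head(ann$end_ms, -1) > tail(ann$start_ms, -1))
    if (length(overlap) > 0) {
      stop_data(sprintf(
        "overlapping annotations: phase %s [%g, %g) and phase %s [%g, %g)",
        ann$phase_id[overlap[1]], ann$start_ms[overlap[1]], ann$end_ms[overlap[1]],
        ann$phase_id[overlap[1] + 1], ann$start_ms[overlap[1] + 1], ann$end_ms[overlap[1] + 1]
      ))
    }
  }
  ann$label <- factor(as.character(ann$label), levels = phase_labels)
  ann
}

#' Write phase annotations
#'
#' @param annotations tibble with `phase_id,label,start_ms,end_ms`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_annotations <- function(annotations, path) {
  annotations <- validate_annotations(annotations)
  out <- mutate(annotations, label = as.character(.data$label))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a per-phase feature table
#'
#' Feature tables are plain CSV: `phase_id`, `label`, then one column per
#' feature. All rows must share one feature set. Values round-trip losslessly
#' (shortest round-trip float representation).
#'
#' @param features tibble with columns `phase_id`, `label` and numeric
#'   feature columns.
#' @param path CSV path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_feature_table <- function(features, path) {
  features <- as_tibble(features)
  if (!all(c("phase_id", "label") %in% names(features))) {
    stop_contract("feature table needs 'phase_id' and 'label' columns")
  }
  feat_cols <- setdiff(names(features), c("phase_id", "label", "origin"))
  if (!all(vapply(features[feat_cols], is.numeric, logical(1)))) {
    stop_contract("all feature columns must be numeric")
  }
  if (nrow(features) == 0) {
    warn("writing a header-only feature table (no rows)")
  }
  out <- mutate(features, label = as.character(.data$label))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("phase_id", "label") %in% names(x))) {
    stop_contract("feature table needs 'phase_id' and 'label' columns")
  }
  x$label <- factor(as.character(x$label), levels = phase_labels)
  x
}
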