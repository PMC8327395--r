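#' I-VT filter configuration
#'
#' Parameters of the velocity-threshold identification (I-VT) filter: a sample
#' whose point-to-point velocity is strictly below `velocity_threshold` is a
#' fixation sample, otherwise a saccade sample. Fixation events shorter than
#' `min_fixation_ms` are discarded from analysis (their flanking saccades are
#' kept separate, not merged). Runs of invalid samples no longer than
#' `max_gap_ms` inside an event are bridged; longer gaps split the event.
#'
#' @param velocity_threshold velocity threshold in px/ms (default 2.1).
#' @param min_fixation_ms minimum fixation duration in ms (default 90).
#' @param max_gap_ms longest invalid gap bridged inside one event (default 75).
#'
#' @return An object of class `ivt_config`.
#' @export
ivt_config <- function(velocity_threshold = 2.1, min_fixation_ms = 90,
                       max_gap_ms = 75) {
  if (any(c(velocity_threshold, min_fixation_ms, max_gap_ms) <= 0)) {
    stop_config("all ivt_config parameters must be positive")
  }
  structure(
    list(
      velocity_threshold = velocity_threshold,
      min_fixation_ms = min_fixation_ms,
      max_gap_ms = max_gap_ms
    ),
    class = "ivt_config"
  )
}

sample_valid <- function(samples) {
  (samples$valid_left | samples$valid_right) &
    is.finite(samples$x_px) & is.finite(samples$y_px)
}

#' Per-sample point-to-point gaze velocities
#'
#' Velocity at sample *i* is the Euclidean distance from sample *i-1* divided
#' by the time difference (px/ms), i.e. a two-point backward difference with
#' no smoothing. The first sample inherits the second sample's velocity.
#' Velocity across an invalid sample is undefined: both the invalid sample and
#' the first valid sample after it get `NA`.
#'
#' @param recording a [gaze_recording()].
#' @return A tibble with columns `t_ms`, `velocity_px_ms`, `valid`.
#' @export
point_velocities <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  valid <- sample_valid(s)
  if (sum(valid) < 2) {
    stop_insufficient("point velocities need at least 2 valid samples")
  }
  n <- nrow(s)
  v <- rep(NA_real_, n)
  dx <- diff(s$x_px)
  dy <- diff(s$y_px)
  dt <- diff(s$t_ms)
  step_v <- sqrt(dx^2 + dy^2) / dt
  # velocity defined only when both endpoints of the step are valid
  ok <- valid[-n] & valid[-1]
  v[-1][ok] <- step_v[ok]
  # backward-difference convention: the stream's first sample mirrors the
  # second (gaps later in the stream stay undefined)
  if (is.na(v[1]) && !is.na(v[2]) && valid[1]) v[1] <- v[2]
  tibble(t_ms = s$t_ms, velocity_px_ms = v, valid = valid)
}

#' Label samples as fixation, saccade or invalid
#'
#' Applies the I-VT rule: velocity strictly below the threshold means
#' fixation, at or above it means saccade. Invalid samples (both eyes
#' flagged invalid, or no usable position) are labelled `invalid`; a valid
#' sample whose velocity is undefined (first valid sample after a gap) takes
#' the label implied by its following step when available, else `invalid`.
#'
#' @param recording a [gaze_recording()].
#' @param cfg an [ivt_config()].
#' @return Character vector of labels, one per sample:
#'   `"fixation"`, `"saccade"` or `"invalid"`.
#' @export
label_samples <- function(recording, cfg = ivt_config()) {
  vel <- point_velocities(recording)
  lab <- rep("invalid", nrow(vel))
  defined <- !is.na(vel$velocity_px_ms)
  lab[defined & vel$velocity_px_ms < cfg$velocity_threshold] <- "fixation"
  lab[defined & vel$velocity_px_ms >= cfg$velocity_threshold] <- "saccade"
  # a valid sample just after a bridged gap: adopt the next defined label so
  # that gap bridging does not chop one sample off the resumed event
  undef_valid <- which(vel$valid & !defined)
  if (length(undef_valid) > 0) {
    nxt <- findInterval(undef_valid, which(defined)) + 1L
    def_idx <- which(defined)
    for (i in undef_valid) {
      after <- def_idx[def_idx > i]
      if (length(after) > 0) lab[i] <- lab[after[1]]
    }
  }
  lab
}

#' Segment labelled samples into fixation and saccade events
#'
#' Maximal runs of same-labelled samples become events. Runs of invalid
#' samples no longer than `max_gap_ms` flanked by the same label are bridged
#' (the invalid samples contribute to neither centroid nor path); longer gaps
#' split events. Fixation events with duration below `min_fixation_ms` are
#' then removed and counted — their neighbouring saccades remain separate
#' events. Event duration is last minus first member-sample timestamp;
#' fixation centroids are the arithmetic mean of member positions.
#'
#' @param labels per-sample labels from [label_samples()].
#' @param recording the [gaze_recording()] the labels belong to.
#' @param cfg an [ivt_config()].
#' @return A tibble of events (class `gaze_events`) with columns `kind`,
#'   `start_ms`, `end_ms`, `duration_ms`, `centroid_x`, `centroid_y`,
#'   `start_x`, `start_y`, `end_x`, `end_y`, `path_px`, `n_samples`, and an
#'   attribute `discarded_fixations`.
#' @export
segment_events <- function(labels, recording, cfg = ivt_config()) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  if (length(labels) != nrow(s)) {
    stop_contract("labels must align 1:1 with recording samples")
  }
  eff <- labels
  # bridge short invalid gaps with identical labels on both sides
  r <- rle(eff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr >= 3) {
    for (k in seq(2, nr - 1)) {
      if (r$values[k] == "invalid" && r$values[k - 1] == r$values[k + 1] &&
          r$values[k - 1] != "invalid") {
        gap_ms <- s$t_ms[ends[k] + 1L] - s$t_ms[starts[k] - 1L]
        if (gap_ms <= cfg$max_gap_ms) {
          eff[starts[k]:ends[k]] <- paste0("bridged_", r$values[k - 1])
        }
      }
    }
  }
  core <- sub("^bridged_", "", eff)
  r2 <- rle(core)
  run_id <- rep(seq_along(r2$lengths), r2$lengths)
  # member samples contribute position; bridged invalid samples do not
  member <- eff %in% c("fixation", "saccade") & core != "invalid"
  idx <- which(member)
  if (length(idx) == 0) {
    ev <- tibble(
      kind = character(), start_ms = double(), end_ms = double(),
      centroid_x = double(), centroid_y = double(),
      start_x = double(), start_y = double(),
      end_x = double(), end_y = double(),
      path_px = double(), n_samples = integer()
    )
  } else {
    g <- run_id[idx]
    firsts <- idx[!duplicated(g)]
    lasts <- idx[!duplicated(g, fromLast = TRUE)]
    counts <- as.integer(tabulate(g)[unique(g)])
    xs <- s$x_px[idx]
    ys <- s$y_px[idx]
    cx <- as.numeric(rowsum(xs, g)) / counts
    cy <- as.numeric(rowsum(ys, g)) / counts
    same <- diff(g) == 0
    dseg <- sqrt(diff(xs)^2 + diff(ys)^2)
    path <- as.numeric(rowsum(c(dseg * same, 0), g))
    ev <- tibble(
      kind = r2$values[unique(g)],
      start_ms = s$t_ms[firsts],
      end_ms = s$t_ms[lasts],
      centroid_x = cx, centroid_y = cy,
      start_x = s$x_px[firsts], start_y = s$y_px[firsts],
      end_x = s$x_px[lasts], end_y = s$y_px[lasts],
      path_px = path,
      n_samples = counts
    )
  }
  ev <- mutate(ev, duration_ms = .data$end_ms - .data$start_ms, .after = "end_ms")
  short_fix <- ev$kind == "fixation" & ev$duration_ms < cfg$min_fixation_ms
  discarded <- sum(short_fix)
  ev <- ev[!short_fix, ]
  attr(ev, "discarded_fixations") <- discarded
  class(ev) <- c("gaze_events", class(ev))
  ev
}

#' Detect gaze events with the I-VT filter
#'
#' Convenience wrapper: [point_velocities()] + [label_samples()] +
#' [segment_events()].
#'
#' @inheritParams label_samples
#' @return See [segment_events()].
#' @examples
#' rec <- generate_dataset(n_mnl = 1, n_non = 1, seed = 1)$recording
#' ev <- detect_events(rec)
#' table(ev$kind)
#' @export
detect_events <- function(recording, cfg = ivt_config()) {
  segment_events(label_samples(recording, cfg), recording, cfg)
}
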