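# Shared fixtures and independent oracles. The oracles deliberately use
# plain loops and re-derive everything from first principles so they stay
# independent of the vectorized implementation they check.

dt60 <- 1000 / 60

# build a gaze recording from coordinate vectors at a fixed rate
make_recording <- function(x, y, t = NULL, pupil = NULL, valid = NULL,
                           rate_hz = 60, geometry = screen_geometry()) {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) * 1000 / rate_hz
  if (is.null(pupil)) pupil <- rep(3.5, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  gaze_recording(
    tibble::tibble(
      t_ms = t, x_px = x, y_px = y,
      pupil_left = pupil, pupil_right = pupil,
      valid_left = valid, valid_right = valid
    ),
    rate_hz = rate_hz, geometry = geometry
  )
}

# brute-force I-VT reference: explicit per-sample loops, no vectorization
oracle_ivt <- function(recording, cfg = ivt_config()) {
  s <- recording$samples
  n <- nrow(s)
  valid <- (s$valid_left | s$valid_right) & is.finite(s$x_px) & is.finite(s$y_px)
  vel <- rep(NA_real_, n)
  for (i in 2:n) {
    if (valid[i] && valid[i - 1]) {
      vel[i] <- sqrt((s$x_px[i] - s$x_px[i - 1])^2 + (s$y_px[i] - s$y_px[i - 1])^2) /
        (s$t_ms[i] - s$t_ms[i - 1])
    }
  }
  if (is.na(vel[1]) && !is.na(vel[2]) && valid[1]) vel[1] <- vel[2]
  lab <- rep("invalid", n)
  for (i in seq_len(n)) {
    if (!is.na(vel[i])) {
      lab[i] <- if (vel[i] < cfg$velocity_threshold) "fixation" else "saccade"
    }
  }
  # valid samples with undefined velocity adopt the next defined label
  for (i in seq_len(n)) {
    if (valid[i] && is.na(vel[i])) {
      j <- i + 1
      while (j <= n && is.na(vel[j])) j <- j + 1
      if (j <= n) lab[i] <- lab[j]
    }
  }
  # gap bridging
  eff <- lab
  i <- 1
  while (i <= n) {
    if (eff[i] == "invalid") {
      j <- i
      while (j < n && eff[j + 1] == "invalid") j <- j + 1
      if (i > 1 && j < n && lab[i - 1] == lab[j + 1] && lab[i - 1] != "invalid" &&
          (s$t_ms[j + 1] - s$t_ms[i - 1]) <= cfg$max_gap_ms) {
        eff[i:j] <- paste0("gap_", lab[i - 1])
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  core <- sub("^gap_", "", eff)
  events <- list()
  i <- 1
  while (i <= n) {
    if (core[i] == "invalid") { i <- i + 1; next }
    j <- i
    while (j < n && core[j + 1] == core[i]) j <- j + 1
    member <- (i:j)[eff[i:j] %in% c("fixation", "saccade")]
    if (length(member) > 0) {
      events[[length(events) + 1]] <- list(
        kind = core[i],
        start_ms = s$t_ms[member[1]],
        end_ms = s$t_ms[member[length(member)]],
        centroid_x = mean(s$x_px[member]),
        centroid_y = mean(s$y_px[member]),
        n_samples = length(member)
      )
    }
    i <- j + 1
  }
  ev <- dplyr::bind_rows(lapply(events, tibble::as_tibble))
  if (nrow(ev) > 0) {
    ev$duration_ms <- ev$end_ms - ev$start_ms
    drop <- ev$kind == "fixation" & ev$duration_ms < cfg$min_fixation_ms
    discarded <- sum(drop)
    ev <- ev[!drop, ]
  } else {
    discarded <- 0L
  }
  attr(ev, "discarded_fixations") <- discarded
  ev
}

# random mixed-label streams for the oracle-equivalence property
random_stream <- function(n, p_invalid = 0.1) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- 500; y[1] <- 380
  for (i in 2:n) {
    step <- if (stats::runif(1) < 0.4) stats::runif(1, 36, 80) else stats::runif(1, 0, 20)
    ang <- stats::runif(1, 0, 2 * pi)
    x[i] <- min(max(x[i - 1] + step * cos(ang), 1), 1023)
    y[i] <- min(max(y[i - 1] + step * sin(ang), 1), 767)
  }
  valid <- stats::runif(n) > p_invalid
  valid[1:2] <- TRUE
  make_recording(x, y, valid = valid)
}

# tiny labelled feature sets for classifier tests
toy_features <- function(n_per_class, sep = 3, seed = 1, p = 4) {
  set.seed(seed)
  mk <- function(lab, mu) {
    m <- matrix(stats::rnorm(n_per_class * p, mu, 1), n_per_class)
    colnames(m) <- sprintf("f%d", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(
        phase_id = sprintf("%s_%d", lab, seq_len(n_per_class)),
        label = factor(lab, levels = c("MNL", "non-MNL"))
      ),
      tibble::as_tibble(m)
    )
  }
  dplyr::bind_rows(mk("MNL", 0), mk("non-MNL", sep))
}
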