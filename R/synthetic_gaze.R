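#' Distribution preset for one phase class
#'
#' Describes the latent event statistics from which synthetic gaze streams of
#' one class (MNL or non-MNL) are generated: lognormal phase / fixation /
#' saccade durations, gamma saccadic amplitudes, the fraction of sub-90 ms
#' fixations (which the I-VT minimum-duration filter later discards, producing
#' the roughly 2:1 saccade:fixation count ratio), the adjusted-pupil-size
#' process (phase-level mean, between-phase and within-phase SD, AR(1)
#' smoothness), within-fixation positional jitter, and the angular noise of
#' return saccades. Saccades that follow a discarded short fixation reverse
#' the previous saccade's direction (a glance-and-return pattern); this is
#' what lets inter-fixation distances be stochastically smaller than the
#' chained saccadic amplitudes, as observed in real scanning behaviour.
#'
#' Defaults for the two classes are frozen in [mnl_preset()] and
#' [non_mnl_preset()], calibrated (scripts/calibrate_presets.R) so that the
#' full detection + feature pipeline reproduces the reference per-phase group
#' statistics.
#'
#' @param label `"MNL"` or `"non-MNL"`.
#' @param phase_duration_mean_s,phase_duration_sd_s lognormal phase duration.
#' @param fix_duration_mean_s,fix_duration_sd_s lognormal duration of
#'   retained (long) fixations, seconds; draws are clamped to at least
#'   `fix_min_s`.
#' @param fix_min_s shortest long-fixation duration (must exceed the 90 ms
#'   I-VT minimum after sampling-rate quantization).
#' @param p_short_fix fraction of fixations drawn short (< 90 ms).
#' @param short_fix_samples integer range (2 values) of sample counts for
#'   short fixations.
#' @param sacc_duration_mean_s,sacc_duration_sd_s lognormal saccade duration.
#' @param sacamp_mean_deg,sacamp_shape gamma saccadic amplitude (degrees).
#' @param return_angle_sd SD (radians) of the angular noise on return
#'   saccades.
#' @param return_amp_sd lognormal SD of the return-saccade amplitude relative
#'   to the outgoing saccade (0 = exact return to the previous fixation).
#' @param aps_mean,aps_between_sd phase-level adjusted-pupil-size mean and
#'   between-phase SD (percent).
#' @param aps_within_sd,aps_ar1 within-phase APS noise SD (percent) and AR(1)
#'   coefficient at 60 Hz.
#' @param eye_noise_sd independent per-eye APS noise SD (percent).
#' @param jitter_px within-fixation positional jitter SD (px); must be small
#'   enough that intra-fixation velocities stay below the I-VT threshold.
#' @param min_step_px smallest inter-sample step during a saccade (px); must
#'   map to a velocity at or above the I-VT threshold at the sampling rate.
#'
#' @return An object of class `class_preset`.
#' @export
class_preset <- function(label,
                         phase_duration_mean_s, phase_duration_sd_s,
                         fix_duration_mean_s, fix_duration_sd_s,
                         fix_min_s = 0.125,
                         p_short_fix,
                         short_fix_samples = c(2L, 5L),
                         sacc_duration_mean_s, sacc_duration_sd_s,
                         sacamp_mean_deg, sacamp_shape,
                         return_angle_sd, return_amp_sd = 0.25,
                         aps_mean, aps_between_sd,
                         aps_within_sd = 5.8, aps_ar1 = 0.97,
                         eye_noise_sd = 0.8,
                         jitter_px = 3,
                         min_step_px = 36) {
  label <- match.arg(label, phase_labels)
  p <- structure(as.list(environment()), class = "class_preset")
  means <- c(
    p$phase_duration_mean_s, p$fix_duration_mean_s, p$sacc_duration_mean_s,
    p$sacamp_mean_deg, p$aps_within_sd
  )
  if (any(!is.finite(means)) || any(means <= 0)) {
    stop_config("all class_preset means must be positive")
  }
  if (p$p_short_fix < 0 || p$p_short_fix >= 1) {
    stop_config("p_short_fix must lie in [0, 1)")
  }
  p
}

#' @export
print.class_preset <- function(x, ...) {
  cat(sprintf(
    "<class_preset> %s: phase %.2f s, SacAmp %.2f deg, APS %.1f%%\n",
    x$label, x$phase_duration_mean_s, x$sacamp_mean_deg, x$aps_mean
  ))
  invisible(x)
}

#' Default presets for the two phase classes
#'
#' Calibrated generator parameters for MNL and non-MNL phases. Phase-level
#' means and between-phase SDs come from the reference group statistics
#' (SD = SE * sqrt(n) with n = 51 MNL / 77 non-MNL phases); event-level
#' duration and amplitude marginals were then tuned by iterative search
#' (scripts/calibrate_presets.R) so that the *detected* statistics — after
#' 60 Hz rendering, I-VT filtering and the 90 ms minimum-duration rule —
#' recover the reference table cells.
#'
#' @param ... overrides passed to [class_preset()].
#' @return A `class_preset`.
#' @export
mnl_preset <- function(...) {
  defaults <- list(
    label = "MNL",
    phase_duration_mean_s = 12.35, phase_duration_sd_s = 10.36,
    fix_duration_mean_s = 0.3069, fix_duration_sd_s = 0.12,
    p_short_fix = 0.545,
    sacc_duration_mean_s = 0.105, sacc_duration_sd_s = 0.03,
    sacamp_mean_deg = 2.96, sacamp_shape = 1.5,
    return_angle_sd = 0.2, return_amp_sd = 0.3514,
    aps_mean = 46.96, aps_between_sd = 11.0
  )
  do.call(class_preset, utils::modifyList(defaults, list(...)))
}

#' @rdname mnl_preset
#' @export
non_mnl_preset <- function(...) {
  defaults <- list(
    label = "non-MNL",
    phase_duration_mean_s = 22.80, phase_duration_sd_s = 17.64,
    fix_duration_mean_s = 0.2903, fix_duration_sd_s = 0.11,
    p_short_fix = 0.595,
    sacc_duration_mean_s = 0.095, sacc_duration_sd_s = 0.03,
    sacamp_mean_deg = 1.50, sacamp_shape = 1.5,
    return_angle_sd = 0.45, return_amp_sd = 0.8,
    aps_mean = 64.38, aps_between_sd = 12.55
  )
  do.call(class_preset, utils::modifyList(defaults, list(...)))
}

lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  p <- lnorm_pars(mean, sd)
  rlnorm(n, p$meanlog, p$sdlog)
}

# choose a landing point preserving the drawn amplitude: resample the
# direction until the landing stays in bounds, falling back to aiming at the
# screen centre (amplitude capped at the centre distance only as a last
# resort)
plan_landing <- function(pos, amp_px, geometry, margin = 30,
                         prev_angle = NA, return_sacc = FALSE,
                         return_angle_sd = 0.35) {
  lo <- c(margin, margin)
  hi <- c(geometry$width_px - margin, geometry$height_px - margin)
  in_bounds <- function(p) all(p >= lo) && all(p <= hi)
  if (return_sacc && is.finite(prev_angle)) {
    ang <- prev_angle + pi + rnorm(1, 0, return_angle_sd)
    land <- pos + amp_px * c(cos(ang), sin(ang))
    if (in_bounds(land)) return(list(landing = land, angle = ang))
  }
  for (k in seq_len(32)) {
    ang <- runif(1, 0, 2 * pi)
    land <- pos + amp_px * c(cos(ang), sin(ang))
    if (in_bounds(land)) return(list(landing = land, angle = ang))
  }
  ctr <- c(geometry$width_px, geometry$height_px) / 2
  u <- ctr - pos
  d <- sqrt(sum(u^2))
  u <- if (d > 0) u / d else c(1, 0)
  amp_px <- min(amp_px, max(d, 1))
  list(landing = pos + amp_px * u, angle = atan2(u[2], u[1]))
}

#' Draw the latent event plan for one phase
#'
#' Samples the hidden ground truth of one phase: alternating saccade/fixation
#' events (the phase starts with a saccade and ends with a fixation, so
#' consecutive phases never merge events across the boundary) until the drawn
#' phase duration is filled, plus the phase's target adjusted-pupil-size
#' level. Saccade landing points displace the current position by the drawn
#' amplitude in a uniform random direction (return saccades reverse the
#' previous direction); short fixations are drawn with the preset's
#' probability and marked for later discarding by the minimum-duration rule.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param label phase class, `"MNL"` or `"non-MNL"`.
#' @param preset a [class_preset()] (defaults to the class default).
#' @param geometry a [screen_geometry()].
#' @param rate_hz sampling rate.
#' @param start_xy gaze position at phase onset (px).
#' @return A list of class `event_plan`: `label`, `events` (tibble with
#'   `kind`, `n_samples`, `amp_deg`, `x`, `y` — the fixation centroid or
#'   saccade landing point), `aps_level`, `n_samples`.
#' @export
sample_event_plan <- function(label, preset = NULL,
                              geometry = screen_geometry(), rate_hz = 60,
                              start_xy = c(512, 384)) {
  label <- match.arg(label, phase_labels)
  if (is.null(preset)) {
    preset <- if (label == "MNL") mnl_preset() else non_mnl_preset()
  }
  dt_ms <- 1000 / rate_hz
  # within-fixation jitter must keep intra-fixation velocities sub-threshold
  if (6 * preset$jitter_px / dt_ms >= 2.1) {
    stop_config("jitter_px too large: within-fixation velocity would cross the I-VT threshold")
  }
  if (preset$min_step_px / dt_ms < 2.1) {
    stop_config("min_step_px too small: saccade samples would fall below the I-VT threshold")
  }
  phase_dur_s <- max(rlnorm_ms(1, preset$phase_duration_mean_s, preset$phase_duration_sd_s), 3)
  target_n <- round(phase_dur_s * rate_hz)
  pos <- start_xy
  prev_angle <- NA_real_
  prev_amp_px <- NA_real_
  prev_fix_short <- FALSE
  kind <- character(0); n_samp <- integer(0)
  amp <- double(0); xs <- double(0); ys <- double(0)
  total <- 0L
  while (total < target_n) {
    # saccade; a saccade following a discarded short fixation is a return
    # saccade: direction reversed and amplitude tied to the outgoing one
    d_s <- max(rlnorm_ms(1, preset$sacc_duration_mean_s, preset$sacc_duration_sd_s),
               2 / rate_hz)
    n_sac <- max(2L, 2L * round(d_s * rate_hz / 2))
    is_return <- prev_fix_short && is.finite(prev_amp_px)
    if (is_return) {
      a_px <- prev_amp_px *
        exp(rnorm(1, 0, preset$return_amp_sd) - preset$return_amp_sd^2 / 2)
      a_px <- min(a_px, 380)
      a_deg <- px_to_deg(a_px, geometry)
    } else {
      a_deg <- rgamma(1, shape = preset$sacamp_shape,
                      scale = preset$sacamp_mean_deg / preset$sacamp_shape)
      a_px <- min(deg_to_px(a_deg, geometry), 380)
    }
    ld <- plan_landing(pos, a_px, geometry,
                       prev_angle = prev_angle, return_sacc = is_return,
                       return_angle_sd = preset$return_angle_sd)
    kind <- c(kind, "saccade"); n_samp <- c(n_samp, n_sac)
    amp <- c(amp, a_deg); xs <- c(xs, ld$landing[1]); ys <- c(ys, ld$landing[2])
    pos <- ld$landing; prev_angle <- ld$angle; prev_amp_px <- a_px
    total <- total + n_sac
    # fixation at the landing point
    prev_fix_short <- runif(1) < preset$p_short_fix
    n_fix <- if (prev_fix_short) {
      sample(preset$short_fix_samples[1]:preset$short_fix_samples[2], 1)
    } else {
      d_f <- max(rlnorm_ms(1, preset$fix_duration_mean_s, preset$fix_duration_sd_s),
                 preset$fix_min_s)
      max(round(d_f * rate_hz), ceiling(preset$fix_min_s * rate_hz))
    }
    kind <- c(kind, "fixation"); n_samp <- c(n_samp, n_fix)
    amp <- c(amp, NA_real_); xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
    total <- total + n_fix
  }
  aps_level <- min(max(rnorm(1, preset$aps_mean, preset$aps_between_sd), 5), 95)
  structure(
    list(
      label = label,
      events = tibble(kind = kind, n_samples = n_samp, amp_deg = amp, x = xs, y = ys),
      aps_level = aps_level,
      n_samples = total,
      preset = preset
    ),
    class = "event_plan"
  )
}

# zigzag saccade path from `from` to `to` over n samples: every inter-sample
# step has length max(min_step, D/n) so the I-VT filter sees saccade
# velocities throughout, while the net displacement stays exactly `to - from`
saccade_path <- function(from, to, n, min_step, geometry) {
  d <- to - from
  dist <- sqrt(sum(d^2))
  along <- dist / n
  step <- max(min_step, along)
  h <- sqrt(max(step^2 - along^2, 0))
  u <- if (dist > 0) d / dist else c(1, 0)
  perp <- c(-u[2], u[1])
  # offset alternates 0,h,0,...,0 (n even by construction)
  offs <- rep(c(h, 0), length.out = n)
  ctr <- c(geometry$width_px, geometry$height_px) / 2
  mid <- (from + to) / 2
  if (sum((mid + h * perp - ctr)^2) > sum((mid - h * perp - ctr)^2)) perp <- -perp
  k <- seq_len(n)
  px <- from[1] + k / n * d[1] + offs * perp[1]
  py <- from[2] + k / n * d[2] + offs * perp[2]
  px[n] <- to[1]; py[n] <- to[2]
  cbind(
    pmin(pmax(px, 1), geometry$width_px - 1),
    pmin(pmax(py, 1), geometry$height_px - 1)
  )
}

#' Render an event plan into 60 Hz gaze samples
#'
#' Turns the latent plan into a raw sample stream: within fixations the
#' position is the centroid plus sub-threshold jitter; within saccades the
#' position follows a constant-speed (zigzag when needed) path whose every
#' inter-sample displacement meets the velocity threshold; pupil values are
#' built in APS space (phase level + smooth AR(1) noise + independent per-eye
#' noise, clamped to \[0, 100\]) and mapped to an arbitrary diameter scale —
#' the min-max normalization cancels the units.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param plan an `event_plan` from [sample_event_plan()].
#' @param geometry a [screen_geometry()].
#' @param rate_hz sampling rate.
#' @param start_xy gaze position just before the phase (px).
#' @return A list: `samples` (tibble of gaze samples without timestamps —
#'   the caller assigns the global 60 Hz clock), `truth` (per-event tibble
#'   with planned kind/duration/amplitude), `end_xy`.
#' @export
render_gaze <- function(plan, geometry = screen_geometry(), rate_hz = 60,
                        start_xy = c(512, 384)) {
  stopifnot(inherits(plan, "event_plan"))
  ev <- plan$events
  n_total <- sum(ev$n_samples)
  if (nrow(ev) == 0) {
    return(list(
      samples = empty_samples(), truth = ev, end_xy = start_xy
    ))
  }
  preset <- plan$preset
  x <- double(n_total); y <- double(n_total)
  pos <- start_xy
  at <- 0L
  for (i in seq_len(nrow(ev))) {
    n <- ev$n_samples[i]
    tgt <- c(ev$x[i], ev$y[i])
    if (ev$kind[i] == "saccade") {
      p <- saccade_path(pos, tgt, n, preset$min_step_px, geometry)
      x[at + seq_len(n)] <- p[, 1]
      y[at + seq_len(n)] <- p[, 2]
    } else {
      x[at + seq_len(n)] <- pmin(pmax(tgt[1] + rnorm(n, 0, preset$jitter_px), 1),
                                 geometry$width_px - 1)
      y[at + seq_len(n)] <- pmin(pmax(tgt[2] + rnorm(n, 0, preset$jitter_px), 1),
                                 geometry$height_px - 1)
    }
    pos <- tgt
    at <- at + n
  }
  # APS process: phase level + AR(1) within-phase noise, then per-eye noise
  rho <- preset$aps_ar1
  innov_sd <- preset$aps_within_sd * sqrt(1 - rho^2)
  e <- double(n_total)
  e[1] <- rnorm(1, 0, preset$aps_within_sd)
  if (n_total > 1) {
    eps <- rnorm(n_total - 1, 0, innov_sd)
    for (k in 2:n_total) e[k] <- rho * e[k - 1] + eps[k - 1]
  }
  aps <- plan$aps_level + e
  aps_l <- pmin(pmax(aps + rnorm(n_total, 0, preset$eye_noise_sd), 0), 100)
  aps_r <- pmin(pmax(aps + rnorm(n_total, 0, preset$eye_noise_sd), 0), 100)
  samples <- tibble(
    x_px = x, y_px = y,
    pupil_left = aps_to_pupil(aps_l),
    pupil_right = aps_to_pupil(aps_r),
    valid_left = TRUE, valid_right = TRUE
  )
  truth <- mutate(ev, duration_s = .data$n_samples / rate_hz)
  list(samples = samples, truth = truth, end_xy = pos)
}

# fixed affine APS -> pupil-diameter map (arbitrary mm-like scale); the trial
# pre-roll touches APS 0 and 100 so min-max normalization inverts it exactly
aps_to_pupil <- function(aps) 2.5 + aps / 100 * 2.0

empty_samples <- function() {
  tibble(
    x_px = double(), y_px = double(),
    pupil_left = double(), pupil_right = double(),
    valid_left = logical(), valid_right = logical()
  )
}

#' Generate a complete synthetic labelled recording
#'
#' Produces one continuous 60 Hz recording of `n_mnl` MNL and `n_non` non-MNL
#' phases (interleaved evenly), with exact phase annotations and the latent
#' ground-truth event list. A 2-second pre-roll fixation at screen centre
#' sweeps the adjusted pupil size from 0 to 100%, so the trial-wide pupil
#' extrema that anchor the min-max normalization exist by construction.
#' Deterministic for a fixed seed.
#'
#' @param n_mnl,n_non phase counts per class (>= 1).
#' @param preset_mnl,preset_non [class_preset()]s for the two classes.
#' @param seed integer seed.
#' @param geometry a [screen_geometry()].
#' @param rate_hz sampling rate (default 60).
#' @return A list of class `synthetic_gaze_set`: `recording`
#'   (a [gaze_recording()]), `annotations` (tibble), `truth` (tibble of
#'   latent events with `phase_id`).
#' @examples
#' d <- generate_dataset(n_mnl = 2, n_non = 3, seed = 42)
#' table(d$annotations$label)
#' @export
generate_dataset <- function(n_mnl, n_non,
                             preset_mnl = mnl_preset(), preset_non = non_mnl_preset(),
                             seed = 1, geometry = screen_geometry(), rate_hz = 60) {
  if (n_mnl < 1 || n_non < 1) stop_config("need at least one phase per class")
  set.seed(as.integer(seed %% 2147483647))
  dt_ms <- 1000 / rate_hz
  # even interleave of the two classes
  n_tot <- n_mnl + n_non
  mnl_pos <- unique(round(seq(1, n_tot, length.out = n_mnl)))
  while (length(mnl_pos) < n_mnl) {
    mnl_pos <- sort(union(mnl_pos, setdiff(seq_len(n_tot), mnl_pos)[1]))
  }
  labels <- rep("non-MNL", n_tot)
  labels[mnl_pos] <- "MNL"

  # pre-roll: centre fixation whose APS ramps 0 -> 100, anchoring Eq-style
  # min-max normalization
  n_pre <- round(2 * rate_hz)
  ctr <- c(geometry$width_px, geometry$height_px) / 2
  ramp <- seq(0, 100, length.out = n_pre)
  pre <- tibble(
    x_px = ctr[1] + rnorm(n_pre, 0, 2), y_px = ctr[2] + rnorm(n_pre, 0, 2),
    pupil_left = aps_to_pupil(ramp), pupil_right = aps_to_pupil(ramp),
    valid_left = TRUE, valid_right = TRUE
  )

  pos <- ctr
  chunks <- vector("list", n_tot)
  truths <- vector("list", n_tot)
  n_per_phase <- integer(n_tot)
  for (i in seq_len(n_tot)) {
    preset <- if (labels[i] == "MNL") preset_mnl else preset_non
    plan <- sample_event_plan(labels[i], preset, geometry, rate_hz, start_xy = pos)
    r <- render_gaze(plan, geometry, rate_hz, start_xy = pos)
    chunks[[i]] <- r$samples
    truths[[i]] <- mutate(r$truth, phase_id = i, label = labels[i])
    n_per_phase[i] <- nrow(r$samples)
    pos <- r$end_xy
  }
  samples <- bind_rows(c(list(pre), chunks))
  samples <- mutate(samples, t_ms = (row_number() - 1) * dt_ms, .before = 1)
  rec <- gaze_recording(samples, rate_hz = rate_hz, geometry = geometry)

  bounds <- n_pre + c(0, cumsum(n_per_phase))
  annotations <- tibble(
    phase_id = seq_len(n_tot),
    label = factor(labels, levels = phase_labels),
    start_ms = bounds[seq_len(n_tot)] * dt_ms,
    end_ms = bounds[seq_len(n_tot) + 1] * dt_ms
  )
  structure(
    list(
      recording = rec,
      annotations = annotations,
      truth = bind_rows(truths)
    ),
    class = "synthetic_gaze_set"
  )
}

#' @export
print.synthetic_gaze_set <- function(x, ...) {
  cat(sprintf(
    "<synthetic_gaze_set> %d samples, %d MNL + %d non-MNL phases\n",
    nrow(x$recording$samples),
    sum(x$annotations$label == "MNL"), sum(x$annotations$label == "non-MNL")
  ))
  invisible(x)
}
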