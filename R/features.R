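#' Trial-wide pupil extrema for min-max normalization
#'
#' Finds the minimum and maximum pupil diameter per eye over all valid samples
#' of the whole trial. These anchor the adjusted pupil size (APS): the
#' per-sample min-max normalization that makes pupil data comparable across
#' subjects regardless of units.
#'
#' @param recording a [gaze_recording()].
#' @return A list of class `pupil_range` with elements `ps_min_left`,
#'   `ps_max_left`, `ps_min_right`, `ps_max_right`.
#' @export
pupil_range <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  out <- list()
  for (eye in c("left", "right")) {
    ps <- s[[paste0("pupil_", eye)]]
    ok <- s[[paste0("valid_", eye)]] & is.finite(ps)
    if (!any(ok)) {
      stop_insufficient(sprintf("no valid pupil samples for the %s eye", eye))
    }
    lo <- min(ps[ok])
    hi <- max(ps[ok])
    if (hi <= lo) {
      stop_insufficient(sprintf(
        "degenerate pupil range for the %s eye (min == max == %g)", eye, lo
      ))
    }
    out[[paste0("ps_min_", eye)]] <- lo
    out[[paste0("ps_max_", eye)]] <- hi
  }
  structure(out, class = "pupil_range")
}

#' Adjusted pupil size (APS)
#'
#' Min-max normalizes a pupil diameter against trial-wide extrema:
#' `APS = (ps - ps_min) / (ps_max - ps_min) * 100` (percent). Values drifting
#' outside the trial extrema by numerical noise are clamped to `[0, 100]`.
#'
#' @param ps pupil diameter(s), same units as the extrema.
#' @param ps_min,ps_max trial-wide extrema (see [pupil_range()]).
#' @return APS in percent, same length as `ps`.
#' @examples
#' adjusted_pupil_size(3.5, 3.0, 4.0) # 50
#' @export
adjusted_pupil_size <- function(ps, ps_min, ps_max) {
  if (!is.finite(ps_min) || !is.finite(ps_max) || ps_max <= ps_min) {
    stop_insufficient("degenerate pupil range: ps_max must exceed ps_min")
  }
  pmin(pmax((ps - ps_min) / (ps_max - ps_min) * 100, 0), 100)
}

#' Saccadic amplitude in degrees of visual angle
#'
#' Converts the pixel displacement between two gaze points to physical
#' millimetres via the display's pixel pitch (per axis), then to visual angle:
#' `2 * atan(d_mm / (2 * view_dist_mm))`, in degrees.
#'
#' @param x1,y1,x2,y2 endpoint coordinates in px (vectorized).
#' @param geometry a [screen_geometry()].
#' @return Amplitude(s) in degrees.
#' @examples
#' g <- screen_geometry(width_mm = 300, height_mm = 225)
#' saccade_amplitude_deg(0, 0, 100, 0, g) # about 2.797 degrees
#' @export
saccade_amplitude_deg <- function(x1, y1, x2, y2, geometry = screen_geometry()) {
  dx_mm <- (x2 - x1) * geometry$width_mm / geometry$width_px
  dy_mm <- (y2 - y1) * geometry$height_mm / geometry$height_px
  d_mm <- sqrt(dx_mm^2 + dy_mm^2)
  2 * atan(d_mm / (2 * geometry$view_dist_mm)) * 180 / pi
}

# inverse of saccade_amplitude_deg for an isotropic pitch; used by the
# synthetic generator to plan displacements in px from drawn amplitudes
deg_to_px <- function(deg, geometry = screen_geometry()) {
  pitch <- geometry$width_mm / geometry$width_px
  2 * geometry$view_dist_mm * tan(deg * pi / 180 / 2) / pitch
}

px_to_deg <- function(px, geometry = screen_geometry()) {
  pitch <- geometry$width_mm / geometry$width_px
  2 * atan(px * pitch / (2 * geometry$view_dist_mm)) * 180 / pi
}

#' Cumulative frequency of values beyond (or within) a bound
#'
#' The percentage of values strictly above a bound (`side = "above"`, used for
#' saccadic amplitude ladders) or at-or-below it
#' (`side = "below_or_equal"`, used for inter-fixation distance bands).
#'
#' @param values numeric vector (non-empty).
#' @param bound the threshold.
#' @param side `"above"` (strict) or `"below_or_equal"` (inclusive).
#' @return Percent in `[0, 100]`.
#' @export
cumulative_frequency <- function(values, bound, side = c("above", "below_or_equal")) {
  side <- match.arg(side)
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    stop_insufficient("cumulative_frequency needs at least one finite value")
  }
  hits <- if (side == "above") values > bound else values <= bound
  100 * sum(hits) / length(hits)
}

#' Modal 5%-interval index of an APS distribution
#'
#' Splits the APS range 0-100% into 20 equal intervals indexed 1-20
#' (half-open `[5(k-1), 5k)` for k = 1..19, closed `[95, 100]` for k = 20)
#' and returns the index of the most populated interval. Ties break toward
#' the smaller index.
#'
#' @param aps_values APS values in percent, within `[0, 100]`.
#' @return Integer in 1..20.
#' @examples
#' aps_modal_bin_index(rep(47, 5)) # 10
#' @export
aps_modal_bin_index <- function(aps_values) {
  aps_values <- aps_values[is.finite(aps_values)]
  if (length(aps_values) == 0) {
    stop_insufficient("aps_modal_bin_index needs at least one value")
  }
  if (any(aps_values < 0 | aps_values > 100)) {
    stop_contract("APS values must lie in [0, 100]")
  }
  idx <- pmin(floor(aps_values / 5) + 1L, 20L)
  counts <- tabulate(idx, nbins = 20L)
  which.max(counts) # which.max already breaks ties toward the smaller index
}

sacamp_thresholds <- seq(1.5, 7.5, by = 0.5)
fixdis_bounds <- c(25, 50, 75, 100)

# map events to annotated phases by event midpoint; returns phase row index
# (NA when the midpoint falls outside every interval). Intervals are
# half-open [start_ms, end_ms).
assign_events_to_phase <- function(events, annotations) {
  mid <- (events$start_ms + events$end_ms) / 2
  ord <- order(annotations$start_ms)
  pos <- findInterval(mid, annotations$start_ms[ord])
  out <- rep(NA_integer_, length(mid))
  inside <- pos >= 1 & pos <= nrow(annotations)
  cand <- ord[pmax(pos, 1)]
  ok <- inside & mid < annotations$end_ms[cand] & mid >= annotations$start_ms[cand]
  out[ok] <- cand[ok]
  out
}

# per-sample enclosing retained-event kind ("fixation"/"saccade"/NA)
sample_event_kind <- function(t_ms, events) {
  if (nrow(events) == 0) return(rep(NA_character_, length(t_ms)))
  ord <- order(events$start_ms)
  st <- events$start_ms[ord]
  en <- events$end_ms[ord]
  kd <- events$kind[ord]
  pos <- findInterval(t_ms, st)
  out <- rep(NA_character_, length(t_ms))
  inside <- pos >= 1 & t_ms <= en[pmax(pos, 1)]
  out[inside] <- kd[pos[inside]]
  out
}

panel_one_window <- function(samples, events, pr, geometry,
                             window_start, window_end, phase_dur_s) {
  fix <- events[events$kind == "fixation", ]
  sac <- events[events$kind == "saccade", ]
  n_fix <- nrow(fix)
  n_sac <- nrow(sac)
  if (n_fix + n_sac == 0) return(NULL)
  sac_dur_s <- sum(sac$duration_ms) / 1000
  fix_dur_s <- sum(fix$duration_ms) / 1000
  amp <- if (n_sac > 0) {
    saccade_amplitude_deg(sac$start_x, sac$start_y, sac$end_x, sac$end_y, geometry)
  } else {
    numeric(0)
  }
  fix_ord <- fix[order(fix$start_ms), ]
  fixdis <- if (n_fix >= 2) {
    sqrt(diff(fix_ord$centroid_x)^2 + diff(fix_ord$centroid_y)^2)
  } else {
    numeric(0)
  }
  out <- tibble(
    phase_duration_s = phase_dur_s,
    saccade_duration_s = sac_dur_s,
    saccade_number = n_sac,
    fixation_number = n_fix,
    saccade_frequency = n_sac / phase_dur_s,
    fixation_frequency = n_fix / phase_dur_s,
    gaze_event_frequency = (n_sac + n_fix) / phase_dur_s,
    mean_saccade_duration_s = if (n_sac > 0) mean(sac$duration_ms) / 1000 else NA_real_,
    mean_fixation_duration_s = if (n_fix > 0) mean(fix$duration_ms) / 1000 else NA_real_,
    saccade_duration_pct =
      if (sac_dur_s + fix_dur_s > 0) 100 * sac_dur_s / (sac_dur_s + fix_dur_s) else NA_real_,
    saccade_number_pct = 100 * n_sac / (n_sac + n_fix),
    fixation_number_pct = 100 * n_fix / (n_sac + n_fix),
    mean_sacamp_deg = if (n_sac > 0) mean(amp) else NA_real_
  )
  for (th in sacamp_thresholds) {
    out[[sprintf("sacamp_above_%.1f", th)]] <-
      if (length(amp) > 0) cumulative_frequency(amp, th, "above") else NA_real_
  }
  for (b in fixdis_bounds) {
    out[[sprintf("fixdis_below_%d", b)]] <-
      if (length(fixdis) > 0) cumulative_frequency(fixdis, b, "below_or_equal") else NA_real_
  }
  in_win <- samples$t_ms >= window_start & samples$t_ms < window_end
  kind <- sample_event_kind(samples$t_ms[in_win], events)
  for (eye in c("left", "right")) {
    ps <- samples[[paste0("pupil_", eye)]][in_win]
    ok <- samples[[paste0("valid_", eye)]][in_win] & is.finite(ps)
    aps <- adjusted_pupil_size(
      ps[ok], pr[[paste0("ps_min_", eye)]], pr[[paste0("ps_max_", eye)]]
    )
    kk <- kind[ok]
    out[[paste0("aps_trial_", eye)]] <- if (length(aps) > 0) mean(aps) else NA_real_
    out[[paste0("aps_sac_", eye)]] <-
      if (any(kk %in% "saccade")) mean(aps[kk %in% "saccade"]) else NA_real_
    out[[paste0("aps_fix_", eye)]] <-
      if (any(kk %in% "fixation")) mean(aps[kk %in% "fixation"]) else NA_real_
    out[[paste0("aps_cf55_", eye)]] <-
      if (length(aps) > 0) 100 * mean(aps >= 55 & aps <= 100) else NA_real_
    out[[paste0("aps_modal_bin_", eye)]] <-
      if (length(aps) > 0) aps_modal_bin_index(aps) else NA_real_
  }
  for (m in c("aps_trial", "aps_sac", "aps_fix", "aps_cf55", "aps_modal_bin")) {
    out[[paste0(m, "_avg")]] <- (out[[paste0(m, "_left")]] + out[[paste0(m, "_right")]]) / 2
  }
  out
}

#' Per-phase metric panel
#'
#' Computes, for every annotated phase, the full set of per-phase gaze and
#' pupil measures: event counts, durations and frequencies; mean saccadic
#' amplitude plus its cumulative-frequency ladder (above 1.5-7.5 degrees);
#' inter-fixation (centroid-to-centroid) distance bands (at or below
#' 25/50/75/100 px); and the adjusted-pupil-size measures (trial / in-saccade
#' / in-fixation means, the share of samples in the 55-100% band, and the
#' modal 5%-interval index), per eye and eye-averaged. Events belong to the
#' phase holding their midpoint. Phases with no retained events are dropped
#' with a warning.
#'
#' @param recording a [gaze_recording()].
#' @param annotations phase annotation tibble (see [read_phase_annotations()]).
#' @param events optional pre-computed [detect_events()] result.
#' @param cfg an [ivt_config()].
#' @return A tibble with one row per retained phase: `phase_id`, `label`,
#'   then one column per measure.
#' @export
phase_metrics <- function(recording, annotations, events = NULL,
                          cfg = ivt_config()) {
  stopifnot(inherits(recording, "gaze_recording"))
  annotations <- validate_annotations(annotations)
  if (is.null(events)) events <- detect_events(recording, cfg)
  pr <- pupil_range(recording)
  s <- recording$samples
  ph_of <- assign_events_to_phase(events, annotations)
  rows <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    ev <- events[!is.na(ph_of) & ph_of == i, ]
    dur_s <- (annotations$end_ms[i] - annotations$start_ms[i]) / 1000
    p <- panel_one_window(
      s, ev, pr, recording$geometry,
      annotations$start_ms[i], annotations$end_ms[i], dur_s
    )
    if (is.null(p)) {
      warn(sprintf(
        "phase %s has no retained gaze events; dropped from the panel",
        annotations$phase_id[i]
      ))
      return(NULL)
    }
    bind_cols_front(p, annotations$phase_id[i], annotations$label[i])
  })
  rows
}

bind_cols_front <- function(panel, phase_id, label) {
  dplyr::bind_cols(tibble(phase_id = phase_id, label = label), panel)
}

#' The 12 selected classifier features, per phase
#'
#' Assembles the feature vector fed to the classifier: the 4 significant
#' time/frequency measures (phase duration, saccade duration, saccade and
#' fixation number), the 3 gaze-travel measures (inter-fixation distance at
#' or below 75 px, mean saccadic amplitude, saccadic amplitude above 2.5
#' degrees), and the 5 pupil measures (APS in trial / saccade / fixation, APS
#' share in 55-100%, modal APS interval index), pupil features eye-averaged.
#' All features except the full annotated `phase_duration_s` are computed on
#' an onset-anchored analysis window of at most `window_ms` (the whole phase
#' when shorter).
#'
#' @inheritParams phase_metrics
#' @param window_ms analysis-window length in ms (default 5000: 5-second
#'   phases are what the detector consumes).
#' @return A tibble: `phase_id`, `label`, then the 12 feature columns.
#' @export
phase_features <- function(recording, annotations, events = NULL,
                           cfg = ivt_config(), window_ms = 5000) {
  stopifnot(inherits(recording, "gaze_recording"))
  annotations <- validate_annotations(annotations)
  if (is.null(events)) events <- detect_events(recording, cfg)
  pr <- pupil_range(recording)
  s <- recording$samples
  win <- mutate(annotations,
    end_ms = pmin(.data$end_ms, .data$start_ms + window_ms)
  )
  ph_of <- assign_events_to_phase(events, win)
  purrr::map_dfr(seq_len(nrow(win)), function(i) {
    ev <- events[!is.na(ph_of) & ph_of == i, ]
    full_dur_s <- (annotations$end_ms[i] - annotations$start_ms[i]) / 1000
    win_dur_s <- (win$end_ms[i] - win$start_ms[i]) / 1000
    p <- panel_one_window(
      s, ev, pr, recording$geometry, win$start_ms[i], win$end_ms[i], win_dur_s
    )
    if (is.null(p)) {
      warn(sprintf(
        "phase %s has no retained gaze events in its analysis window; dropped",
        annotations$phase_id[i]
      ))
      return(NULL)
    }
    tibble(
      phase_id = annotations$phase_id[i],
      label = annotations$label[i],
      phase_duration_s = full_dur_s,
      saccade_duration_s = p$saccade_duration_s,
      saccade_number = p$saccade_number,
      fixation_number = p$fixation_number,
      fixdis_below_75 = p$fixdis_below_75,
      mean_sacamp_deg = p$mean_sacamp_deg,
      sacamp_above_2.5 = p$sacamp_above_2.5,
      aps_trial = p$aps_trial_avg,
      aps_sac = p$aps_sac_avg,
      aps_fix = p$aps_fix_avg,
      aps_cf55 = p$aps_cf55_avg,
      aps_modal_bin = p$aps_modal_bin_avg
    )
  })
}

feature_vector_names <- c(
  "phase_duration_s", "saccade_duration_s", "saccade_number",
  "fixation_number", "fixdis_below_75", "mean_sacamp_deg",
  "sacamp_above_2.5", "aps_trial", "aps_sac", "aps_fix",
  "aps_cf55", "aps_modal_bin"
)
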