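#!/usr/bin/env Rscript
# Iterative calibration of the synthetic-gaze presets.
#
# The generator's phase-level pupil parameters are analytic (group mean and
# between-phase SD read directly off the reference statistics), but the
# event-level duration and amplitude marginals interact with 60 Hz rendering,
# the I-VT filter and the 90 ms minimum-duration rule, so their preset values
# are found by fixed-point iteration: measure the recovered group statistics
# on a large simulated batch, nudge each marginal toward its target, repeat.
# The converged constants are frozen into mnl_preset()/non_mnl_preset(); this
# script is kept so the calibration is reproducible and auditable.
#
# Usage: Rscript scripts/calibrate_presets.R [n_phases_per_class] [rounds]

suppressMessages({
  library(gazenav)
  library(dplyr)
})

args <- commandArgs(trailingOnly = TRUE)
n_per_class <- if (length(args) >= 1) as.integer(args[1]) else 600
rounds <- if (length(args) >= 2) as.integer(args[2]) else 5

targets <- list(
  mnl = list(phase_dur = 12.53, fix_dur = 0.30, sacamp = 2.48, fixdis75 = 63.60),
  non = list(phase_dur = 22.97, fix_dur = 0.28, sacamp = 1.45, fixdis75 = 82.53)
)

measure <- function(pm, pn, seed) {
  d <- generate_dataset(n_per_class, n_per_class, pm, pn, seed = seed)
  m <- phase_metrics(d$recording, d$annotations)
  m %>%
    group_by(label) %>%
    summarise(
      phase_dur = mean(phase_duration_s),
      fix_dur = mean(mean_fixation_duration_s),
      sacamp = mean(mean_sacamp_deg),
      fixdis75 = mean(fixdis_below_75),
      aps = mean(aps_trial_left),
      cf55 = mean(aps_cf55_left),
      modal = median(aps_modal_bin_left),
      .groups = "drop"
    )
}

# start from the shipped defaults: a rerun verifies the frozen calibration
# is a fixed point (up to simulation noise) rather than re-deriving it
pm0 <- mnl_preset(); pn0 <- non_mnl_preset()
state <- list(
  mnl = list(phase_dur_mean = pm0$phase_duration_mean_s,
             fix_dur_mean = pm0$fix_duration_mean_s,
             sacamp_mean = pm0$sacamp_mean_deg,
             return_amp_sd = pm0$return_amp_sd),
  non = list(phase_dur_mean = pn0$phase_duration_mean_s,
             fix_dur_mean = pn0$fix_duration_mean_s,
             sacamp_mean = pn0$sacamp_mean_deg,
             return_amp_sd = pn0$return_amp_sd)
)

mk_presets <- function(st) {
  list(
    mnl = mnl_preset(
      phase_duration_mean_s = st$mnl$phase_dur_mean,
      fix_duration_mean_s = st$mnl$fix_dur_mean,
      sacamp_mean_deg = st$mnl$sacamp_mean,
      return_amp_sd = st$mnl$return_amp_sd
    ),
    non = non_mnl_preset(
      phase_duration_mean_s = st$non$phase_dur_mean,
      fix_duration_mean_s = st$non$fix_dur_mean,
      sacamp_mean_deg = st$non$sacamp_mean,
      return_amp_sd = st$non$return_amp_sd
    )
  )
}

for (r in seq_len(rounds)) {
  ps <- mk_presets(state)
  g <- measure(ps$mnl, ps$non, seed = 1000 + r)
  for (cls in c("mnl", "non")) {
    row <- g[g$label == (if (cls == "mnl") "MNL" else "non-MNL"), ]
    tg <- targets[[cls]]
    st <- state[[cls]]
    st$phase_dur_mean <- st$phase_dur_mean * tg$phase_dur / row$phase_dur
    st$fix_dur_mean <- st$fix_dur_mean + (tg$fix_dur - row$fix_dur)
    # damped multiplicative update: the zigzag renderer makes detected
    # amplitude a mildly nonlinear (floored) function of the planned one
    st$sacamp_mean <- st$sacamp_mean * (tg$sacamp / row$sacamp)^0.8
    # looser return amplitudes spread consecutive retained fixations apart
    # and lower the share of inter-fixation distances <= 75 px
    st$return_amp_sd <- min(max(st$return_amp_sd * (row$fixdis75 / tg$fixdis75)^1.5, 0.02), 1.5)
    state[[cls]] <- st
  }
  cat(sprintf("round %d measured:\n", r))
  print(as.data.frame(g), digits = 4)
  cat("updated state:\n")
  str(state)
}

cat("\nfinal preset constants:\n")
for (cls in c("mnl", "non")) {
  st <- state[[cls]]
  cat(sprintf(
    "%s: phase_duration_mean_s = %.4f, fix_duration_mean_s = %.4f, sacamp_mean_deg = %.4f, return_amp_sd = %.4f\n",
    cls, st$phase_dur_mean, st$fix_dur_mean, st$sacamp_mean, st$return_amp_sd
  ))
}
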