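---
title: "Detecting navigation loss from eye-tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting navigation loss from eye-tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During simulated colonoscopy, a trainee occasionally loses spatial
orientation: the bowel lumen disappears from the scope view and the operator
scans the colon wall searching for the way forward. These *moments of
navigation loss* (MNL) are the cardinal sign of task difficulty in endoscopy
training — they are when an instructor would step in. `gazenav` implements a
complete pipeline that detects MNL phases from a 60 Hz eye-tracking stream:
event detection, per-phase gaze and pupil features, group statistics,
adversarial augmentation of the small per-phase sample, and a gated
recurrent classifier. Because the underlying human recordings are not
publicly deposited, the package also ships a calibrated synthetic gaze
generator; every quantitative claim the test-suite makes is made on that
generator's output, and this vignette is explicit about what that does and
does not establish.

## Event detection: the I-VT filter

Gaze samples arrive at 60 Hz as screen coordinates in pixels. The velocity
at sample $i$ is the two-point backward difference
$v_i = \lVert p_i - p_{i-1}\rVert / \Delta t$ in px/ms, with no smoothing
window; the first sample inherits the second's velocity. A sample is a
*fixation* sample when $v_i$ is strictly below the threshold (default
2.1 px/ms) and a *saccade* sample otherwise — the threshold value itself
classifies as saccade. Maximal same-label runs become events; fixation
events shorter than 90 ms are then discarded outright. Their flanking
saccades are **not** merged: the observed roughly 2:1 saccade:fixation
count ratio only arises if brief fixations vanish *between* two counted
saccades, so deletion-without-merge is the behaviour the downstream counts
assume.

Two numerical details worth noting:

* **Threshold units.** 2.1 px/ms (~2100 px/s) is far above common angular
  I-VT defaults; it is used exactly as specified, in pixel units, and is
  configurable via `ivt_config()`.
* **Gap bridging.** Runs of invalid samples up to 75 ms (a typical
  blink-robustness value; configurable) are bridged when the same label
  flanks them; the invalid samples contribute to neither centroid nor path.
  Longer gaps split events. This is an extension beyond the minimal filter
  description and defaults to behaviour that is conservative for fixation
  durations.

Event duration is `t(last member sample) − t(first member sample)`, so a
seven-sample fixation at 60 Hz lasts 100 ms and survives the 90 ms rule,
while a five-sample one (66.7 ms) does not.

## Per-phase measures

For each annotated phase (half-open interval `[start_ms, end_ms)`), events
are assigned by their midpoint, which guarantees boundary events are never
double-counted. The panel (`phase_metrics()`) contains:

* counts, summed durations, frequencies, and count/duration shares of
  saccades and fixations. *Saccade duration percent* is not defined
  precisely in the source material; it is implemented as saccade event time
  over total (saccade + fixation) event time, and flagged here as a choice.
* **Saccadic amplitude** per saccade from its event endpoints, converted to
  degrees through the screen geometry:
  $\theta = 2\,\mathrm{atan}\!\left(d_{mm} / 2D\right)$ with per-axis pixel
  pitch and viewing distance $D$ (default 600 mm on a 340 × 255 mm,
  1024 × 768 px display — a true 4:3 panel so both axes share one pitch).
  The cumulative-frequency ladder reports the percentage of saccades
  strictly above 1.5°–7.5° in 0.5° steps.
* **Inter-fixation distance** between consecutive *retained* fixation
  centroids, with inclusive cumulative frequencies at 25/50/75/100 px.
* **Adjusted pupil size (APS)**: per-sample min–max normalization of pupil
  diameter against trial-wide extrema,
  $\mathrm{APS} = (ps - ps_{\min})/(ps_{\max} - ps_{\min}) \times 100\%$,
  computed per eye; units cancel, which is why the simulator's arbitrary
  pupil scale is harmless. APS is summarized per phase as the mean over all
  samples (duration-unweighted), split by enclosing event kind
  (saccade/fixation), as the share of samples in the [55, 100]% band, and
  as the modal index of twenty 5% intervals (half-open except the last,
  ties toward the smaller index).

The classifier consumes 12 features per phase (`phase_features()`): the four
significant time/frequency measures, the three gaze-travel measures
(inter-fixation distance ≤ 75 px, mean amplitude, amplitude > 2.5°), and
five pupil measures (eye-averaged). All but the phase duration are computed
on an onset-anchored window of at most 5 s — the detector operates on
5-second phases — while the duration feature carries the full annotated
length. One vector per annotated phase reconciles the 5-second windows with
the train/test sample counts (51 + 77 and 17 + 44).

## Group statistics and feature selection

`compare_measure()` reports group means with standard errors, per-group
Shapiro–Wilk normality p-values, and a two-sided independent-samples t-test.
Welch's variant is the default because the original SPSS workflow does not
state whether variances were pooled; `var_equal = TRUE` reproduces the
pooled test. Each phase is one observation — per-subject clustering is not
modelled, a deliberate simplification matching the reported degrees of
freedom, and a known limitation. No multiple-testing correction is applied
(raw p against α = 0.05), again matching the original analysis and likewise
a limitation rather than a recommendation.

`select_features()` keeps candidates with p < α, with one twist: each
cumulative-frequency ladder contributes only its best representative — the
significant threshold with the largest absolute group difference — because
the measure screening worked that way (the ladder as a whole is
significant almost everywhere; the maximal-difference rung is the
informative summary). With the printed comparison tables as input the
selection returns exactly the 12 classifier features.

## The synthetic gaze generator

`generate_dataset()` produces one continuous labelled recording: a
2-second pre-roll fixation whose APS sweeps 0 → 100% (so the trial-wide
pupil extrema that anchor the normalization exist by construction),
followed by interleaved MNL / non-MNL phases. Each phase is planned as a
latent alternating saccade–fixation sequence and then rendered to samples;
the latent plan is retained, so the I-VT filter is tested against ground
truth rather than against itself.

Key modelling choices:

* **Durations** are lognormal. Phase-level means and between-phase SDs are
  taken from the reference group statistics (SD = SE·√n, n = 51/77).
* **Short fixations.** A preset fraction of fixations (0.545 MNL / 0.595
  non-MNL) is drawn below 90 ms. The minimum-duration rule later discards
  them, which is what produces the ~2:1 retained saccade:fixation ratio.
* **Saccades** draw gamma amplitudes (in degrees, converted to px through
  the same geometry the detector uses, so the conversion round-trips
  exactly). A saccade that follows a discarded short fixation is a *return
  saccade*: direction reversed with angular noise, amplitude tied to the
  outgoing amplitude by a lognormal factor. This glance-and-return pattern
  is the mechanism that lets inter-fixation distances be stochastically
  smaller than chained amplitudes — without it the printed amplitude and
  fixation-distance tables are jointly unreachable under independent
  uniform directions.
* **Rendering.** Within fixations, position is centroid + Gaussian jitter
  (3 px SD — small enough that intra-fixation velocities stay far below
  threshold). Within saccades, every inter-sample step is at least 36 px
  (≥ 2.16 px/ms at 60 Hz), achieved with a zigzag path when the
  displacement alone is too slow; saccade sample counts are even so the
  zigzag closes. The landing point preserves the drawn amplitude exactly
  (directions are resampled near screen edges rather than reflecting,
  because reflection would bias amplitudes).
* **Pupil.** APS is generated directly: a phase-level mean (Gaussian,
  between-phase SD from the reference SEs) plus a smooth AR(1) within-phase
  process (marginal SD 5.8%, chosen so the share of samples at or above 55%
  matches the reference cell given the between-phase spread) plus small
  independent per-eye noise. The left/right asymmetry seen in the original
  data is *not* modelled. Pupil values map to an arbitrary affine diameter
  scale; Eq-style min–max normalization cancels it.

Event-level means cannot be set analytically — quantization to the 60 Hz
grid, the minimum-duration filter, and the zigzag renderer all shift the
*detected* statistics away from the planned ones — so the shipped presets
were calibrated by fixed-point iteration (`scripts/calibrate_presets.R`):
simulate several hundred phases per class, run the full detection + feature
pipeline, nudge each marginal toward its target, repeat. The calibrated
world recovers the reference group means of amplitude, fixation duration,
phase duration, inter-fixation distance, and the APS measures within two
pooled standard errors, across seeds.

**What a green test establishes — and what it does not.** The recovery
tests show the pipeline's measurement chain is faithful: a stream with
known statistics, after detection and feature extraction, yields those
statistics back. They do not show that real colonoscopic gaze looks like
the generator's output; real scanpaths have main-sequence kinematics,
smooth pursuit, blinks, drift, and between-subject structure that the
generator deliberately omits. Classification results on synthetic data are
a benchmark of the protocol, not a clinical claim.

## Adversarial augmentation

Per class, a generator maps 100-dimensional uniform [−1, 1] noise to a
12-dimensional feature vector; features are min–max scaled to [−1, 1]
(scaler fitted on real vectors only, hence synthetic and test data are
mapped through real-data statistics). The stated image-style architecture
(first convolutional layer 5 × 5 × 64, 1024-unit fully connected layer) is
applied to vectors as its 1-D analog: kernels of length 5 with 64 filters,
the 1024-unit layer in both networks. Training uses binary cross-entropy,
one generator/discriminator update pair per minibatch (batch 32), Adam with
learning rate 0.001 and momentum β₁ = 0.5, for 5000 epochs by default. The
learning rate — described as *variable* in the source protocol — decays
linearly to ~0 over training; empirically this is what makes the endpoint
stable rather than oscillating. Exact network depth beyond the stated
layers is unspecified in the source; the implementation uses the minimal
stack (noise → FC 1024 → FC 12·64 → conv → tanh, and conv → FC 1024 → 1),
which is enough capacity for 12-dimensional targets. De-scaled synthetic
vectors are clipped to hard feature bounds and integer features (counts,
modal bin) are rounded, so synthetic rows satisfy the same type contract
as real ones.

Synthesis quality is checked two ways: distribution-matching and
mode-collapse guards on a toy 12-dimensional Gaussian (synthetic means
within 0.15 of real means on the scaled scale; per-feature SD within 30%),
and `embedding_overlap()` — a joint t-SNE embedding (exact, perplexity 30,
seeded; implemented in-package because no t-SNE library is available in
the declared environment) on which a cross-validated logistic
discriminator scores real-vs-synthetic separability. 0.5 means full
overlap; identical sets score ≤ 0.55, disjoint clusters ≥ 0.95. "Visual
inspection" of the embedding is replaced by this score because a test
cannot inspect visually.

The networks are trained by compiled (RcppArmadillo) loops — no deep
learning framework exists in the declared environment, so forward passes,
backpropagation, Adam and RMSProp are implemented from first principles.
The R reference implementation of the same forward/backward passes is kept
and tested against the compiled path and against finite differences.

## The classifier and the feeding experiment

The classifier is a single LSTM cell (32 units) applied to one feature
vector per time step (time step = 1), followed by a 2-node softmax;
categorical cross-entropy, RMSProp (rate 0.001, decay 0.9 — the optimizer's
secondary constants are framework defaults and recorded here), batch 32,
1000 epochs, orthogonal weight initialization, zero biases. With a single
time step the LSTM degenerates toward a gated feed-forward unit; it is
implemented as specified rather than "fixed". With the initial hidden and
cell state at zero, the forget gate and recurrent matrix receive no
gradient; they are retained for fidelity to the stated unit. Features are
z-scored with statistics from the *real* training rows only, applied
unchanged to synthetic and test vectors.

`feeding_experiment()` composes training sets of the real vectors plus
0/200/1000/1600/2000 synthetic vectors per class, trains one model per
strategy, and evaluates every strategy on the identical held-out test set.
Generators record the provenance of their training rows; a generator that
saw test phases is rejected. **The positive class is non-MNL** — the
reported sensitivities are exact multiples of 1/44 and specificities of
1/17, which identifies the 44 non-MNL / 17 MNL test split as the
denominator assignment. The ROC sweeps the softmax score and is emitted per
strategy (whether the original single ROC referred to the best model or all
strategies is unstated, so all are provided).

At study scale the real training set (128 phases) is small enough that the
1000-epoch LSTM memorizes it (training loss → 0); augmentation is what
restores generalization, which is precisely the argument for the
synthesized data. On the synthetic benchmark the real+1000S strategy's
median accuracy over five seeds is the headline acceptance quantity.

## Reproducibility

Every stochastic stage takes a seed; `run_pipeline()` derives per-stage
seeds from one master seed by a deterministic hash, so stages can be rerun
in isolation and a fixed config reproduces its report bit-for-bit. Output
artifacts embed a fingerprint of the configuration that produced them.
Desk-scale reductions (GAN epochs 1000 instead of 5000 in the acceptance
runs, reduced epochs in unit tests) are applied to training lengths only —
never to sample sizes, thresholds, or tolerances.

## Known limitations

* Per-subject clustering of phases is not modelled in the statistics; each
  phase is treated as independent, matching the reference analysis.
* No multiple-testing correction (by design, matching the protocol).
* The generator omits oculomotor physiology (main sequence, pursuit,
  blinks) and left/right pupil asymmetry.
* GAN depth beyond the stated layers, and the variance-pooling choice of
  the t-tests, are resolved by documented assumption.
* The pixel-unit velocity threshold ties event detection to this specific
  display geometry; angular thresholds would transfer better but are out of
  scope.
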