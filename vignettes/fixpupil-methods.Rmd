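---
title: "Methods: fixation-aligned pupillometry for visual search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixation-aligned pupillometry for visual search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fixpupil)
```

## The analysis problem

During free-viewing visual search the pupil dilates transiently when the
eyes land on task-relevant items, but two measurement problems stand between
the raw tracker output and that signal. First, blinks leave artifacts that
outlast the tracker's parsed blink events: as the eyelid clears the pupil
image, the measured area swings violently for some tens to hundreds of
milliseconds after the nominal blink end. Second, a video eye tracker images
the pupil from a fixed camera, so eye rotation foreshortens the image and
measured pupil size becomes a function of gaze direction (the pupil
foreshortening error, PFE) — in a task that requires eye movements, this is
a gaze-correlated artifact sitting directly on top of the signal of
interest.

`fixpupil` implements the full chain from raw samples to cluster-corrected
group statistics, and pairs it with a synthetic-session generator whose
ground truth makes every stage testable.

## Preprocessing

**Blink endpoint extension.** The derivative criterion is operationalised
as: first difference of the pupil per sample, z-scored over all samples
outside the parsed blink spans (a difference that touches a blink sample is
excluded — it measures the parser's boundary, not signal), absolute value,
then a boxcar mean over `window_ms` (default 100 ms). The blink end is
pushed to the first post-blink sample at which this windowed activity is at
or below `z_fraction` (default 0.10) of its whole-recording mean, capped at
`max_extend_ms` (default 1000 ms) past the parsed offset.

The window is *forward-looking* by default (`window_align = "forward"`):
the criterion asks whether the `window_ms` of signal starting at a candidate
sample is quiet. A trailing window answers a different question — whether
the *preceding* window was quiet — and therefore systematically overshoots
the artifact end by roughly the window length; with a 100-ms window that
error is five downsampled samples, large enough to smear fixation-aligned
baselines. Both alignments (and `"centered"`) are available as parameters.

Two properties of real tracker output make the 10%-of-mean rule meaningful,
and the generator reproduces both. (1) The clean trace is smooth at the
sample level: physiological pupil fluctuation (hippus) lives below ~1 Hz and
the tracker's on-line filtering leaves almost no white sample-to-sample
noise, so the clean windowed derivative activity is far below the recording
mean. (2) Blink artifacts are violent: their derivative magnitudes exceed
the clean level by orders of magnitude and dominate the recording-mean
activity, which lifts the 10% threshold safely above the clean level. If
the per-sample noise were white and of ordinary magnitude, the windowed
mean would concentrate tightly around its own mean and *never* fall below
10% of it — the rule only makes sense for smooth traces with large
artifacts, which is exactly what video pupillometry produces.

**Repair, downsampling, smoothing.** Extended spans are merged when they
touch and reconstructed by linear interpolation between the nearest valid
samples (spans touching a recording edge are filled with the nearest valid
value and flagged). Repair happens at the native 1000 Hz; the trace is then
downsampled to 50 Hz by non-overlapping bin averaging — the bin mean doubles
as an anti-aliasing filter — and smoothed with a zero-phase (forward–
backward) 3rd-order Butterworth low-pass at 4 Hz. Zero-phase filtering has
no group delay, which matters because peak *latencies* are part of the
scientific claims; the effective amplitude response is the squared
single-pass Butterworth magnitude. Edge transients are controlled by
odd-reflection padding of three filter warm-up lengths, which keeps the DC
error below 1e−6. Near the Nyquist frequency the bilinear digital design
attenuates more than the analog prototype `1/(1+(f/fc)^6)` predicts; the
tests therefore treat the analog curve as an upper bound on transmitted
amplitude in the stopband and as a two-sided reference (within 2–10%) in
the passband, where the designs agree.

## PFE quantification and correction

Per session, ordinary least squares of recorded pupil size on horizontal
and vertical gaze position (`fit_pfe()`), fitted on the ellipse-tracking
calibration recording: 30 s of smooth pursuit of a target moving
counterclockwise around a circle that maps the 20°×20° stimulus field, six
rotations. Interpolated samples are excluded from the fit but still
corrected. The first second is trimmed by default (`trim_ms = 1000`)
because the trial-initiating button press dilates the pupil at the start of
the recording and, being time-locked to a fixed point of the gaze path,
biases the slopes. The correction `Pc = P − b1·X − b2·Y` is applied to both
tasks of the same session — valid only while the recording geometry is
unchanged between tasks, which is why the model is strictly per-session.
The model is planar by construction; no interaction or polynomial terms.

The default in the pipeline is to fit after full preprocessing (repair,
50 Hz, smoothed); fitting at the native rate gives the same estimates up to
the filter's passband ripple since both the gaze path (0.2 Hz) and the
foreshortening component it induces are far inside the passband.

## Fixation selection

Detection is optional: parsed fixation events from the tracker are honoured
when present, and the built-in detector (`detect_fixations()`) exists so the
pipeline is self-contained. It computes velocity and acceleration from
9-sample Savitzky–Golay differentials of the gaze trace and flags samples
exceeding the motion (0.1° over the window), velocity (30°/s) or
acceleration (8000°/s²) thresholds as saccade samples; maximal runs of
non-saccade, non-blink samples become fixations.

The selection chain runs merge → assign → **classify** → duration filters →
boundary exclusions:

- brief fixations (<100 ms) merge into the spatially nearest adjacent
  neighbour if its centre is within 1°, taking the union span and the
  duration-weighted centre, iterating until none remain; otherwise they are
  discarded;
- fixations are assigned to the nearest item centre within 1.25°, ties
  broken by the lowest item id;
- visits are classified on the **full** merged sequence: the first fixation
  on an item is its discovery; a later fixation is a revisit only if gaze
  left the item in between and its onset is ≥1000 ms after the discovery
  onset, otherwise `revisit_short` (never analysed). Classification happens
  *before* the eligibility filters deliberately: a refixation whose initial
  fixation happens to fall inside an excluded window is still a refixation,
  and relabelling it a discovery would corrupt the discovery/revisit
  contrast. Target discoveries are numbered 1–3 within trial by onset;
- the duration filters drop fixations under 120 ms and, using the mean and
  SD of target-fixation durations pooled over the **whole dataset** (not per
  subject — the cap is meant to trim a common tail, and per-subject caps
  with few target fixations would be unstable), any fixation longer than
  mean + 3 SD;
- fixations with onset within 1000 ms of search onset, or later than
  3000 ms before a terminating button press, are excluded (exclusion is by
  fixation *onset*; a fixation that merely overlaps the window boundary
  survives).

Named selections (`select_epoch_events()`) reproduce the analysis contrasts:
all target fixations from 1–3-target trials vs all distractor fixations
from 0-target trials, the discovery/revisit splits of each, and first vs
second target discoveries in multi-target trials. Every selection is
restricted to correctly answered trials.

## Averaging

Epochs span −500:2000 ms around the fixation onset at 50 Hz (126 samples)
and are expressed as %-change from the mean pupil over the 500 ms before
the event; epochs whose window leaves the recording or whose baseline mean
is not positive are rejected with a recorded reason. Overlapping epochs are
retained — de-overlapping would bias the selection toward sparse scanpaths.
Grand averages are subject-first (`unit = "subject"`): epochs are averaged
within subject, then across subjects, so subjects contribute equally
regardless of epoch counts; SEM bands are bootstrap SDs of the mean over
resampled units (5000 iterations by default, seeded).

Whole-trial traces use a single baseline — the mean pupil over the 1000 ms
before search onset — for the onset-locked, search-phase and offset-locked
segments of a trial; the search phase is resampled onto a 101-point
normalised-phase grid by linear interpolation so searches of different
lengths can be compared at equivalent stages. 101 points resolves the 50-Hz
structure of the shortest realistic searches without inventing detail for
the longest. Trials whose baseline is more than half interpolated are
flagged and dropped from condition averages; subjects with an empty cell
are dropped from that grouping.

## Cluster-corrected permutation tests

All contrasts are within-subject, so the permutation scheme flips the sign
of each subject's difference trace. Pointwise statistics are one-sample
*t* values of the differences (df = n−1); the cluster-forming threshold is
the theoretical two-tailed *t* quantile at `cluster_alpha` (default =
α = 0.05); clusters are maximal supra-threshold runs and their statistic is
the mass (sum of *t*). The null distribution is the maximum |mass| over
sign-flip patterns: all `2^n` patterns enumerated exactly when `2^n ≤
n_perm` (n ≤ 10 at the default 1024), otherwise `n_perm` seeded random
draws. Corrected p-values use the add-one convention `(1+k)/(1+N)`, so p is
never zero and the test is valid (slightly conservative) under Monte-Carlo
sampling. In the exhaustive branch each pattern's t-series is computed
through the same code path as the observed statistic so that the identity
pattern reproduces it bit for bit; zero-variance time points yield signed
infinities and are flagged rather than silently clamped.

## The synthetic-session generator

The generator (`sim_config()`, `simulate_ellipse_session()`,
`simulate_search_session()`, `simulate_study()`) reproduces the reference
study conditions: a 30-s ellipse calibration per session; search trials of
2000 ms fixation, 4000 ms mask, up to 10 s of search and a 2000 ms mask; 30
items on a 10×10 grid spanning 20°×20° with the four centre cells excluded
and at most one target per quadrant; 0–3 targets; 18 trials per targets
level per session and two sessions per subject, each session drawing its
own foreshortening plane (b1 ~ N(−0.483, 0.276) truncated negative,
b2 ~ N(0.009, 0.257), around the reference coefficients).

Choices the study description leaves open, fixed once on realism grounds:

- **Pupil noise**: hippus as band-limited Gaussian noise (0.5 Hz, marginal
  SD 20 units = 1% of the 2000-unit baseline) plus white measurement noise
  of SD 0.05 units — video trackers smooth on-line, so sample-to-sample
  noise is far below physiological fluctuation. Slow drift: 0.05 Hz, SD 15.
- **Blinks**: Poisson at 0.15 Hz with ~150-ms closures (pupil = 0), giving
  ~4–5% interpolated data; the recovery artifact is a decaying 125-Hz
  oscillation lasting `artifact_tail_ms` = 140 ms with initial derivative
  amplitude 1000 units/ms — the scale of real eyelid-clearance artifacts,
  and what gives the endpoint-extension rule a well-defined target.
- **Response kernels**: Erlang-family, `(t/tp)^s · exp(s(1−t/tp))` with
  shape s = 4, parameterised by peak amplitude and latency; defaults sit at
  the reported responses (discovery 2.02% at 680 ms, target revisit 3.41%
  at 520 ms, distractor revisit 1.47% at 500 ms), plus a search-onset
  transient (5% at 2000 ms), a press-locked kernel beginning 1000 ms before
  the press (5%, peaking 1200 ms after its start) and a linear search-phase
  load ramp of 5% + 1.8% per target.
- **Behaviour**: truncated-lognormal fixation durations (median 250 ms,
  never below 120 ms — sub-criterion fixations would be merged or dropped
  anyway and keeping them out makes the eligibility ledger exact), 25-ms
  saccades (which always exceed the detection thresholds), a reading-order
  bias in item visit order, 12% revisit probability, and termination on the
  third target discovery or an exhausted array (otherwise timing out at
  10 s) with a 10% response error rate.

The ground truth logs every injected event, blink span (with its artifact
end) and fixation, including each fixation's eligibility under the
selection rules (duration cap pooled within session), so pipeline
selections can be reconciled against the generator's bookkeeping count for
count.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: gaze-measurement error and calibration drift
(fixation positions are exact up to a small placement jitter), saccadic
main-sequence dynamics, pupil responses to luminance, blinks that split
fixations, smooth-pursuit contamination of the search scanpath, and any
nonlinearity of the foreshortening error beyond the planar model.

## Problem sizes used by the test suite

The acceptance checks run the study conditions at desk scale, chosen once:
the endpoint-extension check uses a 450-s trace (≥50 blinks); kernel
recovery uses single-target sessions (360 trials per condition, conditions
{0, 1}) so kernels are isolated, with the foreshortening plane off, since
the check targets the averaging chain, not the correction; the type-I
calibration uses 200 null datasets of 20 subjects × 126 time points at 1024
permutations; the end-to-end check uses ten replicates of a 20-subject,
2-session study with 2 trials per condition per session. `scripts/
acceptance.R` re-runs the same computations at comparable sizes, fully
driven by `--seed`.

## Known limitations

- The endpoint-extension rule inherits the ambiguity of its threshold: on
  traces with substantial white noise the criterion is unreachable and
  every blink extends to the cap. The implementation exposes the window
  alignment and fraction, but the rule itself presumes smooth traces.
- The built-in detector approximates a proprietary parser; with noisy gaze
  it will not reproduce another parser's events exactly, which is why
  precomputed events take precedence.
- `%`-change normalisation divides by a per-epoch baseline; epochs with
  heavily interpolated baselines are retained (only whole-trial baselines
  carry a >50% interpolation flag), matching the reference procedure rather
  than guarding against it.
- The permutation test assumes exchangeability of within-subject difference
  signs; it does not cover between-subject designs.
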