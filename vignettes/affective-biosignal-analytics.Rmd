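---
title: "Affective learning analytics from multimodal biosignals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affective learning analytics from multimodal biosignals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectlytics)
```

## The analysis this package implements

`affectlytics` implements a descriptive affective-analytics pipeline for
educational experiments in which a participant completes two recorded
sessions — a conventional web-based virtual-patient (VP) case that
establishes their personal biosignal baseline, and a mixed-reality (MR)
session — while wearing an EEG amplifier (256 samples/s, Cz/Fz of the 10-20
system) and a wristband recording heart rate (1 sample/s) and electrodermal
activity (4 samples/s).

The pipeline computes four metrics per scenario segment:

* **theta/beta power ratio**: EEG power in theta (4–8 Hz) over power in
  beta (13–21 Hz). Frontal-midline theta rises with working-memory load and
  sustained attention, so an increased ratio indexes cognitive engagement.
* **alpha amplitude** (µV): RMS amplitude of the 8–12 Hz rhythm. Alpha is
  suppressed by attention-demanding engagement and judgement calls, and
  rises in relaxed or guided disengagement.
* **mean HR** (bpm) and **mean EDA** (µS): peripheral arousal indices;
  both rise with sympathetic activation, independent of valence.

Segments are the half-open intervals between consecutive scenario events:
node transitions in the VP session, coordinator gestures in the MR session.
The stretch from session start to the first event is treated as an
orientation period and excluded. The VP segment means are averaged
(unweighted) into a per-participant baseline; MR segment means are averaged
the same way; the per-participant comparison is `delta = MR − baseline`.
Group tables report the arithmetic mean and the **population** SD
(divisor *n*) over participant means. A shift table counts, per group and
in total, participants whose delta moved in the canonical directions
(theta/beta up, alpha down, HR up, EDA up), with strict inequalities on
unrounded deltas — a zero delta counts as neither direction. The study this
mirrors performed no inferential statistics, so neither does the package.

## Time, synchronization, and segmentation

All alignment is timestamp arithmetic on a shared UTC clock, never index
arithmetic: the three devices start recording at different instants (the
synthetic generator staggers them deliberately: EEG at `t0`, EDA at
`t0 + 0.5` s, HR at `t0 + 1.2` s). Sample `k` (0-based) of a stream is
stamped `start_utc + k/rate`, and every window is half-open
`[start, end)`. Half-open windows make slicing a *partition*: cutting a
stream at any ordered boundaries and concatenating the pieces reproduces
the sample sequence exactly, so no sample is counted twice or lost at a
segment boundary. The manual, video-based synchronization step of the
original rig is replaced by a plain annotation-file contract
(`time_utc,label,kind` CSV); clock drift between devices is assumed absent.

## EEG feature extraction

**Artifact rejection.** The segment is split into consecutive 1-s epochs;
an epoch is rejected iff any absolute sample exceeds 100 µV. This is the
simplest defensible stand-in for an unspecified "automatic artifact
removal" stage; both the epoch length and the threshold are exposed in
`eeg_config()`. Surviving epochs are concatenated before spectral
estimation. We analyzed the alternative — estimating each contiguous
artifact-free run separately — and rejected it: every run contributes two
Hann-tapered edges, and with a handful of artifacts per minute the
underweighted edges bias band amplitudes by several percent, while the
splice discontinuities of concatenation are negligible for band-integrated
power under the taper.

**Spectral estimation.** Band power is the integral of a Welch PSD
(Hann windows, 50% overlap, mean-detrended, one-sided, a flush window so
the signal tail is always covered) over the half-open band
`[low, high)` — half-open so the shared 8 Hz edge of theta and alpha is
never double-counted. The default window is **4 s**. At 2-s windows the
0.5 Hz resolution bandwidth is a large fraction of the 4-Hz-wide theta and
alpha bands; spectral smearing past the band edges then biases narrow-band
power low by up to ~10%, which we measured as band-RMS errors up to ~7% on
minute-scale segments. At 4 s (0.25 Hz resolution, ≥16 theta cycles per
window) the same error stays under ~4%. Band *power* carries roughly twice
the relative error of band *amplitude*; the pipeline reports amplitude
(RMS) where a µV quantity is needed.

**Amplitude convention.** Reported "alpha amplitude (µV)" is the RMS of
the band-limited component, `sqrt(band power)` — chosen because it has a
closed-form oracle (a sinusoid of peak A has band power A²/2, RMS A/√2).
The original instrument's internal amplitude metric is undocumented, so
absolute µV comparability with the published tables is not claimed;
a `peak_equivalent` convention (RMS × √2) is available in `eeg_config()`.

**Degenerate inputs.** A segment with no samples, a segment whose epochs
are all rejected, and a beta power at the numeric floor (below machine
precision or below 10⁻⁶ of theta power, a scale-invariant threshold that
only spectral leakage can reach) all yield `NA` plus a classed warning
(`affectlytics_undefined_feature`) — never a silent zero. Downstream,
undefined metrics propagate as `NA` deltas, are excluded from group means,
and classify as `indeterminate`.

## Peripheral features

HR and EDA are summarized as the arithmetic mean and population SD of the
raw samples in the window. EDA deliberately gets no tonic/phasic
decomposition: the comparison this pipeline reproduces operates on mean
conductance, and skin-conductance-response deconvolution is out of scope.

## Aggregation conventions

* Unweighted averaging of segment means (not duration-weighted), because
  the comparison is defined per segment; duration weighting is available
  via `baseline_summary(duration_weighted = TRUE)`.
* Population SD everywhere in group tables (the convention the published
  group table verifiably follows); `pop_sd()` is exported.
* Display rounding is round-half-away-from-zero (`round_display()`), two
  decimals for ratios and µV (three for µS, integer bpm); all comparisons
  and shift counts use unrounded values.
* The shift table's total row is the column sum over groups, always.

## Affect rules

The engagement label is a pure function of the signs of the dead-zoned EEG
deltas: theta/beta up with alpha down is `full_cognitive_engagement`
(working-memory load plus attention-driven alpha suppression); theta/beta
down with alpha up is `guided_disengagement` (the pattern of a fully guided
learner making no judgement calls); both up is `ambivalent_engagement`
(task commitment without full cognitive challenge). Every remaining
pattern — including both-down, for which no established reading exists —
is `indeterminate` rather than a guess. `arousal_elevated` is true when
the EDA or HR delta clears its dead-zone. Dead-zones default to 0 (pure
sign logic, appropriate for group-level qualitative reading); for noisy
single-participant use we recommend dead-zones of the order of the
feature-estimation error (e.g. ~3% of the baseline ratio, ~0.2 µV alpha,
1–2 bpm, 0.05 µS).

## The synthetic-data generator

The generator emulates the sensor rig well enough to give every pipeline
stage a parameter-recovery surface with known ground truth:

* **EEG**: per segment, each band contributes a carrier of exactly the
  specified RMS. The default carrier is white noise confined to the band by
  brick-wall FFT shaping and rescaled in the time domain — the ground-truth
  band energy is then exact and fully inside the integration window, and
  spectral estimation is exercised across the whole band. A pure-sinusoid
  mode (band-center frequency) is retained for analytic oracles. The
  background is 1/f noise of configurable RMS. Artifacts are
  rectangular-windowed half-sine transients, 0.2–0.5 s wide, at least 5×
  the largest band amplitude and at least 600 µV, injected at seeded times
  that are returned as ground truth.
* **EDA**: piecewise-constant tonic level per segment with a 5-s linear
  ramp at each boundary (a full-segment ramp would destroy the segment-mean
  ground truth), plus the requested number of phasic responses per segment:
  bi-exponential pulses (1-s rise, 4-s decay) with peak amplitudes drawn
  uniformly in [0.1, 0.5] µS at stratified onsets. Samples are clamped
  non-negative.
* **HR**: per-segment level, Gaussian per-sample jitter (SD 2 bpm), a slow
  sinusoidal drift (1 bpm, 120-s period), clamped to [30, 220] bpm.

All randomness flows from one master seed through a named substream per
modality, so regenerating one modality never perturbs another. What the
generator does **not** emulate: volume-conducted or ocular artifact
topographies, heart-rate variability structure, SCR shape variability,
non-stationary drifts within a segment, or inter-device clock drift.
Passing recovery tests therefore demonstrate correctness of the signal
processing and aggregation, not robustness to every pathology of real
recordings.

`synthetic_cohort()` builds the cohort used by the recovery tests:
6 participants (groups cycling student/postgraduate/neurosurgeon), two
sessions each of 4 × 120-s segments — matching the pacing of a roughly
ten-minute case traversed through a handful of scenario events — with 1/f
noise at 10% of the weakest band's RMS, artifacts at 2/min, and
baseline-to-MR effects (±30–70% on band powers, ±8 bpm, ±0.8 µS) far above
the ~4% feature-estimation error, cycling through the three engagement
archetypes. At these sizes the full cohort runs in seconds; the 120-s
segment length is what a Welch estimator needs for the ~4% ceiling (at
30-s segments the realization variance alone reaches ~7%).

## Worked example

```{r example, eval = FALSE}
library(affectlytics)
library(dplyr)

# a participant with a known engagement pattern
coh <- synthetic_cohort(seed = 1, n_participants = 3)
p <- coh$participants[[1]]
summ <- summarize_participant(p$vp, p$mr)
summ

# cohort aggregation and interpretation
summaries <- bind_rows(lapply(coh$participants, function(p) {
  summarize_participant(p$vp, p$mr)
}))
group_summary(summaries)
shift_table(summaries)
classify_groups(group_summary(summaries))
```

## Known limitations

* Absolute reproduction of published per-participant EEG magnitudes from
  raw signals is not claimed (instrument-internal preprocessing is
  undocumented); published values enter the pipeline as per-participant
  means at the aggregation stage.
* The published tables the reference fixtures transcribe contain internal
  inconsistencies (a handful of group cells and shift totals do not equal
  the aggregate of their own per-participant rows); this package always
  reports the recomputed aggregate and treats the discrepant printed cells
  as logged discrepancies.
* Band-power estimates on segments much shorter than ~60 s carry >5%
  uncertainty for the 4-Hz-wide bands; interpret per-segment EEG values on
  short segments with care.
* No drift correction between device clocks; UTC stamps are trusted.
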