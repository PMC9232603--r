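---
title: "Monitoring heel-raise exercise from smart-insole signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring heel-raise exercise from smart-insole signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heelraiser)
```

## The problem

Heel raises are a staple exercise in rehabilitation of chronic ankle
instability (CAI): they strengthen the peroneus longus (PL), the lateral
lower-leg muscle that supports the weakened lateral ligaments. The catch is
posture: the PL is recruited strongly only when the raise is performed with
ankle *eversion*; with *inversion* the plantar flexors still work but the PL
largely does not, and the inversion pattern itself is what a CAI patient
should avoid. Unsupervised home training therefore needs a way to tell the
two apart.

A low-cost pressure-sensing insole — four force-sensing resistors (toe,
heel, 1st and 4th metatarsal heads) plus a 3-axis accelerometer at 30 Hz —
carries enough information for this. `heelraiser` implements the complete
analysis chain: repetition segmentation, phase splitting, pressure/EMG
feature extraction, phase-percent ensemble statistics, and
eversion/inversion (EV/IV) classification, together with a synthetic
session generator so every stage is testable without recordings.

## Signals and conventions

* **Pitch** (degrees) is rotation about the medio-lateral axis: 0 = flat
  foot, positive = heel up. **Roll** is rotation about the long axis of the
  foot: positive = eversion, negative = inversion. Both conventions are
  fixed here because published plots rarely state them numerically.
* **Channel-to-anatomy map**: `F1` = toe, `F2` = 1st metatarsal head
  (medial forefoot), `F3` = 4th metatarsal head (lateral forefoot),
  `F4` = heel. The map is chosen so the medial partial pressure formula
  below reads directly off the channel names.
* The insole stream is the **master clock** (30 Hz). Orientation and
  grid-COP streams are interpolated onto it; EMG keeps its native rate
  (configurable, default 2000 Hz) and only event boundaries are mapped
  across clocks, by nearest sample. EMG is never down-sampled before
  feature extraction.

When no orientation stream is available, pitch is estimated from the
accelerometer as `asin(ay / |a|)` (degrees), low-pass filtered at 3 Hz
(2nd-order Butterworth, zero-phase, with odd-reflection padding to avoid
edge transients). During rise and drop the foot accelerates, so the
surrogate is biased there; but its extrema coincide with the true pitch
extrema, which is all segmentation needs.

## Segmentation

Events are found with a **threshold on pitch** (default 5°, hysteresis 2°
against chatter); events shorter than 1 s are discarded, events separated
by less than 1 s merged, and windows extended outward to the nearest local
pitch minimum so the full rise onset and drop completion are contained.

Phases come from the **pitch gradient** (central differences of a
zero-phase moving average, window 0.3 s). The rise is the largest positive
gradient peak, the drop the largest negative peak after it. Each of the
four boundaries is refined to the time where the gradient crosses **half of
the respective peak value**. The reason for half-peak rather than a fixed
gradient level: for any pitch profile whose slope transition is symmetric
about the underlying trapezoid corner — an ideal piecewise-linear corner
seen through a symmetric smoother, or a cosine-tapered corner — the
half-peak crossing sits *exactly* at the corner, independent of the
smoothing width and of the phase durations. A fixed level (say 3 °/s) is
instead biased by up to half the smoothing width, which is several samples
at 30 Hz. The absolute gradient threshold (default 3 °/s) is still used as
a validity gate: an event whose peak |gradient| never reaches it is
reported with `valid = FALSE` rather than given meaningless phases.

All thresholds are configurable via `segmentation_config()`; the defaults
sit far below a typical ~25° heel-raise excursion and far above idle noise.

## Features

* **Waveform length (WL)**, the EMG envelope:
  `WL(t) = sum_{n=t-N+2}^{t} |x(n) - x(n-1)|` — the sum of the `N - 1`
  absolute successive differences ending at sample `t`. Output is
  window-end aligned (causal); the first `N - 1` samples are undefined.
  Centre alignment was rejected: a causal envelope is what a biofeedback
  loop could actually compute. `N` defaults to 0.25 s at the EMG rate.
  WL is positively homogeneous and translation invariant, which the test
  suite verifies; magnitudes are not comparable between subjects (see
  normalisation below).
* **Medial partial pressure**: `MPP = 100 * F2 / (F2 + F3)` percent. When
  the combined forefoot load falls below a floor (default 1 % of the
  session's 95th-percentile forefoot load) both sensors are effectively
  unloaded and the ratio is reported as `NA` instead of a meaningless
  division. MPP is invariant to the unknown FSR calibration (any common
  scale factor cancels), so device units never need converting.
* **Medio-lateral COP**: `ML COP = 100 * (W - COPx) / W` percent of the
  insole width `W`, computed from a grid-pressure insole. The formula is
  implemented exactly as defined by the reference system. Note the sign
  convention is arguable — with `COPx` a medial coordinate the expression
  reads as a lateral-referenced fraction — and is deliberately kept
  verbatim rather than "corrected", so values remain comparable with that
  system; the ambiguity is flagged here instead of silently resolved.
* `cop_from_grid()` collapses a sensor row to a COP coordinate by
  force-weighted mean position, `sum(x_i F_i) / sum(F_i)`.

`phase_features()` reduces everything to one row per event × phase
(rise/hold/drop): arithmetic means over the phase's samples, with
undefined MPP samples excluded, and WL means computed on the EMG clock
over the nearest-sample-mapped phase interval. Phase membership uses
nearest-sample index ranges rather than floating-point time comparisons,
so a sample sitting exactly on a corner cannot flip phases through
round-off.

## Ensemble statistics

Even cued sessions vary in phase duration, so traces are compared on a
**phase-percent axis**: each phase is linearly resampled onto
`points_per_phase` (default 100) equally spaced fractions of its own
duration and the phases concatenated rise → hold → drop. Allocation is
equal per phase, not duration-proportional, matching how such plots are
conventionally drawn. The across-event pointwise mean and sample SD
summarise a session (`ensemble_trace()`); a single event has SD 0.

Between-subject EMG comparison divides each subject × muscle WL value by
that subject's mean rise-phase WL (`normalize_emg_to_rise()`). The
denominator pools all conditions present for the subject by default; a
`per-condition` mode exists because the pooling choice is genuinely open —
the choice used is recorded in the result's `denominator` attribute.

## Classification

Each event × phase contributes a point on the (MPP, roll) plane. Two
boundary kinds are provided:

* `mpp_threshold` — a single vertical line at the midpoint of the class
  mean MPPs. Works within a subject; across subjects the MPP operating
  ranges shift enough that one line fails, which is precisely the argument
  for per-subject calibration.
* `linear_2d` — a two-class linear discriminant on (MPP, roll) with equal
  priors and pooled within-class covariance, written in closed form so the
  boundary weights and offset are inspectable and serialisable. This is
  the minimal linear rule that adds foot orientation to pressure, and it
  separates the classes pooled across subjects and across single/double
  leg conditions.

Ties (a point exactly on the boundary) are labelled IV: in rehabilitation a
false "improper posture" flag is the safer error. Event labels are the
majority over the event's three phase points; a rise-only mode is available
via `event_points(phases = "rise")` since PL recruitment is decided during
the concentric rise.

`fit_linear_relation()` (ordinary least squares, `R^2 = 1 - SSE/SST`)
quantifies how well the accelerometer channels track the reference angles;
a constant response is reported as degenerate rather than `R^2 = 1`.

## The synthetic generator

`generate_session()` emulates the cued protocol: per repetition, idle,
rise, hold and drop durations are drawn around 5, 1, 3 and 1 s with a
coefficient of variation of 0.08 (a plausible spread for metronome-cued
movement). The pitch is a trapezoid (default peak 25°, a plausibility
choice — it only needs to clear the detection threshold by a wide margin)
whose corners are smoothed by 0.2 s cosine slope tapers *centred on the
corner times*; the profile is built from the taper's closed-form integral,
so the plateau and the return to zero are exact and the programmed corners
are exactly recoverable by the half-peak rule. Variant morphology:

| quantity | eversion (EV) | inversion (IV) |
|---|---|---|
| roll excursion during rise | +5° | −10° |
| MPP idle → hold | 55 → 75 % | 45 → 25 % |

These profile values are stand-ins chosen to be qualitatively faithful
(medial shift under eversion, lateral under inversion); no published
numeric MPP/roll values exist to copy. Forces keep a constant total load;
the heel channel unloads quadratically with pitch fraction; forefoot
channels are split so the instantaneous MPP follows the programmed
baseline→raised interpolation exactly in the noiseless case — which makes
generator and feature module mutually checkable to machine precision.
Accelerometer channels are the static gravity projection of the noiseless
angles plus band-limited motion bursts (damped 4 Hz oscillations during
rise and drop) and Gaussian sensor noise.

EMG is amplitude-modulated Gaussian noise — a standard surrogate, since WL
responds to envelope amplitude; no motor-unit model is attempted. Gains
(see `default_emg_gains()`) encode the recoverable contrasts: PL rise gain
0.12 mV under EV versus 0.03 mV (and 0.4 s onset delay) under IV; GM/GL
indifferent to orientation but scaled ×1.6 under single-leg load (the
factor is a free default, not a measured value); soleus with a modest
orientation effect. Activation peaks in the rise and decays through hold
and drop.

`generate_cohort()` adds subject-level offsets to the MPP baselines and
the roll excursion. The default MPP offsets are laid out on quantile-spaced
positions spanning ±20 % (plus N(0, 3) jitter), roll offsets N(0, 1.5°).
The stratified layout was chosen over i.i.d. Gaussian draws deliberately:
it emulates the pronounced between-subject scatter of a small cohort
*representatively* at n = 5, so the phenomenon the package must reproduce —
within-subject EV/IV separation intact while one pooled MPP threshold
fails — is a stable property of the generator rather than a coin flip over
seeds. Offsets are shared between a subject's conditions, as a subject
trait.

**What the generator does not emulate:** FSR nonlinearity and hysteresis,
clock drift between devices, fatigue across repetitions, motor-unit
structure in the EMG, balance corrections in single-leg stance beyond the
generic motion bursts, and residual structure in the accel-versus-angle
relation beyond those bursts. Passing tests on synthetic data therefore
demonstrate algorithmic correctness (boundary recovery, equation-level
accuracy, the programmed contrasts), not field performance on patients.

## Numerical choices and degenerate inputs

* Zero-phase smoothing everywhere a boundary time is at stake; odd
  moving-average windows so the smoother is symmetric.
* Jittered phase durations are floored at max(2.5 × taper, 0.25 s) so
  corner transitions stay resolvable; a draw at or below zero triggers a
  warning and a redraw.
* `linear_2d` adds a ridge of 1e-8 × trace to the pooled covariance so
  duplicated or collinear calibration points do not crash the solve.
* Monotone ramps without a completed drop give a degenerate zero-length
  drop with a warning; events without a supra-threshold rise are flagged
  invalid; a trace shorter than `min_event_s` warns and returns no events.
* Round-trip file I/O writes 12 significant digits, comfortably inside the
  1e-9 relative reproduction the I/O tests demand.

## Problem sizes used by the test suite

The suite exercises the pipeline at the protocol's own scale: sessions of
five repetitions (~55 s at 30 Hz, EMG at 2000 Hz where needed), 20 seeded
replicates per variant for event-count stability, 100 replicates for the
noise-robustness property (without EMG, which is irrelevant to
segmentation), a 5-subject × 4-variant cohort for the calibration and EMG
contrast checks, and 1000-case random sweeps for the equation-level
oracles. These sizes keep the full suite under a minute while leaving the
statistical margins of the checks wide.

## A worked run

```{r example}
gs <- generate_session(synthesis_params(variant = "DL-EV", seed = 1))
events <- segment_session(gs$session)
round(as.data.frame(events)[, c("rise_s", "hold_s", "drop_s",
                                "preceding_idle_s")], 3)

feats <- phase_features(gs$session, events)
round(subset(feats, phase == "hold",
             c(event_index, mean_mpp_pct, mean_roll_deg)), 2)
```

The detected durations recover the cued 5/1/3/1 s protocol up to the
programmed jitter, and the hold-phase MPP sits at the programmed eversion
plateau (75 %) up to sensor noise.

## Known limitations

* The EV/IV boundary is linear by design; strongly nonlinear per-subject
  structure would need a different classifier and is out of scope.
* The accel pitch surrogate is biased during rise/drop (true acceleration
  adds to gravity); only its extrema and crossings are trustworthy, which
  suffices for segmentation but not for angle-accurate kinematics.
* The ML COP sign convention follows the defining grid-pressure system
  verbatim; compare magnitudes and trends, not the medial/lateral naming.
* Constant-lag synchronization only; clock drift correction is a non-goal.
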