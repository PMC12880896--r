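---
title: "Landing stabilisation and muscle activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landing stabilisation and muscle activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landstab)
```

`landstab` analyses gymnastics landings recorded with a lower-back IMU and
six-channel lower-limb surface EMG, within a fully within-subject design:
every subject performs every motor task (DL, SB, SF, AS) under both gaze
instructions (down, ahead), two to three repetitions per cell. This vignette
is the package's own account of the models, the parameters that matter, the
synthetic-data generator, and the numerical and design choices.

## The measurement model

A body-worn accelerometer measures specific force: about +1 g vertical in
quiet upright stance, about 0 g in free fall. A landing trial therefore has
a characteristic shape: stance, one or two flight phases of near-zero
specific-force magnitude, a sharp impact transient as the feet strike, a
damped oscillation as the body absorbs the impulse, and a return to quiet
stance. All stabilisation quantities are anchored on **contact time**,
defined as the first local peak of vertical acceleration above a threshold
after the end of the *last* flight phase — the acrobatic series (AS)
contains an earlier flight (round-off/handspring) that must not be mistaken
for the landing flight.

### Contact detection parameters

| parameter | default | units | rationale |
|---|---|---|---|
| flight magnitude threshold | 0.3 | g | well above sensor noise (~0.02 g), well below stance (1 g) |
| minimum flight duration | 0.08 | s | rejects transient dips during ground contact |
| impact peak threshold | 2 | g | landing impacts at lower-back level are several g |
| search horizon after flight | 0.2 | s | impact follows flight end within one spike width |

These are free parameters with sensible defaults: the detection *rule*
(last flight, then first supra-threshold vertical peak) is the fixed part;
the constants are exposed as arguments of `detect_contact()`.

## Stabilisation indices

Each of the six IMU channels is low-pass filtered (4th-order Butterworth,
30 Hz, applied forward and backward so the phase is zero and peaks do not
move), windowed over 3 s and 1 s after contact, and zeroed by subtracting
the mean of the window's final 0.5 s (3-s window) or 0.25 s (1-s window) —
deviation is measured from *terminal quiet stance*, not from a grand mean.

The **dynamic stability index** is the root-mean-square deviation of the
zeroed segment from zero, in the channel's own units (g or deg/s). It is
scale-equivariant (`dsi(c*x) = c*dsi(x)`) and time-reversal invariant, both
asserted in the tests.

The **time to stabilisation** uses the sequential (cumulative) average
`s_k = mean(x_1..x_k)` with threshold `T = 0.25 * SD` of the same quiet tail
used for zeroing: TTS is the earliest time after which the sequential
average stays inside `[-T, T]`. Many variants of this family exist; the
package fixes the cumulative-average/quiet-tail-SD/zero-reference variant as
default and exposes `variant = "series_sd"` (threshold from the whole
segment's SD) as a named alternative. The reference level is 0 rather than
the series mean because the segment is explicitly zeroed first. Two bounded
conventions keep the output well-defined: if the condition is never met the
window length is returned and flagged `censored`; a zero threshold with
non-zero signal is censored with a warning.

A consequence worth knowing: with the strict quiet-tail threshold, TTS is
finite only when the windowed signal has near-zero net area (the cumulative
average converges to the windowed mean). For the vertical channel the
analysis window opens at the impact peak, so roughly half the loading lobe
is inside the window; even with an area-balancing unloading phase, the
filter-edge residue (~0.005 g in the synthetic regime) can exceed the
threshold (~0.002 g), and vertical 3-s TTS then censors at the window
length. This is a property of the variant, not a bug; the series-SD variant
resolves it, and censoring rates are reported in the run manifest.

## EMG activity patterns

Processing order is fixed: resample to 1000 Hz, band-pass 30-350 Hz,
full-wave rectify, quality-screen, normalise, integrate. Notes on each step:

- **Resampling** (1926 or 1111 Hz to 1000 Hz) is cubic-spline interpolation
  onto the uniform output grid. 1111 to 1000 is a non-integer ratio, so
  decimation is unavailable; interpolation preserves envelope timing, which
  is what the ±300 ms windows depend on (impulse relocation under 1 ms,
  asserted in tests).
- **"Bidirectional 4th order"** is read as: design order 4, apply forward
  and backward — zero phase, effective order 8.
- The **quality screen** (exclude above 3 mV, or on saturation/flatline
  artefacts) is applied to the *raw* signal: 3 mV is an electrode-level
  physical bound, so screening after filtering would test the wrong
  quantity. Saturation is operationalised as ≥ 50 consecutive samples
  within 0.1% of the global extremum, flatline as ≥ 200 consecutive
  identical values.
- **Normalisation** divides all of a participant's processed signals (per
  muscle) by the maximum processed amplitude over that participant's AS
  trials, pooling both gaze conditions. The maximum is taken within the
  -300..+300 ms analysis window by default ("observed during AS" is read as
  observed in the analysed window); `whole_trial = TRUE` switches to the
  whole recording.
- **Integration**: 30 non-overlapping 20-ms windows spanning -300..+300 ms,
  node 16 opening exactly at the contact sample; node value = sample sum ×
  1 ms (rectangular rule — at a fixed 1000 Hz rate the trapezoid correction
  is below 0.1% and is not offered). A constant normalised signal of 1
  yields nodes of exactly 0.020.

Normalisation must precede integration: the divisor is defined on the
signal, not on node values, and a participant-level scale factor commutes
with integration while a pattern-level maximum does not.

## Scalar statistics

Repetitions are averaged per subject × task × gaze cell before testing
(standard for repeated-measures designs with unequal repetition counts);
empty cells are an error, never imputed. The two-way fully within-subject
ANOVA decomposes, for subject i, task j, gaze k:

```
Y_ijk = mu + S_i + T_j + G_k + (TG)_jk + (ST)_ij + (SG)_ik + e_ijk
```

and tests each fixed effect against its own interaction with subject:
`F_task = MS_task / MS_task:subject`, `F_gaze = MS_gaze / MS_gaze:subject`,
`F_int = MS_TG / MS_TG:subject`, with `df_den = df_num * (n - 1)`. The
engine is a direct sums-of-squares computation, vectorised over response
columns (the SPM layer evaluates it at 30 nodes at once); tests verify exact
agreement with `stats::aov` error strata and exact SS conservation. Effects
whose SS are at the cancellation-error floor (constant data) report F = 0,
p = 1. No sphericity correction is applied by default (Greenhouse-Geisser
is available behind `gg_correction = TRUE`; its epsilon uses the Box formula
on the double-centred covariance and, for the interaction, an approximation
on the cell covariance).

Post hocs are paired t-tests on subject-level condition means with
Bonferroni adjustment `min(1, m p)`: task marginals (m = 6), gaze marginals
(m = 1), or all 8 cells (m = 28); a slice-wise reading (task pairs within
each gaze plus gaze contrasts within each task, m = 16) is provided by
`interaction_simple_effects()` for interaction follow-up. Degenerate paired
samples follow stated conventions: identical samples give difference 0,
p = 1; zero-variance non-zero differences give p = 0.

Normality screening is a one-sample Kolmogorov-Smirnov statistic against a
normal with estimated mean and SD; because parameters are estimated, the
p-value is Lilliefors-corrected by seeded Monte Carlo (default 10^4 draws).
The pipeline screens the cell-centred residuals per outcome (the
distributional assumption of the model), and reports a degenerate flag
instead of a p-value for zero-variance outcomes (e.g. fully censored TTS).

## Waveform statistics (SPM)

The 30-node patterns are tested with the same within-subject ANOVA at every
node, giving an F-curve per effect. Family-wise inference across nodes uses
the **max-F permutation** approach rather than random-field theory: no
smoothness estimation, exact by construction up to Monte-Carlo error.
Exchangeability is respected within subject:

- *gaze*: the two gaze cells are swapped or not, independently per
  (subject, task) — 2^(n·a) distinct relabelings;
- *task*: task labels are permuted independently per (subject, gaze);
- *interaction*: estimated main effects are subtracted first, then whole
  cells are permuted within subject — a residualised, approximate restricted
  permutation (documented as such).

The critical value F* is the (1 - alpha) quantile of the permuted max-F
sample (default 1000 permutations, seeded); clusters are maximal runs of
nodes with F > F*, and each cluster's p is the fraction of the null sample
reaching its peak F. Exact enumeration is available for the gaze effect at
small designs and is verified against a brute-force enumeration in the
tests. F* is non-increasing in alpha, and `alpha = 1` marks every node.

## The synthetic-data generator

The generator emulates the study design (18 subjects × 4 tasks × 2 gaze ×
3 repetitions by default) and the signal structure the analysis assumes:

- IMU: stance (vertical ≈ 1 g + noise), task-specific flight(s) (≈ 0 g),
  a loading half-sine of task-specific amplitude peaking at contact with an
  area-balancing unloading undershoot (amplitude A/4, width 2w), then a
  damped oscillation `A e^(-t/tau) sin(2 pi f t + phi)` per channel with the
  zero-integral phase `phi = -atan(2 pi f tau)`. The area balancing reflects
  how a settling body absorbs the landing impulse; it is also what makes the
  sequential-average TTS finite (see above).
- AS trials carry a first flight and an intermediate ground contact before
  the landing flight (a flag drops the first flight, as the series can be
  performed without the handspring).
- EMG: per muscle, a Gaussian carrier band-limited to 30-350 Hz at the
  native rate — so the downstream band-pass is approximately transparent and
  envelope-level tests are isolated from filter effects — multiplied by a
  burst envelope that rises a task- and muscle-specific lead time before
  contact (forward somersaults drive earlier posterior-chain preactivation,
  backward somersaults earlier tibialis/rectus activity) and decays after.
- Heterogeneity: log-normal subject-level and repetition-level amplitude
  factors; task effects and the (default-zero) gaze effect are proportional
  shifts of the oscillation amplitude, so one scalar moves all six channels
  coherently despite their different units.
- Determinism: every stream's seed is a stated hash of (master seed,
  subject, task, gaze, repetition, stream), so identical configurations are
  bit-identical and adding trials never perturbs existing ones.

Ground truth per trial records the contact time, flight intervals, the
closed-form damped-sinusoid RMS per channel over the 3-s window (the
vertical channel additionally carries the impact tail, which the
narrow-impact noise-free test configuration keeps below its 2% tolerance),
and the true EMG envelope onsets.

What the generator does *not* emulate: postural sway and low-frequency
drift in quiet stance, sensor saturation and motion artefacts (the QC path
is exercised by injected amplitudes instead), soft-tissue resonance
differences across channels, gaze-dependent EMG timing, and any
musculoskeletal dynamics. Passing tests therefore demonstrate that the
pipeline recovers what it is designed to recover under the assumed signal
structure — not that the defaults match any particular cohort's landing
heights or impact magnitudes, which are free parameters here.

## Problem sizes and tolerances

The simulation-based checks use sizes chosen to make their Monte-Carlo
error small relative to the asserted bands: ANOVA reference agreement on 50
seeded tables at 1e-8; null gaze rejection over 1000 replicates at n = 18
(asserted within 5% ± 2%); SPM family-wise error over 200 replicates of 500
permutations at n = 8, 30 nodes (within 0.05 ± 0.02); contact recovery over
500 trials (≥ 95% within ±5 ms); TTS oracle agreement on 200 segments
(exact); KS calibration with reduced Monte-Carlo depth (the calibration
properties are size-independent). The full end-to-end study (432 trials,
1000 permutations per effect and muscle) completes in a few minutes on one
CPU.

## Known limitations

- Vertical-channel TTS censors at the 3-s window under the default
  quiet-tail threshold variant (discussed above).
- The interaction permutation is approximate (residualised); its size is
  slightly off exact for small n.
- The Greenhouse-Geisser option for the interaction uses an approximate
  epsilon; the default analysis applies no sphericity correction.
- `aggregate_reps()` requires a complete design; subjects missing cells
  must be excluded by the caller (the SPM stage drops incomplete subjects
  per muscle automatically and logs it).
- The benchmark against a recorded cohort requires the corresponding
  dataset; `gaze_marginal_differences()` computes the gaze-condition
  marginal differences the package reports for any study table built from
  such data.
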