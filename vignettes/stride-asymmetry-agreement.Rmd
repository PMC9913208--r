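---
title: "Quantifying vertical movement asymmetry and two-system agreement in trotting horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertical movement asymmetry and two-system agreement in trotting horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

## The measurement problem

At trot, a horse's head and pelvis trace a double sinusoid in the
vertical: each stride produces two peaks (push-off) and two valleys
(impact), one per diagonal step. A sound horse loads both diagonals
equally and the two peaks and two valleys match; a lame horse unloads
the painful limb, and the mismatch between the two valleys (`MinDiff`)
and between the two peaks (`MaxDiff`) is the standard objective lameness
indicator. Because horses differ in size and sensors differ in scale,
the differences are normalised by the stride's range of motion
`R = max(p1, p2) - min(v1, v2)`:

$$V_i = \frac{v_{i+1} - v_i}{R_i}, \qquad P_i = \frac{p_i - p_{i+1}}{R_i}.$$

`equigait` implements the full processing chain from raw keypoint
trajectories to these normalised extreme-value differences (NEVd), and
the statistics used to judge whether two measurement systems — in the
motivating use case a markerless smartphone application (`sc`, 60 Hz)
against marker-based optical motion capture (`mc`, 200 Hz) — agree well
enough to be used interchangeably.

## Processing chain

1. **Stride splitting** (`prefilter_hoof()`, `split_strides()`). Hoof
   trajectories are band-pass filtered to the trot band (0.6–2.2 Hz,
   7th-order Butterworth prototype, zero phase). The zero crossings of
   left-minus-right hoof height mark half-stride boundaries; their mean
   length gives the stride frequency. Fore and hind pair estimates are
   averaged when both exist. Crossing intervals shorter than 0.15 s are
   treated as chatter and merged.
2. **Stride-scaled band-pass** (`bandpass_vds()`). Head/pelvis signals
   are filtered to `[0.75 f_stride, 2.42 f_stride]` (10th-order
   prototype): the band keeps the first harmonic (the asymmetry carrier
   at the stride frequency) and the second harmonic (the symmetric
   double oscillation) while removing baseline wander and higher
   harmonics.
3. **Synchronisation** (`estimate_shift()`). The two systems are
   triggered manually, so their clocks differ by one unknown offset. It
   is recovered by maximising the sum of the normalised
   cross-correlations of the head and pelvis signals across systems,
   with parabolic refinement of the discrete peak.
4. **Extremum extraction** (`extract_extrema()`, `robust_extrema()`).
   In marked lameness the large first harmonic can swallow one local
   extremum per stride. The robust method high-passes above
   `1.5 f_stride` to isolate the second-harmonic curve shape, finds its
   extrema, and then takes the most extreme value of the original
   signal within ±50 ms of each candidate.
5. **Segmentation and metrics** (`segment_strides()`,
   `stride_metrics()`). A stride segment runs peak-to-second-next-peak
   and contains two peaks and two valleys.
6. **Quality control** (`flag_hf_noise()`, `remove_outliers()`,
   `exclude_trials()`). See below.
7. **Agreement statistics** (`stride_deviations()`, `trial_summary()`,
   `dataset_summary()`, `rmsd_pair()`, `bland_altman()`).

## Design decisions in detail

**Zero-phase filtering.** All filters are applied forward–backward.
Peak and valley *timing* feeds the metrics directly; a causal filter
would delay extrema by tens of milliseconds and bias the stride
segmentation. The quoted orders (7th, 10th) are the orders of the
low-pass prototypes.

**Second-order sections.** Both stride filters have very narrow
normalised bands (at 200 Hz the band-pass spans ≈1 % of the Nyquist
range), where the direct transfer-function polynomial form is
numerically singular — coefficients overflow and the output is NaN. The
design is therefore kept in zero-pole form (analog Butterworth
prototype, band transform, prewarped bilinear transform) and realised
as cascaded biquads. The implementation agrees with an independent
reference implementation to < 0.01 mm away from the edges and matches
the closed-form prewarped magnitude response, which the test suite
checks at multiple frequencies.

**Edge handling.** The first and last 1.5 stride periods of every
filtered signal are flagged (attribute `edge_s`) and excluded from
extremum extraction; transients of a narrow band-pass decay slowly and
would otherwise contaminate the first and last stride.

**Synchronisation normalisation.** The joint objective sums
*variance-normalised* correlations per body part, so the head (larger
amplitude, more coverage) cannot out-vote the pelvis purely by scale.
The intended reading of the joint criterion is joint agreement, not
amplitude weighting. A single global shift is estimated per trial:
recordings are tens of seconds, leaving no room for measurable clock
drift.

**Side anchoring.** Which of a stride's two halves is "left" determines
the sign of `MinDiff`/`MaxDiff`. The segmentation phase is chosen so
that each segment's first valley falls inside a left-fore-hoof-high
interval from the stride splitter, and the reference system's intervals
are expressed in its clock via the estimated shift, so both systems use
the same convention within a trial.

**High-frequency noise rule.** A stride is discarded when, in at least
one quarter of the stride interval, the majority of the frequency
content lies above 10 Hz. Two implementation choices deserve note.
First, "majority of the frequency content" is read as *power*
dominance: amplitude-bin counting scales with the number of DFT bins
and would flag clean high-rate signals on measurement noise alone.
Second, the 10 Hz split is computed by filtering the whole stride slice
(zero-phase low-pass) rather than by windowed DFT: a quarter-stride
window is a fraction of a second, its bin width exceeds 5 Hz, and trot
harmonics leak above the cut. Only the constant level is discounted on
the low side — the within-window trend of the displacement curve is
genuine sub-10 Hz content (a quarter stride is roughly one monotone
half-lobe of the second harmonic, so detrending it away would leave
almost nothing to compare against). The rule runs on the *raw* stride
slice: the band-pass removes precisely the content the rule looks for.

**Feature-space outlier removal.** Each stride is represented by the
four differences (`MinDiff`, `MaxDiff`, `p1 − v1`, `p2 − v2`). The
discriminant-analysis step described for the original system is not
reproducible from its published description (no classes, training data
or threshold are specified), so the package substitutes a documented
robust rule on the same features: location and scatter are estimated
from the central 75 % of strides (smallest classical Mahalanobis
distances), the scatter is rescaled by the Gaussian consistency factor
for that trimming fraction, and strides beyond the χ²(4) 0.975 quantile
are removed — at most 20 % of strides, largest distances first, and
never below 8 strides. A singular scatter falls back to per-feature
robust z-scores (|z| > 3.5).

**Trial exclusion.** A trial with fewer than 10 matched strides for
either body part is excluded from both analyses ("fewer than 10"
excludes 9 and below).

**Geometric scale.** Trial summaries multiply the dimensionless NEVd by
the trial-mean reference range of motion, so all reported agreement
numbers are in mm of vertical displacement; the dimensionless values
remain available in the per-stride tables. Standard deviations are
sample SDs (n − 1).

## The trial simulator

`generate_trial()` stands in for horses, cameras and the keypoint
tracker. Its latent signal is exactly the family the analysis assumes —
a dominant second harmonic plus a first harmonic — with the coefficient
pair solved numerically (Nelder-Mead on a dense-grid evaluation) so the
latent's true `V` and `P` equal requested targets and its range of
motion a requested value. On top of this skeleton it reproduces the
features of a real trot-up that the pipeline must survive:

* per-stride period jitter (SD 3 % of the period, as a monotone cubic
  phase map so the signal stays smooth) — real horses do not trot like
  metronomes, and without this quasi-periodicity the trigger offset
  would only be identifiable up to a whole stride period;
* per-stride fluctuation of the first-harmonic amplitude (SD 12 % of
  the second-harmonic amplitude), which produces within-trial metric
  SDs of roughly 5–10 mm, inside the 3.1–28.1 mm range of the bundled
  reference tables;
* a per-pass amplitude envelope (±8 %) mimicking speed changes between
  runway passes;
* white measurement noise per system (defaults 1 mm mc, 2 mm sc), a
  20 mm baseline wander at 0.1 Hz, and a planted trigger offset
  (default 0.5 s);
* four hoof signals phased so diagonal pairs move together, which also
  fixes the side convention;
* pelvis sc data only during "away" passes (a single camera sees the
  pelvis only from behind), with pass lengths chosen so the
  head:pelvis matched-stride ratio resembles the bundled tables
  (≈ 28:16);
* high-frequency bursts (15–25 Hz, quarter-stride, 3× the symmetric
  amplitude) on a configurable fraction of sc strides, emulating
  tracking glitches.

`oracle_nevd()` evaluates the noiseless latent on a 0.1 ms grid and
extracts extrema through the same second-harmonic window construction,
giving exact per-stride ground truth for any asymmetry, including the
severe regime (first harmonic > 2× second) where a raw peak/valley pair
merges and disappears.

What the simulator does **not** emulate: keypoint-detector error
structure (pixel-correlated, occlusion-driven), perspective and
distance effects, gait irregularities such as breaks into canter, and
real biological waveform variety beyond two harmonics. Passing
simulation tests therefore demonstrates correctness of the signal
processing under the model's assumptions, not field performance of any
tracking system.

## Numerical choices

* Resampling between rates is linear interpolation at the finer rate;
  samples inside data gaps contribute nothing to the synchronisation
  objective.
* RMSD resamples each stride at 101 equally spaced points between its
  own first and third peak; the single-camera curve is rescaled by
  `R_mc / R_sc` before differencing. RMSD therefore also absorbs
  residual synchronisation and peak-quantisation error, not pure shape
  difference.
* Plateaus of equal samples yield one extremum at the plateau midpoint;
  same-kind extremum runs are reduced to their most extreme member.
* Filter padding is odd reflection, sized at three periods of the lower
  band edge.
* Timestamps are snapped to the declared grid when within 10 % of a
  sample period, else rejected.

## Validation problem sizes

The test suite validates offset recovery over 50 simulated trials
(offsets uniform in ±2 s, noise up to ~15 % of the range of motion;
median error well under one 60 Hz sample), NEVd recovery over 50 noisy
trials (≥ 90 % of trial means within 2.5 mm of truth at 5 mm white
noise per system), and glitch screening over 50 trials (median
detection 100 %, median false removal 0 %). Simulated trials use 14–28
strides, matching the per-trial stride counts of the bundled tables.

## Known data inconsistencies

The bundled per-trial tables are internally consistent with their
printed dataset summary (mean absolute deviation 2.2 mm for both body
parts, maxima 8.7/6.5 mm, stride totals 655/404) with one exception:
the published summary quotes 26.2 mm as the markerless system's largest
within-trial SD, but no markerless column of the tables contains it —
the markerless columns top out at 22.3 mm, and 26.2 mm appears only as
a *reference-system* entry (head trial 16). The package reproduces the
tables, not the inconsistent summary cell; the corresponding acceptance
assertion is expected to fail and documents the discrepancy.

## Limitations

Straight-line trot only; no circle or treadmill support. The stride
splitter needs at least one clean hoof pair from the single camera. The
outlier rule is a documented approximation of an unreproducible
original. Clinical interpretation thresholds are deliberately out of
scope: the package quantifies asymmetry and agreement, it does not
grade lameness.
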