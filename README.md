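# equigait

Stride asymmetry quantification and two-system agreement for equine
gait signals.

## What it does, and for whom

Objective lameness assessment in horses measures the vertical
displacement of the head and pelvis during trot. Each stride produces
two peaks and two valleys; a lame horse unloads the painful diagonal,
and the signed difference between the two valleys (**MinDiff**) and
between the two peaks (**MaxDiff**) indicates impact and push-off
asymmetry. Normalising by the stride's range of motion
`R = max(p1, p2) − min(v1, v2)` gives size-independent indices

    V = MinDiff / R        P = MaxDiff / R

`equigait` is for biomechanics researchers and tool builders who need
to (a) turn keypoint trajectories — from markerless video tracking or
marker-based motion capture — into per-stride asymmetry metrics, and
(b) quantify the agreement between two systems that recorded the same
trial. The pipeline implements:

* hoof-signal band-pass filtering (0.6–2.2 Hz, 7th-order Butterworth,
  zero phase) and left/right stride splitting with stride-frequency
  estimation;
* stride-frequency-scaled band-pass of head/pelvis signals
  (0.75–2.42 × f_stride, 10th order, zero phase, realised as
  second-order sections for numerical stability);
* cross-correlation trigger-offset estimation between systems;
* robust peak/valley extraction via the second stride harmonic
  (survives severe lameness where naive extrema cancel);
* stride quality control: a >10 Hz spectral dominance screen per
  quarter-stride and robust Mahalanobis outlier removal on the four
  peak–valley difference features, plus trial exclusion below 10
  matched strides;
* agreement statistics: per-stride and per-trial deviations on the
  geometric (mm) scale, pooled absolute dataset summaries
  (D̄, maxD, minD), scale-corrected waveform RMSD, and Bland-Altman
  bias with 95 % limits of agreement.

A two-harmonic trot simulator with exact analytic ground truth
(`trot_config()`, `generate_trial()`, `oracle_nevd()`) stands in for
horses and cameras, and per-trial reference tables from a 23-horse
smartphone-vs-motion-capture validation study ship with the package
(`load_trial_tables()`).

## Worked example

Simulate a dual-system trial of a moderately asymmetric horse
(planted V = 0.20, P = −0.10, 0.5 s trigger offset) and run the full
comparison:

```r
library(equigait)
cfg <- trot_config(asym_v = 0.2, asym_p = -0.1, seed = 3)
sim <- generate_trial(cfg)
cmp <- compare_trial(sim$recording)
rep <- agreement_report(list(cmp))
print(rep)
#> <agreement_report> 1 included trials
#>   head: 25 strides, 1 trials; Dbar 0.09, maxD 0.10, minD 0.08 mm; mean RMSD 1.80 mm
#>   pelvis: 16 strides, 1 trials; Dbar 0.82, maxD 1.09, minD 0.56 mm; mean RMSD 2.80 mm
print(cmp$shift)
#> <sync_result> t_shift = +0.5003 s (objective 1.783, range +/-5 s)
round(as.data.frame(rep$parts$head$trials[, -1]), 2)
#>    N    dV  dP   Vsc   Vmc   Psc   Pmc sVsc sVmc sPsc sPmc   Rmc
#> 1 25 -0.08 0.1 15.74 15.82 -7.79 -7.88 3.22 3.13 1.76 1.69 74.39
```

Reading the output: the planted 0.5 s trigger offset is recovered to
0.3 ms; 25 head and 16 pelvis strides were matched between systems
(the pelvis is visible to a single camera only while the horse trots
away, hence fewer). The trial-mean MinDiff on the geometric scale is
≈ 15.8 mm (0.20 × the 74 mm measured range, after filtering), the two
systems differ by well under 1 mm on every trial-mean metric, and the
stride-curve RMSD is 1.8–2.8 mm. `write_report()` serialises the whole
report to JSON losslessly.

The bundled validation tables reproduce their published summary:

```r
dataset_summary(load_trial_tables("head"))
#>       Dbar maxD minD  M
#> 1 2.163043  8.7    0 23
```

which rounds to the published head D̄ of 2.2 mm over the 23 trials.

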