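Package: equigait
Title: Stride Asymmetry Quantification and Two-System Agreement for
    Equine Gait Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying vertical movement asymmetry of the head
    and pelvis in trotting horses from keypoint trajectory data, and for
    assessing agreement between two measurement systems recording the same
    trial (for example a markerless single-camera application against
    marker-based optical motion capture). Implements stride splitting from
    hoof signals, stride-frequency-scaled zero-phase Butterworth band-pass
    filtering, robust peak and valley extraction based on the second stride
    harmonic, normalised extreme-value differences (MinDiff, MaxDiff),
    stride- and trial-level quality control, cross-correlation time
    synchronisation between systems, scale-corrected waveform RMSD and
    Bland-Altman limits of agreement. Includes a two-harmonic trot-signal
    simulator with analytic ground truth for validation, and bundled
    per-trial reference tables from a 23-horse dual-system validation
    study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
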