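# pitcherp

Simulation and analysis of pitch-discriminative event-related potentials
(ERPs) from multichannel EEG.

## The problem

When listeners hear the notes of the C-major scale (C4...B4), scalp ERPs
can carry a graded amplitude code for pitch: the mean amplitude in a late
analysis window changes *linearly* with pitch (coded 1-7), with opposite
signs in the two hemispheres — more negative with rising pitch over left
frontotemporal electrodes, more positive over their right mirrors — and
the effect is concentrated frontally rather than parietally. `pitcherp`
is for EEG researchers who want a tested, reproducible implementation of
that analysis chain, together with a forward simulator that generates
whole synthetic experiments (20 subjects in musically-trained/MT and
non-trained/NT groups, 14 blocks x 50 one-second tone trials, 31-channel
10-20 montage at 500 Hz) whose ground truth has exactly the structure the
analysis is designed to detect.

The chain: zero-phase notch/band filtering -> correlation-based
bad-channel detection with spherical-spline interpolation ->
surface-Laplacian (CSD) re-referencing -> artifact subspace
reconstruction (cutoff 30) -> epoching at [-100, 800) ms with baseline
correction and target-trial exclusion -> sliding-window (100 ms / 10 ms
step) **separability** scan on the chronologically first half of the
trials:

    S = (1 / C(K,2)) * sum_{i<j} |c_i - c_j| / (sigma_i + sigma_j)

(a Davies-Bouldin-style index over per-pitch window-amplitude groups,
`c` = median, `sigma` = sample SD) -> on the second half of the trials:
ANOVA channel selection with bilateral completion, paired left/right
tests per pitch, per-subject OLS slopes of amplitude on pitch, one-sample
slope tests, frontal-vs-parietal asymmetry contrasts (exact Wilcoxon
signed-rank), MT-vs-NT slope comparison, exact rank-sum behavior test,
and behavior-slope correlations — all with Benjamini-Hochberg FDR.

## A worked example

```r
library(pitcherp)

cfg <- run_config(seed = 1, n_per_group = 10, n_blocks = 4,
                  filter = FALSE, detect_bad = FALSE,
                  laplacian = FALSE, asr = FALSE)   # sensor-space analysis
res <- run_pipeline(cfg, out_dir = "run1")
res
```

which prints (output from this exact call):

```
<erp_analysis>
  selected window: [530, 630) ms
  selected channels: F7, F3, F4, F8, FC5, FC1, FC2, FC6, T7, T8
  MT: 10 channels with nonzero slope; 4/4 frontal>parietal contrasts significant
  NT: 9 channels with nonzero slope; 4/4 frontal>parietal contrasts significant
  behavior: 13.0 +/- 1.05 vs 2.7 +/- 2.21, p = 1.1e-05
```

Reading it: the half-1 separability scan picked the [530, 630) ms window
(one 10 ms step from the generator's planted [540, 640) effect window —
overlapping windows make neighbouring starts nearly equivalent); channel
selection recovered exactly the ten frontotemporal effect channels;
slopes are significantly negative on the left and positive on the right
in both groups; every frontal pair shows a
larger right-minus-left slope difference than its parietal counterpart;
and the MT group counts far more target blocks correctly than the NT
group (exact rank-sum). `run1/` holds the separability curve, all test
tables as TSV, per-pitch grand-average ERPs, a JSON manifest that makes
the run byte-for-byte reproducible, and a plain-text summary.

Individual stages are ordinary functions (`generate_schedule()`,
`simulate_subject()`, `filter_line_and_band()`, `surface_laplacian()`,
`asr_clean()`, `epoch_and_filter()`, `scan_windows()`,
`select_channels()`, `fit_pitch_slopes()`, ...), and recordings can be
written/read as EDF + events TSV (`write_recording()`,
`read_recording()`). A thin command-line front-end lives at
`inst/scripts/pitcherp` (`simulate`, `analyze`, `run`, `make-fixtures`).

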