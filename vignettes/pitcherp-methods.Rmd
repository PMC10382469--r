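---
title: "Methods: simulating and analysing pitch-discriminative ERPs"
author: "pitcherp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing pitch-discriminative ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When listeners hear the seven notes of the C-major scale (C4...B4), do
scalp ERPs carry a graded, pitch-linear amplitude code -- and is that code
hemispherically anti-symmetric (amplitudes growing more negative with
rising pitch on the left, more positive on the right), strongest over
frontotemporal cortex, and sharpened by musical training? `pitcherp`
implements the complete analysis chain needed to ask those questions of a
31-channel, 500 Hz EEG experiment in which 20 participants (10 musically
trained, MT; 10 non-trained, NT) hear 14 blocks of 50 one-second tone
trials, each block with a designated target pitch whose presentations the
participant silently counts. Analyses use non-target trials only.

Because raw recordings from such a study are not redistributable, the
package pairs the analysis chain with a forward simulator whose ground
truth has exactly the statistical structure the analysis is designed to
detect. Every inferential claim the package makes about itself is a
parameter-recovery statement: *when data contain the planted structure,
the chain finds it; when they do not, it stays quiet.*

## The forward model

For subject $s$, channel $c$ and a trial of pitch $p \in \{1..7\}$, the
noiseless signal is

$$ x_c(t) = T(t) + \beta_c \,(p - 4)\, g(t), $$

where $T(t)$ is a fixed evoked template (a damped 10 Hz sinusoid over
0-500 ms, ~5 uV), $g(t)$ is a unit pulse whose plateau covers the effect
window exactly (10 ms raised-cosine ramps outside it, so the window mean
of $g$ is exactly 1), and $\beta_c$ is the amplitude-per-pitch-step slope.
Centring at pitch 4 mirrors the convention of displaying fits with their
x-intercept at "Fa". Defaults:

* **Effect channels**: the four frontal pairs F7-F8, F3-F4, FC5-FC6,
  FC1-FC2 plus T7-T8; $\beta = -s$ on the left member, $+s$ on the right,
  0 elsewhere -- the anti-symmetric frontotemporal topography under study.
* **Effect window**: [540, 640) ms after onset.
* **Slope magnitude**: $s = 0.5$ uV/step for MT subjects; NT subjects get
  $0.7 s$. The 0.7 ratio makes the group contrast directionally
  consistent at every channel yet too small to survive FDR at $n = 10$
  per group -- the qualitative pattern such studies report. Per-subject
  magnitudes jitter by 0.1 uV/step (SD).
* **Noise**: 5 uV total SD per channel, an equal-variance mix of 1/f
  ("pink") and white noise. The pink component is synthesised spectrally
  at 1/8 of the sampling rate and linearly upsampled; its energy lies
  below ~30 Hz, so the band limitation is immaterial while avoiding
  full-rate FFTs. Half of the noise **variance** (50%) is a common-mode
  field shared by all channels, which gives healthy channel pairs
  correlations near 0.55 -- like volume-conducted EEG, and necessarily
  above the 0.4 bad-channel criterion (a smaller shared fraction would
  make the criterion flag every healthy channel).
* Bad channels (replaced by independent white noise) and 100-300 ms,
  Poisson-timed, high-amplitude artifact bursts are injectable to
  exercise the detection/interpolation and ASR stages.

A design power analysis fixed these values once: with 4 blocks per
subject the per-subject slope standard error is ~0.15 uV/step, so the
per-channel one-sample effect size is $d \gtrsim 2$ even for NT subjects,
and the frontal-minus-parietal asymmetry difference is positive for ~97%
of simulated subjects -- the regime in which the reported findings (all
slopes significant; all four region contrasts significant) are the
expected outcome rather than a coin flip.

The trial scheduler is stratified: each pitch's total count is dealt
round-robin across blocks, which yields the exact global balance of the
real design (each pitch exactly 100 times over 14 blocks; block target
twice per pitch) and keeps per-pitch counts usable in reduced designs.

## Preprocessing

The chain follows the fixed order **temporal filters -> bad-channel
detection and spherical-spline interpolation -> surface Laplacian -> ASR
-> epoching**; every stage is deterministic.

* **Filters**: a biquad notch at 60 Hz (Q = 30) plus a Butterworth
  high-pass at 1 Hz (order 4) and low-pass at 50 Hz (order 6), all run
  forward-backward for zero phase. The low-pass order is 6 rather than 4
  because two-pass filtering squares the magnitude response: order 4
  leaves 40 Hz at -1.24 dB, outside the +/-1 dB passband contract the
  stage promises; order 6 keeps it at -0.5 dB.
* **Bad channels**: a channel is flagged when more than 70% of the other
  channels correlate with it below 0.4 (zero-lag Pearson over the whole
  filtered record; a zero-variance channel counts as correlation 0 and is
  flagged). Flagged channels are rebuilt by Perrin-style spherical
  splines (order m = 4, 50 Legendre terms, regularisation 1e-5).
* **Surface Laplacian**: the spherical-spline current-source-density
  transform, computed as a single precomputable linear operator; output
  follows the CSD sign convention (negative Laplace-Beltrami, so local
  potential maxima are positive). It maps constant topographies to
  numerical zero and replaces the recording reference entirely.
* **ASR**: a simplified calibrated subspace reconstruction. Calibration
  is the quietest 60% of 1-second chunks (lowest aggregate RMS); in each
  0.5 s Hann window (50% overlap, overlap-add) the window covariance is
  eigendecomposed and components whose RMS amplitude exceeds `cutoff`
  (default 30) times the calibration SD projected on that direction are
  dropped before reconstruction. Records shorter than 30 s refuse to
  calibrate and advise bypassing the stage. The published reference
  algorithm's Riemannian refinements are deliberately out of scope; the
  stage is treated as a black-box burst remover and validated by its
  invariants (clean data pass through within 5% RMS; 500 uV bursts leave
  residuals under 100 uV; an astronomically large cutoff is an identity).
* **Epoching**: [-100, 800) ms around each onset (half-open at 500 Hz:
  450 samples, t = 0 at the onset sample), baseline-corrected by the
  [-100, 0) ms mean. Baseline correction is standard ERP practice and
  required for amplitude comparability across trials. Target-pitch trials
  are marked and excluded from all analysis sets. Each subject's
  non-target trials of each pitch are split chronologically: the earliest
  50% (rounded up) is half 1, the rest half 2.

## Window selection by separability

For window starts 0, 10, ..., 700 ms (100 ms windows, 90 ms overlap -- 71
windows), each trial's mean amplitude per channel is grouped by pitch and
scored with a Davies-Bouldin-style separation index

$$ S = \frac{1}{C(K,2)} \sum_{i<j} \frac{|c_i - c_j|}{\sigma_i + \sigma_j}, $$

with $c_i$ the median and $\sigma_i$ the sample SD (denominator $n-1$) of
pitch $i$'s window means. The absolute difference of medians makes the
maximisation meaningful; SDs are taken across trials (not across time)
because the index mimics a cluster-separation score over observations.
Scores are averaged over channels within subject, then over subjects,
with the across-subject SEM reported as dispersion; whether pooling
channels first would match the original analysis exactly is unknowable
from the published description, so the aggregation is declared rather
than inferred. The selected window is the maximum, ties broken toward the
earliest start.

**Double-dipping guard**: the scan consumes only half-1 trials; every
inferential statistic below consumes only half-2 trials. The half label
lives in the epoch metadata, so the split is enforced by construction.

## The inferential battery

All tests operate on per-subject pitch means of the selected-window
amplitude (half 2) -- the subject is the replicate unit throughout,
because every reported test (paired t, one-sample t, signed-rank) is
across subjects. FDR control is Benjamini-Hochberg at q = 0.05 with the
families declared in the run manifest: channels within group (selection,
slope tests, group comparison, correlations), pair x pitch within group
(hemispheric tests), and the 4 coronal-plane matches within group.

* **Channel selection**: per channel and group, a one-way ANOVA across
  the 7 pitch levels (n = 10 subject means per cell), preceded by an
  advisory KS normality check; BH across channels within group; a channel
  significant in either group enters, and the selection is closed under
  the bilateral mirror map (origin flagged `symmetric-completion`).
  Midline channels have no mirror. (Published selections sometimes name
  FC9/FC10; those electrodes do not exist in this 31-channel montage and
  are simply not representable.)
* **Hemispheric asymmetry**: paired t-tests of left vs right subject
  means per selected pair, pitch, and group.
* **Slopes**: closed-form OLS of the 7 pitch means on pitch value 1-7 per
  subject x channel; one-sample t against zero per channel with the
  group-mean sign reported (the expected pattern: negative left, positive
  right).
* **Region contrast**: per subject, asymmetry = slope(right) -
  slope(left); each frontal pair's asymmetry is compared with its
  coronal-plane parietal counterpart by an exact Wilcoxon signed-rank
  across subjects, BH over the 4 matches.
* **Group comparison**: Welch t on |slope| per channel (steepness), BH
  across channels, plus the raw direction so a consistent "MT stiffer"
  pattern remains visible when nothing survives FDR. Mann-Whitney is
  available by flag.
* **Earliest discriminative window**: windows scanned in ascending start;
  per window an ANOVA per selected channel, BH across those channels;
  the first window where a strict majority is significant is reported,
  or "none".
* **Behavior**: the rank-sum comparison of correct-block counts uses the
  exact conditional distribution of the tied rank sum (dynamic
  programming over doubled ranks) rather than the normal approximation:
  counts are small integers, ties are ubiquitous, and at n = 10/10 the
  approximation cannot reach p < 1e-4 even under complete group
  separation, whereas the exact p is 2/C(20,10) = 1.1e-5.
  The behavioral simulator draws rounded normals clipped to [0, 14]; the
  latent centre is solved numerically so the realised mean equals the
  nominal group mean (naive clipping at 14 would bias the MT mean by
  -0.12).
* **Behavior-slope correlation**: Pearson r per channel across all 20
  pooled participants (Spearman by flag), BH across channels.

## Validation harness and problem sizes

`recovery_config()` defines the conditions under which the package
validates itself by repeated simulation: 10 subjects per group (the
study's n) with 4-block subjects -- block count scales only trial numbers,
not the structure under test -- and analysis in sensor space (no temporal
filter, bad-channel pass, Laplacian or ASR). The ground truth is defined
in sensor space, and the synthetic default contains no line noise, DC
offset, bad channels or bursts, so those stages would be identities up to
edge effects; they are validated by their own invariant tests instead.
The surface Laplacian in particular is a spatial derivative: it preserves
the sign topography of the effect but rescales magnitudes, so
slope-recovery-in-microvolts is only meaningful upstream of it. The null
calibration uses 2-block subjects, since false-positive rates, unlike
power, do not depend on trial counts.

Over 50 seeded replicates the batteries check: the selected window start
within +/-30 ms of the planted 540 ms in >= 90% of seeds; slope signs
recovered at >= 95% of effect channel-seeds with mean magnitude within
10%; all four frontal-vs-parietal contrasts significant in >= 90% of
group-runs; under a zero effect, any-channel selection in <= 10% of seeds
(the two per-group BH families make the expected rate ~9.7%, so this
bound sits at the sampling mean) and an earliest discriminative window of
"none" in >= 95% of group-runs.

## What the synthetic data do not emulate

The generator produces Gaussian 1/f + white noise with a single
common-mode field; real EEG has non-Gaussian artifacts (blinks, saccades,
EMG), spatially graded correlation, non-stationary rhythms, and
subject-specific evoked morphology. The evoked template is identical
across channels and subjects, and the pitch effect is exactly linear with
equal spacing -- the analyses *assume* linearity, and the generator grants
it. Passing recovery batteries therefore demonstrates that the chain is
correct and calibrated under its own assumptions, not that those
assumptions hold for any particular laboratory's recordings. Source
localisation, ICA-based artifact correction, realistic head-model forward
simulation and trial-level hierarchical modelling are out of scope.

## Numerical choices worth knowing

* Half-open time conventions everywhere: epochs [-100, 800) ms, windows
  [start, start+100) ms, 2 ms samples.
* Sample SDs use denominator n - 1; a separability pair with zero pooled
  SD and nonzero median distance is skipped and the normaliser reduced
  (warned); an all-degenerate window scores NaN.
* Spline systems are solved once per montage and applied as linear
  operators; interpolation reproduces constants exactly by the
  sum-to-zero constraint.
* EDF output is 16-bit with per-channel physical ranges, so round trips
  are exact to one quantisation step; events travel in a sidecar TSV
  (EDF annotation dialects vary), ground truth in JSON.
* All randomness flows from one root seed through fixed substreams
  (schedule, per-subject noise, artifacts, behavior), so any stage can be
  reproduced in isolation and a rerun from the manifest is byte-identical.
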