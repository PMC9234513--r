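---
title: "Methods: semiautomated Syn-ATP image quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semiautomated Syn-ATP image quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Syn-ATP reports presynaptic ATP as bioluminescence: luciferase anchored to
synaptic vesicles emits photons in proportion to ATP at saturating
luciferin, and an mCherry tag provides a fluorescence channel proportional
to reporter expression. A timepoint pairs a 20-frame fluorescence movie
(2 Hz over 10 s, 20 ms exposures, averaged on ingest) with one 60-s
luminescence exposure; both are 512×512 16-bit EMCCD frames. The ATP
readout is

$$
L/F \;=\; \frac{\sum_{\text{signal}} I_L - n\,\bar B_L}
               {\sum_{\text{signal}} I_F - n\,\bar B_F},
$$

where the sums run over the full-resolution *signal* pixels (neither
background nor cell body), $n$ is their count, and $\bar B_c$ is channel
$c$'s mean background intensity. Writing the numerator as
$\sum(I_L - \bar B_L)$ makes two properties explicit that the pipeline
relies on: a constant offset added to one channel cancels exactly when the
mask is correct, and rescaling both channels by a common factor leaves
L/F unchanged. The ratio is computed per timepoint and assembled into a
per-neuron trace; it is proportional to ATP concentration but not an
absolute calibration (luciferase rate constants are not part of this
package's scope).

The pipeline's central assumption is that whole-field analysis of the
masked image is a better-conditioned estimator than manual per-terminal
ROIs: terminals move with the axon over minutes, but the field-wide sum is
insensitive to that motion, and masks are recomputed independently at every
timepoint.

## Background detection

All segmentation decisions are taken on the luminescence channel, whose
background is far lower and flatter than fluorescence; the resulting mask
is applied verbatim to the fluorescence frame (never re-derived there, so
both channels are corrected against the same pixel population).

1. `block_median_downsample()` replaces each 4×4 block by its median,
   512×512 → 128×128. With 16.4 µm camera pixels behind a 40× objective a
   downsampled pixel spans 1.64 µm, about one nerve terminal (≈1.5 µm), so
   single-pixel noise cannot masquerade as a terminal. Medians over an even
   count are the mean of the two central order statistics — conventional,
   and continuous in the data.
2. The 128×128 image is flattened to a 16,384-entry vector and split by
   two-cluster k-means on scalar intensity. The lower-mean cluster is
   background; the mask requires at least one pixel in each cluster, and a
   constant image raises a degenerate-input error ("no signal detected")
   rather than fabricating a split.
3. Each channel's background level is the mean *full-resolution* intensity
   under the nearest-neighbour-upsampled mask, so levels are on the same
   scale as the full-resolution net-signal sums.

**Clustering determinism.** For scalar data and two clusters the k-means
objective has an exactly solvable form: the optimal partition is a
threshold, found by an exhaustive scan over splits of the sorted vector
minimizing total within-cluster sum of squares (values are centred first to
keep the sum-of-squares arithmetic well conditioned). `synatp` exposes this
scan both as an independent oracle and as a deterministic backend
(`cluster_method = "threshold"`); the default backend runs
`stats::kmeans()` with ten restarts under a configuration seed and is
required by the test suite to agree with the scan exactly. Reproducibility
is the point of the method — removing user-dependent variability — so a
fixed seed is part of the configuration, and repeated runs are
byte-identical.

**Optional median smoothing.** A second, geometry-preserving stage
(`block_median_smooth()`) can replace every 4×4 tile of the *downsampled*
image by its median before clustering (tiles of 4 downsampled pixels span
≈6.6 µm; the flattened vector keeps its 16,384 entries). The design was
genuinely open: region-median smoothing suppresses isolated bright noise,
but the median of a 16-pixel tile ignores any minority, and a nerve
terminal occupies roughly *one* downsampled pixel — so on sparsely
innervated fields the smoothing stage erases exactly the objects being
quantified and hands them to the background cluster. We therefore ship the
stage as a configuration toggle (`smooth`), **off by default**; it is worth
enabling for densely innervated fields with heavy salt-and-pepper noise,
where tiles are majority-signal and the median is protective.

## Cell-body exclusion

The soma synthesizes the reporter and dominates local intensity, but its
ATP metabolism may differ from terminals, so it is excluded. A square
window of side `cell_body_width_px` (default 32 downsampled pixels ≈ 50 µm)
slides with stride 1 over the background-zeroed image; the placement with
the highest window mean is the cell body. At fixed width the highest mean
and the highest total are the same placement; we compute the mean. Ties are
broken by the first placement in row-major scan order (deterministic), and
the search is invariant to adding a constant to all pixels. The search runs
on the background-zeroed image — masking first concentrates the criterion
on detected signal. Detection is a *proposal*: the semiautomated workflow
writes an overlay PNG (`overlay_png()`) and the user accepts, supplies a
manual box (`source = "user"`, applied to all timepoints), or suppresses
masking for soma-free fields (`cell_body_override = "none"`). Exactly zero
or one cell body per field is supported.

## Quality control and corrections

* **Dark-current QC.** Points whose signal sits near the camera's detection
  floor are unreliable. A point passes when the mean intensity attributed
  to signal is at least `qc_factor` (default 3) times the dark-current
  variance (boundary inclusive), evaluated per channel — luminescence uses
  the signal-cluster mean of the clustered image, fluorescence the mean
  full-resolution intensity over the signal region — and fails if either
  channel fails. The operand is a cluster *mean*: a single conservative
  scalar per channel. The variance is camera-specific; `dark_frame_series()`
  plus `estimate_dark_variance()` calibrate it from signal-free frames.
* **Invalid points** (nonpositive net fluorescence, degenerate
  segmentation) are flagged, never dropped, so traces stay aligned with the
  stimulation window; cohort statistics exclude them pointwise.
* **EM gain.** Gain changes rescale intensities linearly; when
  `gain_enabled`, the final L/F is multiplied by `gain_coefficient` (one
  multiplier per series — applied to the computed ratio, not to raw
  frames).
* **pH correction.** Electrical stimulation acidifies the cytosol and
  suppresses luciferase (pKa 7.03 ≈ cytosolic pH); correction is a
  user-supplied vector of per-timepoint positive multipliers from
  independent calibration. Default: none. Raw values are always retained
  alongside corrected ones.

## Cohort statistics

Baseline variability ΔL/F summarises measurement noise over the
pre-stimulation window (default: the first 3 of the standard 8 one-minute
timepoints). "Percent deviation from the mean" admits two readings, so both
are implemented behind `delta_lf_metric`: mean absolute percent deviation
(`mad_pct`, default) and percent coefficient of variation (`cv_pct`); both
are scale-invariant. Population comparisons pool all groups, standardize
per-neuron baseline means by the pooled mean and sample SD (n − 1
throughout — cohorts are small), and compare group z-score distributions.
Average traces are per-timepoint mean ± SEM over valid, QC-passing points
only, with per-timepoint contributor counts. Hypothesis tests (paired t,
Wilcoxon) are deliberately not re-implemented; the report emits the
per-neuron summaries needed to run them in any statistics environment.

## The synthetic-data generator

`generate_scene()` emulates the acquisition well enough to exercise every
decision the pipeline makes, with exactly known truth:

* Backgrounds of 100 (luminescence) and 900 (fluorescence) camera units
  with additive Gaussian noise (SD 4 and 12): luminescence is dim and
  clean, fluorescence bright with a dominant offset — the regime the
  channel-role asymmetry of the pipeline is designed for. The default
  planted ratio is `true_lf = 0.1`.
* 150 puncta of ~4 full-resolution pixels placed along straight axon-like
  paths, amplitudes Gamma-distributed (CV 0.5) around 600 fluorescence
  units to emulate terminal heterogeneity; one 128-pixel (≈50 µm) soma at
  twice the mean punctum amplitude; 20-frame fluorescence movies rendered
  as independent noisy replicates so averaging demonstrably reduces
  variance.
* Every planted pixel obeys
  $I_L - B_L = \text{true\_lf}\,(I_F - B_F)$, so the planted net-signal
  ratio equals `true_lf` under *any* mask — which is what makes noise-free
  recovery an exact, assumption-free check of the quantification chain.
* Puncta are centred on the 4×4 downsample grid (one punctum, one
  downsampled pixel) and the soma is rendered as a grid-aligned square, so
  the planted background mask is unambiguous at the downsampled geometry.
  Both are idealizations for testability, not claims about axon anatomy.

What the generator does **not** model: Poisson shot noise and EMCCD excess
noise, the optical point-spread function, photobleaching or luciferin
kinetics, background drift, focus changes, or cell motion between
timepoints. Passing recovery tests therefore demonstrates the correctness
of the analysis chain under its stated noise model, not performance on all
real data; sudden background changes in particular remain a known failure
mode of whole-field intensity clustering.

Two generator regimes appear in the tests. Exact-recovery checks use
noise-free scenes with homogeneous punctum amplitudes
(`punctum_amp_cv = 0`): with arbitrarily dim terminals an intensity
clustering *must* eventually misassign the dimmest ones (they are genuinely
closer to the background centroid), so exactness is only well-posed in the
separable regime. Statistical checks use the full defaults, where a small
fraction of dim puncta lands in the background cluster; the coupled-channel
construction keeps the recovered L/F within a fraction of a percent of
truth regardless, and the mask still agrees with ground truth on ≥ 99% of
pixels.

## Numerical and interface conventions

* Coordinates are 0-based, row-major, origin top-left; boxes are half-open.
* Frames are held as doubles from ingest; 8/16-bit unsigned and 32-bit
  float grayscale TIFFs are accepted, and 16-bit writing rounds to
  integers (integer data round-trips bit-exactly).
* Degenerate inputs raise typed errors at the operation level; the trace
  builder converts them to flagged points with the timepoint index attached
  in the trace notes.
* Scene generation and clustering preserve the caller's RNG state; all
  randomness flows from explicit seeds.

Problem sizes used by the shipped checks: recovery statistics use 20
independent seeds of the default 512×512 scene at one timepoint each;
clustering-oracle agreement uses 50 random vectors of up to 10,000 points;
simulated cohorts use 10 neurons × 4 timepoints. These sizes give stable
medians while keeping the full suite under a minute of compute on a single
core.

## Known limitations

* Whole-field analysis trades per-terminal resolution for robustness: no
  per-bouton quantification or tracking is provided, by design.
* Exactly 0 or 1 cell body per field; multi-soma fields need user boxes.
* The QC rule compares an intensity mean against a variance, as specified
  for the reference camera; treat `qc_factor` as an empirical,
  camera-specific knob rather than a dimensionally meaningful constant.
* No flat-field correction, registration, or drift compensation.
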