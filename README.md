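# synatp

Semiautomated quantification of presynaptic ATP from dual
luminescence/fluorescence imaging.

## The problem

Syn-ATP is a genetically encoded optical ATP reporter for nerve terminals:
firefly luciferase targeted to synaptic vesicles (luminescence proportional
to ATP at saturating luciferin) fused to mCherry (fluorescence proportional
to reporter expression). A timepoint of a Syn-ATP experiment pairs a
20-frame mCherry movie (2 Hz for 10 s, averaged into one image) with a
single 60-s luminescence exposure on an EMCCD camera. The ATP readout for a
neuron at each timepoint is the background-corrected ratio

```
L/F = (Luminescence − Background_L) / (Fluorescence − Background_F)
```

summed over the neuron's nerve terminals. Manual region-of-interest
analysis of such data is slow, biased by terminal selection, and fragile to
axonal motion over minutes-long sessions. `synatp` implements a
semiautomated whole-field pipeline instead:

1. **Background detection** — the 512×512 luminescence frame is
   block-median downsampled to 128×128 (1.64 µm/pixel), flattened to a
   16,384-entry intensity vector, and split by two-cluster k-means; the
   lower-mean cluster is background. The same mask is applied to the
   fluorescence channel, and each channel's background level is the mean
   intensity under the mask at full resolution.
2. **Cell-body exclusion** — a 32×32-pixel (≈50 µm) window slides one pixel
   at a time over the background-zeroed image; the highest-mean placement
   is the soma and is masked out (its ATP metabolism may differ from
   terminals). The user can accept, override, or suppress the detected box.
3. **Signal estimation** — per timepoint, net L and net F are the summed
   full-resolution intensities over the remaining signal pixels minus
   `count × background level`; their ratio is the L/F trace. A quality
   check requires the clustered signal mean to be at least 3× the camera's
   dark-current variance; EM-gain changes and stimulation-induced pH shifts
   are compensated by configurable multiplicative corrections.

Cohort statistics mirror the standard evaluation: per-neuron baseline
variability ΔL/F (percent deviation from the baseline mean), z-scores of
per-neuron baseline L/F over a combined population
(`z = (x − μ_pooled) / s_pooled`, sample SD), and across-neuron average
traces (mean ± SEM).

Because no public Syn-ATP dataset exists, the package ships a synthetic
scene generator (`generate_scene()`) that emulates the acquisition —
Gaussian camera noise per channel, Gamma-heterogeneous puncta strung along
axon-like paths, one bright soma, and a planted true L/F coupling both
channels — so every pipeline stage is testable against known ground truth.

## Worked example

```r
library(synatp)
spec  <- scene_spec(n_timepoints = 4, seed = 7)   # 512x512, planted L/F = 0.1
scene <- generate_scene(spec)
res   <- run_analyze(scene$series)
res$trace
#> <synatp_trace> neuron 'sim7', 4 timepoints (4 valid, 4 QC pass)
#>   timepoint time_s  net_lum net_fluor         lf ... qc_pass valid
#> 1         0      0 81430.94  811569.7 0.10033759 ...    TRUE  TRUE
#> 2         1     60 81215.77  812169.2 0.09999858 ...    TRUE  TRUE
#> 3         2    120 80272.08  804590.3 0.09976764 ...    TRUE  TRUE
#> 4         3    180 80958.14  812215.5 0.09967569 ...    TRUE  TRUE
res$segmentations[[1]]
#> <synatp_segmentation> 128 x 128 downsampled: 15279 background, 1024 cell-body, 81 signal pixels
#>   background level: lum 100.1, fluor 901.4; cluster means 100.2 / 217.3
#>   cell body (auto): (41, 82) width 32
box_iou(res$segmentations[[1]]$cell_body, scene$truth$soma_box_true)
#> [1] 1
```

The recovered L/F sits within 0.4% of the planted 0.1 at every timepoint
under default camera noise, the detected background level matches the
planted 100-unit luminescence offset to 0.1%, and the soma box lands
exactly on the planted cell body. `run_cohort()` takes lists of traces (or
trace CSVs) plus group labels and writes per-neuron summaries with pooled
z-scores and per-group average traces.

A command-line wrapper with `simulate`, `analyze`, `cohort`, and
`config-init` subcommands lives at
`system.file("cli", "synatp.R", package = "synatp")`; it is a thin shell
over the functions above and produces identical output.

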