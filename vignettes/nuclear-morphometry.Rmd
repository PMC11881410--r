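---
title: "Quantifying nuclear damage in skin histology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear damage in skin histology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histonox)
```

## The problem

Hematoxylin-eosin (HE/HES) stained sections of human skin explants are the
workhorse readout for assessing tissue damage after UV irradiation or
chemical stress. Two nuclear phenotypes carry most of the signal: *pyknotic*
nuclei (condensed, shrunken, darker — an early cell-death morphology) and
*haloed* nuclei, i.e. nuclei surrounded by a clear, empty perinuclear space,
which accumulate in the stratum spinosum of stressed epidermis. Manual
scoring of these phenotypes is slow and observer-dependent; `histonox`
automates it: it segments epidermal nuclei in large brightfield slides and
computes a per-nucleus descriptor panel whose texture component — the
**high-contrast score** — captures the haloed phenotype directly.

## The high-contrast score (HCM)

For each nucleus we take its instance mask, dilate it by a fixed physical
margin (default 2 µm), and compute gray-level co-occurrence (GLCM)
statistics of the luminance plane over that window. The margin is the point:
the halo lives *around* the nucleus, so a window restricted to the nucleus
proper would never see it. Luminance (0.299 R + 0.587 G + 0.114 B) rather
than hematoxylin optical density is used because the halo is a brightness
phenomenon — near-white empty space — not a stain-concentration one.

Intensities are quantized to `G = 16` levels over the **fixed** range
[0, 255] (`level = floor(I·G/256)`). Fixed-range quantization, instead of
per-window min–max scaling, is deliberate: a bright halo must *raise* the
window's contrast relative to a plain nucleus, which requires all windows to
share one intensity scale. Co-occurrence counts are accumulated over the
four distance-1 offsets (0,1), (1,0), (1,1), (1,−1), symmetrized, and
normalized per offset; contrast, energy, entropy (bits) and homogeneity are
averaged across offsets. Contrast is reported as a percentage of its
attainable maximum:

$$\mathrm{contrast\_pct} = 100 \cdot
  \frac{\sum_{i,j}(i-j)^2 P_{ij}}{(G-1)^2} \in [0, 100].$$

This normalization keeps the score bounded and roughly `G`-invariant. The
sample-level **high contrast mean** is the mean of `contrast_pct` over all
analyzed nuclei, and `haloed_fraction_pct` is the percentage of nuclei whose
score strictly exceeds `halo_threshold_pct`.

### Why the halo cutoff defaults to 4%

Under fixed-range 16-level quantization, a window's contrast is essentially
the fraction of pixel pairs that straddle an intensity boundary, weighted by
the squared level jump. A plain epidermal nucleus has one boundary ring
(dark nucleus against pink cytoplasm, a ~7-level jump) and measures about
2% on clean renders; a haloed nucleus adds a second, stronger ring (dark
nucleus against near-white halo, ~10 levels, plus halo against cytoplasm)
and measures 4.5–5%. The default cutoff of 4% sits in the gap between those
two regimes; on clean synthetic scenes it classifies the two truth
subpopulations without error, and it remains clear of the plain
population's upper tail at pixel noise up to σ ≈ 5. Percent-scale scores in
the tens would require texture across the whole window, not a one-ring
boundary effect, so cutoffs far above this regime would classify nothing.
The cutoff is a configuration value (`glcm.halo_threshold_pct`) and should
be re-examined if the quantization depth, margin or stain chemistry change.

## Segmentation design

The paperless parts of segmentation are deliberately classical and pluggable:

* **Tissue ROI** — pixels with HSV saturation above an Otsu threshold *or*
  brightness below 92% of white, closed with a 5 px disk, minus components
  under 1000 µm². Near-constant saturation (blank slide, wall-to-wall
  tissue) falls back to a fixed saturation floor of 0.15, since Otsu is
  meaningless on a unimodal histogram.
* **Stain separation** — per-pixel optical density `−log10((I+1)/256)`
  unmixed with the Ruifrok–Johnston H&E matrix. The `+1` keeps black pixels
  finite. The synthetic generator renders with the same matrix, so
  deconvolution round-trips.
* **Nuclei (classical backend)** — hematoxylin plane → Gaussian smooth
  (σ = 1 µm) → Otsu → fill holes → distance transform → watershed with a
  peak neighbourhood of ~3 µm. The backend interface is a function
  `(tile, cfg, threshold) -> LabelMask`; externally produced CNN masks
  (e.g. U-Net / star-convex models) can be dropped in via the `external`
  backend and the `<sample>_nuclei.tiff` / `<sample>_epidermis.png` naming
  convention, so the descriptor panel is independent of the segmentation
  technology.
* **Epidermis (density-band baseline)** — the epidermis is operationally
  "the nucleus-dense band at the outer tissue surface": a Gaussian density
  map of nucleus centroids (σ = 25 µm) is thresholded at 0.5× its 99th
  percentile, intersected with tissue, and restricted to components
  reaching the outer surface. This is a stated repo decision; no published
  algorithm was available to reproduce.

All thresholds with physical meaning are expressed in micrometres and
converted through the slide's pixel size, so configurations transfer across
scan resolutions.

### Tiling and label merging

Large slides are processed in tiles (default 1024 px core, 64 px overlap ≈
30 µm at the default pixel size — larger than any plausible nucleus).
Each tile is segmented on its overlap-expanded window; an instance is kept
iff its centroid falls in the tile's exclusive core, with boundary ties
going to the lower tile index. Two details make tiled and untiled runs
*identical* rather than merely similar: the Otsu threshold is computed once
on the whole slide and passed to every tile, and Gaussian smoothing uses
replicated (not circular) boundaries so that a tile window and the full
slide agree near image edges.

## Descriptor panel

Per nucleus: area, perimeter, roundness `4πA/P²`, aspect ratio
(second-moment ellipse), luminance min/max/mean/population variance, the
four GLCM features, neighbour count within 30 µm, nearest-neighbour
distance, and relative epidermal depth `d_top/(d_top+d_bot)` (0 = stratum
corneum side, 1 = basal side), where the two distances are measured to the
epidermis' outer surface and dermal boundary respectively. Undefined values
(nearest-neighbour distance in a one-nucleus sample, depth outside the
epidermis, texture in a window with fewer than two pixel pairs) are flagged
`NA`, never silently dropped.

The perimeter is a marching-squares contour length with one pass of
circular vertex smoothing. The raw marching-squares polyline overestimates
a digital disc's perimeter by ~7% (a staircase artifact), pushing a disc's
roundness to 0.91; one smoothing pass brings a radius-20 px disc to
roundness 0.99 while leaving a large square's roundness at its π/4 limit.

Gradient statistics and chromatin substructure are out of scope, as is
cytoplasm/cell segmentation (no defined method exists to reproduce).

## Statistics

Two-group comparison of any descriptor offers Welch (default), Student and
paired t-tests — both equal-variance and paired variants are in active use
in this field's reports, so all are exposed and the robust one is the
default. Effect size is the strictly standardized mean difference
`SSMD = (μ₁−μ₂)/√(σ₁²+σ₂²)` (paired: `mean(d)/sd(d)`). Benjamini–Hochberg
adjustment is available across descriptors. With zero variance in both
groups the test degenerates: equal means report `t = 0, p = 1`; unequal
means report the underflow bound `p = 1e-300`. PCA (SVD of the standardized
table, signs fixed so each loading's largest entry is positive) and a
regularized Fisher LDA axis support multivariate views.

The comparison unit deserves care: pooling nuclei across replicates gives
enormous n and tiny p-values but risks pseudoreplication; comparing
replicate-level summary means is conservative. Both are possible — the
functions accept any value vectors — and per-sample summaries are always
written so either analysis can be rerun.

## The synthetic generator

Because no annotated slide data are redistributable, validation runs on a
seeded generator that emulates exactly the structure the pipeline measures:
a near-white slide background above the tissue, eosin-pink tissue rendered
through Beer–Lambert transmission with the same stain matrix the
deconvolution uses, a nucleus-dense epidermal band over a sparse dermis,
elliptical nuclei (aspect ratio uniform in [1, 1.6], radius normal with
mean 2.8 µm, sd 0.4 µm), a configurable haloed fraction (annulus at 0.95×
background white, default width 1.5 µm), a pyknotic fraction (0.6× radius,
0.5× brightness), and additive Gaussian pixel noise. Nuclei are placed by
rejection sampling with at least a 1 px gap (halos included), and an
infeasible density request fails with the achievable count. Identical
specifications produce bit-identical images; cohort replicate seeds are
derived from the base seed and condition/replicate indices.

The default pixel size is 0.46 µm/px — half the linear resolution of a
typical 40× scan — to keep validation scenes small; physical-unit
parameters make this transparent. What the generator does *not* model:
staining variability and batch effects, nucleus clumping and overlap,
chromatin texture inside nuclei, out-of-focus blur, and saffron (HES)
collagen staining (HES sections are processed as HE). Green tests therefore
demonstrate algorithmic correctness and internal consistency, not clinical
performance on real slides; the CNN-backend hook and external-mask import
exist precisely because real tissue will need stronger segmentation.

## Validation problem sizes

The shipped checks run at desk scale, chosen to keep the full suite in a
few minutes: tiled-vs-untiled equivalence on ten 2048² slides of ~300
nuclei; detection fidelity on a clean 1024² slide (precision/recall at IoU
0.5 ≥ 0.9, epidermis Dice ≥ 0.8); halo validity on a 200-nucleus sample
(subpopulation SSMD ≥ 1) and a 3+3-replicate cohort of 600-nucleus slides
where doubling the generated halo fraction from 0.1 to 0.2 must double the
measured haloed fraction within ±25%; a 1000-resample null calibration of
the two-group test (rejection rate in [0.01, 0.10]); and exactness checks
of the GLCM implementation against brute-force pair enumeration. The
`scripts/acceptance.R` script reruns all of these from scratch under one
seed and reports the resulting numbers.

## Known limitations

* The classical nucleus backend assumes well-separated, roughly convex
  nuclei; dense real epidermis will need the external/CNN backend.
* The epidermis baseline assumes the epidermis faces the top of the image
  (outer surface reachable from above), which holds for standard
  cross-sections but not arbitrary orientations.
* The halo cutoff is calibrated for 16-level quantization and a 2 µm
  margin; changing either shifts the plain/haloed contrast regimes.
* DZI export writes plain JPEG/PNG tiles; no sparse-level optimization.
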