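# histonox

Automated nuclear morphometry and texture scoring for brightfield skin
histology.

`histonox` quantifies nuclear damage in hematoxylin-eosin (HE/HES) stained
skin sections. It detects the tissue, segments nucleus instances in tiles
across large slides, restricts analysis to the epidermis, and computes a
per-nucleus descriptor panel — shape, intensity, neighbourhood density,
relative epidermal depth, and gray-level co-occurrence (GLCM) texture over
each nucleus *plus its perinuclear margin*. The texture component yields
the **high-contrast score**: damaged nuclei surrounded by a clear halo (a
hallmark of UV- and oxidative-stress injury), and condensed pyknotic
nuclei, raise the local gray-level contrast of that window. Its per-sample
mean (the *high contrast mean*, HCM) and the percentage of nuclei above a
calibrated cutoff discriminate stressed from intact tissue.

For a nucleus-window with co-occurrence distribution `P` over `G` quantized
gray levels,

    contrast_pct = 100 * sum_(i,j) (i-j)^2 P[i,j] / (G-1)^2      in [0, 100]
    HCM          = mean over nuclei of contrast_pct
    SSMD         = (mu1 - mu2) / sqrt(var1 + var2)

Group comparisons provide Welch/Student/paired t-tests, SSMD effect sizes,
Benjamini-Hochberg adjustment, PCA and a Fisher LDA axis.

Since annotated slides are rarely redistributable, the package ships a
seeded synthetic H&E generator with exact ground truth (epidermal band,
haloed and pyknotic subpopulations, stain-consistent colors) used by the
whole validation suite.

## Worked example

```r
library(histonox)

cfg <- default_config()
cfg$pixel_size_um <- 0.46          # um per pixel of the scans
cfg$output_dir <- "out"

# two synthetic biopsies: a UV-stressed one (30% haloed nuclei)
# and a control (10%); with real data these are your slide TIFFs
uvb  <- run_sample("uvb.tiff",  cfg, sample_id = "uvb",  condition = "uvb")
ctrl <- run_sample("ctrl.tiff", cfg, sample_id = "ctrl", condition = "ctrl")
print(uvb)
#> <SampleResult 'uvb' [uvb]: 243 nuclei, HCM 2.67%, haloed 28.8%>
print(ctrl)
#> <SampleResult 'ctrl' [ctrl]: 215 nuclei, HCM 2.21%, haloed 8.4%>

compare_groups("glcm_contrast_pct",
               uvb$records$glcm_contrast_pct,
               ctrl$records$glcm_contrast_pct, mode = "welch")
#>         descriptor n_a n_b mean_a mean_b var_a  var_b mean_difference
#>  glcm_contrast_pct 243 215  2.675  2.213 1.397 0.5714          0.4624
#>  t_statistic degrees_of_freedom   p_value   ssmd
#>        5.043              416.8 6.856e-07 0.3296
```

Reading: each processed sample reports its nucleus count, the sample HCM
and the percentage of nuclei classified as haloed (score > 4%). Here the
stressed sample's haloed percentage (28.8%) tracks the generated damage
rate, the control sits near its 10% baseline, and the per-nucleus contrast
distributions separate at p ≈ 7e-7 with SSMD 0.33. `run_sample` also writes
the instance masks, a per-nucleus CSV (one row per nucleus, fixed column
schema) and a summary JSON into `out/`.

Batch projects (a directory of slides plus `metadata.csv` with columns
`file,sample_id,condition`) run with `run_batch()`, which adds per-sample
and per-condition aggregate tables and a run manifest. A command-line front
end is installed with the package:

```sh
histonox synth   --config synth.yaml --out demo/        # synthetic slide + truth
histonox run     --image slide.tiff --out out/ --pixel-size 0.23
histonox batch   --project slides/ --out out/
histonox compare --a out/uvb.csv --b out/ctrl.csv --mode welch
```

Externally produced segmentations (e.g. U-Net / star-convex CNN masks) can
replace the built-in classical segmenter: set
`segmentation.backend: external` and place `<sample>_nuclei.tiff` /
`<sample>_epidermis.png` next to each image. Slides can also be exported as
Deep Zoom (DZI) pyramids with `export_dzi()` for viewing.

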