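# relaxotumor

Voxelwise analysis relating quantitative MR relaxometry to amino-acid PET
uptake in glioma, and synthesis of tumor-load probability maps from
T1-relaxation maps.

## The problem

Gliomas infiltrate far beyond the contrast-enhancing lesion, and parts of
the FLAIR-hyperintense margin can carry tumor cell densities approaching
the enhancing core. Amino-acid PET (¹¹C-methionine, "MET") visualizes that
load but is not universally available. This package asks whether
quantitative relaxometry — voxelwise T1 and T2 relaxation-time maps in
milliseconds — can serve as an MR-only surrogate, and turns the answer into
a probability map. It is aimed at neuro-imaging researchers working with
co-registered multi-modal volumes (NIfTI) and stereotactic biopsy data.

## The method

**Stage 1 — histogram contrast against PET.** Analysis-mask voxels are
partitioned by the tumor-to-normal activity ratio (high: T/N > 1.5). For a
scalar map binned with width *w* (defaults: 100 ms for T1, 5 ms for T2,
0.0005 mm²/s for ADC), the per-bin "likeliness of high MET uptake" is

```
L(k) = (nHk/NH − nLk/NL) / (nHk/NH + nLk/NL)  ∈ [−1, 1]
```

with per-bin class counts nHk, nLk and class totals NH, NL. Bins whose
summed class proportions fall below 0.1/B (5% of the uniform expectation
over the B bins spanning the pooled range) are excluded as unreliable. The
longest contiguous run of included bins with L(k) > 0 is the quantity's
positive range — the values characteristic of high uptake.

**Stage 2 — biopsy validation.** Each stereotactic sample's tumor cell
density, TCD = mean(field counts)/0.0497 mm², is compared between samples
whose 1-cm³ VOI-averaged T1 lies inside vs outside the stage-1 band
(closed interval, default 1850–3200 ms), using the pooled-variance
two-sample t-test.

**Tumor-load mapping.** Each T1 voxel is assigned the equal-prior
posterior p = (L(k)+1)/2 of its bin, giving a probability map of heavy
tumor load, with a validity mask for excluded/out-of-range bins.

A seeded synthetic cohort generator (`cohort_spec()`, `simulate_cohort()`)
produces co-registered volumes and biopsy tables with the two-class
structure the analysis assumes, so the full pipeline is testable without
any data download. See the methods vignette
(`vignettes/relaxometry-tumor-load.Rmd`) for the model, parameter
rationale, and limitations.

## Worked example

```r
library(relaxotumor)

spec <- cohort_spec(n_patients = 2, grid_dims = c(64L, 64L, 16L),
                    n_biopsies = 20, seed = 42)
dir <- file.path(tempdir(), "cohort")
simulate_cohort(spec, dir)

cfg <- run_config(dir, file.path(tempdir(), "out"),
                  quantities = c("T1", "T2"))
res <- run_pipeline(cfg)
res$stage1
#> <stage1_result> 2 patients, NH = 1073, NL = 1887
#>   T1 positive range: 2000 - 3300
#>   T2 positive range: 130 - 235
res$stage2
#> <stage2_result> 40 samples
#>   tcd_by_T1_band: <group_comparison> n = 11 vs 29, means 2897 vs 2092,
#>                   t(38) = 2.475, p = 0.01789
#>   tcd_by_tn: <group_comparison> n = 4 vs 36, means 2741 vs 2266,
#>              t(38) = 0.922, p = 0.3622
```

Reading the output: pooling the two simulated patients, 1073 analysis-mask
voxels were MET-high and 1887 MET-low; T1 values of 2000–3300 ms (and T2 of
130–235 ms) were characteristic of the high-uptake class. Of the 40 biopsy
samples, the 11 whose VOI-averaged T1 fell inside the 1850–3200 ms band had
a mean TCD of 2897 cells/mm² against 2092 cells/mm² outside it
(t(38) = 2.475, p = 0.018). Tumor-load probability maps for each patient
are written to the output directory as `tumorload_<id>.nii.gz`.

A command-line front end with `simulate`, `tn`, `convert`, `likeliness`,
`tumormap`, `validate` and `run-all` subcommands is installed under
`exec/relaxotumor`.

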