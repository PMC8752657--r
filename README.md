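# DWItexture

Texture radiomics and test-retest repeatability screening for two-b-value
ADC maps of prostate lesions.

## What this is for

Prostate diffusion-weighted MRI (DWI) yields apparent diffusion coefficient
(ADC) maps whose texture correlates with histological grade group (GG 1–5).
Two questions decide whether such features are usable biomarkers:

1. **Which two b-values** should the ADC map be computed from? With
   acquisitions at b = 0, 100, 1000, 1500 s/mm², the two-point
   monoexponential fit

   ADC = ln(S(b_low) / S(b_high)) / (b_high − b_low)

   gives four candidate maps — (0,1000), (0,1500), (100,1000), (100,1500) —
   that differ because perfusion (IVIM pseudo-diffusion) contaminates the
   b = 0 signal.
2. **Which features are repeatable?** A feature that correlates with grade
   on one acquisition but not on its immediate repeat is noise. With paired
   test-retest DWI, each candidate feature is screened through a staged
   cascade: Spearman ρ versus grade group at *both* examinations, ROC AUC
   for GG 1–2 vs 3–5 (Mann–Whitney with midrank ties, orientation
   recorded), test-retest ICC(A,1) from two-way ANOVA mean squares, and
   Bland–Altman analysis on percentage differences with a >300% SD
   exclusion.

The package is aimed at imaging scientists building or validating such
screening pipelines. It computes per-voxel ADC maps, 46 features per base
image (15 first-order; 6 GLCM; 11 GLRLM; 11 GLZSM; 3 NGLDM — all
higher-order features verified against exhaustive-enumeration references),
applies lesion QC (ROI < 50 voxels, negative ADC voxels, bounding box < 4
voxels), and runs the per-zone cascade. A synthetic paired-acquisition
cohort generator (bi-exponential IVIM-style decay, Rician noise,
grade-dependent effects programmed separately for the peripheral and
transition zones) makes the whole pipeline testable without patient data.

## Worked example

```r
library(DWItexture)
cfg <- syntheticCohortConfig(seed = 1)        # 30 PZ + 19 TZ lesions, paired exams
cohort <- generateCohort(cfg)
bundle <- runFullStudy(cohort, pipelineConfig(dwiBs = 100))
bundle
#> StudyBundle: 49 lesions (49 passed QC, 0 excluded)
#>   PZ_bins32: 230 records, 38 advanced, 38 selected
#>   TZ_bins32: 230 records, 13 advanced, 13 selected

rep <- bundle$reports$PZ_bins32
sel <- rep[rep$selected, c("base_image", "feature", "rho_first", "rho_second",
                           "auc_first", "auc_second", "icc", "ba_sd_pct")]
print(head(sel[order(sel$rho_first), ], 5), digits = 3, row.names = FALSE)
#>     base_image feature rho_first rho_second auc_first auc_second   icc ba_sd_pct
#>  ADC(100,1500) minimum    -0.602     -0.579     0.821      0.817 0.917      5.76
#>    ADC(0,1500)  median    -0.586     -0.560     0.808      0.799 0.991      1.32
#>    ADC(0,1500) minimum    -0.583     -0.558     0.804      0.808 0.912      5.88
#>  ADC(100,1500)  median    -0.572     -0.559     0.799      0.795 0.991      1.35
#>    ADC(0,1000) minimum    -0.566     -0.556     0.790      0.786 0.936      4.81
```

Each row is one (base image, feature) record that survived the cascade on
the peripheral-zone lesions: low ADC level features fall with grade
(ρ < 0 at both examinations), discriminate GG 1–2 from 3–5 (AUC ≈ 0.8),
and are repeatable (ICC > 0.9, Bland–Altman SD a few percent) — the
programmed behaviour of the synthetic peripheral zone. On the transition
zone the selected records are instead heterogeneity features (busyness,
high-gray-level emphases) on the DWI grids, while ADC level percentiles do
not advance: the generator programs grade-dependent signal heterogeneity,
not a diffusivity level trend, into that zone.

Cohorts round-trip to disk as one voxel CSV per lesion-examination
(`row,col,in_roi,b0,b100,b1000,b1500`) plus a JSON manifest via
`writeCohortCsv()` / `readCohortCsv()`; screening tables and QC reports are
written by `writeStudyBundle()`.

See the vignette (`vignettes/dwi-texture-repeatability.Rmd`) for the
models, conventions and design decisions.

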