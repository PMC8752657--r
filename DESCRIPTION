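Package: DWItexture
Title: Texture Radiomics and Test-Retest Repeatability for Two-b-Value ADC Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diffusion-weighted MRI (DWI) radiomics of prostate
    lesions: voxel-wise apparent diffusion coefficient (ADC) mapping from
    two-b-value signal pairs by monoexponential fit, first-order and
    higher-order (GLCM, GLRLM, GLZSM, NGLDM) texture feature extraction from
    masked 2D regions of interest, and a test-retest feature-screening cascade
    combining Spearman correlation with grade group at both examinations, ROC
    AUC for grade group 1-2 versus 3-5, intraclass correlation, and
    Bland-Altman percentage-difference analysis. Includes a synthetic
    paired-acquisition DWI cohort generator (bi-exponential IVIM-style signal
    decay with Rician noise) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic-cohort.R'
    'voxel-io.R'
    'adc-mapping.R'
    'discretize.R'
    'first-order.R'
    'texture-matrices.R'
    'texture-features.R'
    'extract.R'
    'repeatability-stats.R'
    'screening.R'
    'report.R'
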