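Package: fdmap
Title: Functional Diffusion Maps for Longitudinal Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise treatment-response analysis of longitudinal
    diffusion-weighted MRI (DWI). Computes apparent diffusion coefficient
    (ADC) maps by mono-exponential fitting across b-values, performs robust
    affine multiresolution coregistration of sessions with Pearson-correlation
    quality control, derives per-lesion significance thresholds from duplicate
    baseline scans via the one-way-ANOVA repeatability limit, classifies
    lesion voxels into significantly increased (red), significantly decreased
    (blue) and unchanged (green) ADC with cluster-size filtering (functional
    diffusion maps), and produces lesion- and cohort-level response
    statistics (RECIST classification, exact Wilcoxon signed-rank,
    repeated-measures ANOVA with sphericity diagnostics, lesion-size-weighted
    patient means, progression-free-interval correlations). Includes a
    synthetic lung-lesion phantom generator with known ground truth so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
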