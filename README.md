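# fdmap — functional diffusion maps for longitudinal DWI

`fdmap` is an R package for voxelwise treatment-response analysis of
longitudinal diffusion-weighted MRI (DWI), aimed at quantitative-imaging
researchers who want a tested, reproducible implementation of the
functional diffusion map (fDM) method for body tumors — here tuned to
multi-b-value lung-cancer protocols — without depending on in-house
scanner-side software.

## What it computes

Starting from per-session stacks of 3D signal volumes at several diffusion
weightings *b* (s/mm²), the package:

1. **Fits ADC maps** voxelwise from the mono-exponential decay
   *S(b) = S₀ e^(−b·ADC)* by log-linear least squares over all b-values
   (reported in 10⁻³ mm²/s), with a fit-validity mask for low-signal
   voxels, and optionally corrects eddy-current warping by aligning each
   higher-b volume to the lowest-b volume.
2. **Coregisters sessions**: the second baseline and all posttreatment ADC
   maps are aligned to the first pretreatment map with a robust affine
   multiresolution algorithm (Geman–McClure IRLS over a Gaussian pyramid),
   with the Pearson correlation of the two baseline maps before/after
   registration as quality control.
3. **Calibrates significance per lesion**: treating each ROI voxel of the
   duplicate baseline scans as a subject with two replicates, one-way
   ANOVA gives the within-subject SD *s_w*, and the fDM threshold is the
   repeatability limit **τ = 2.77 s_w** — the ADC change exceeded by
   chance only 5% of the time.
4. **Builds fDMs**: on the intersection of baseline and posttreatment
   ROIs, voxels are labelled red (ΔADC > +τ), blue (ΔADC < −τ) or green
   (otherwise); red/blue clusters smaller than 6 voxels (26-connectivity)
   are relabelled green; the red/blue/green fractions summarize the
   heterogeneous response.
5. **Runs the cohort statistics**: RECIST classification from CT diameters
   (partial response = decrease exceeding 30%), exact Wilcoxon signed-rank
   on paired diameters, per-class mean relative ADC changes,
   repeated-measures ANOVA of the fDM/ADC read-outs with tumor-size change
   as covariate or between-subjects factor (with Mauchly sphericity
   diagnostics and Greenhouse–Geisser correction), lesion-size-weighted
   per-patient means, and Pearson correlations with the progression-free
   interval.

A synthetic phantom module (`phantom_spec()`,
`generate_patient_dataset()`) produces five-session longitudinal datasets
— two duplicate baselines plus weeks 1/2/6 — with known ADC fields, known
voxelwise change labels, Rician noise and known inter-session affine
misalignment, so the entire pipeline is testable against ground truth.
Per-lesion CT-diameter and ADC summary tables for a 9-patient, 13-lesion
lung-cancer cohort ship as CSV fixtures and drive the statistics layer.

## Worked example

Statistics-only run on the bundled cohort tables:

```r
library(fdmap)
report <- run_pipeline(list(mode = "stats"))
print(report)
#> fDM pipeline report
#>   CT diameters: mean 3.7 -> 2.8 cm; Wilcoxon p = 0.000244
#>   RECIST: partial_response = 4, stable_disease = 9
```

Mean lesion diameter fell from 3.7 to 2.8 cm after two chemotherapy
cycles; the exact two-sided Wilcoxon signed-rank p-value over the 13
paired diameters is 2/2¹³ ≈ 0.000244 (every lesion shrank), and 4 of 13
lesions qualify as partial response.  `report$statistics` additionally
holds the per-class mean relative ADC changes (partial response:
+16.2%/+9.4%/+19.0% at weeks 1/2/6; stable disease: −7.4%/−8.9%/−3.5%)
and the repeated-measures ANOVA tables (size-change covariate p = 0.011;
dichotomized-group p = 0.045; time p = 0.554).

Full imaging pipeline on a synthetic patient:

```r
report <- run_pipeline(list(phantom = list(noise_sigma = 30), seed = 7,
                            register_sessions = FALSE))
print(report)
#> fDM pipeline report
#>   CT diameters: mean 3.7 -> 2.8 cm; Wilcoxon p = 0.000244
#>   RECIST: partial_response = 4, stable_disease = 9
#>   repeatability threshold: 0.336 x1e-3 mm^2/s (n = 536)
#>   fDM week1: red 27.2% blue 10.8% green 61.9%
#>   fDM week2: red 27.8% blue 10.3% green 61.9%
#>   fDM week6: red 27.4% blue 10.4% green 62.1%
```

The phantom's ground truth put 25% of lesion voxels up and 10% down (by
±1.2×10⁻³ mm²/s); the pipeline estimates the per-lesion repeatability
threshold from the duplicate baselines and recovers fractions close to
truth (the residual excess over 25%/10% is the ~5% chance rate of a 95%
repeatability limit, partially removed by the cluster filter).  A thin
command-line wrapper over the same functions lives at
`inst/scripts/fdm_pipeline.R`.

See `vignettes/fdm-methods.Rmd` for the model, the numerical choices and
the design decisions, and `?phantom_spec`, `?register_affine`,
`?estimate_repeatability_threshold`, `?rm_anova` for the individual
stages.

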