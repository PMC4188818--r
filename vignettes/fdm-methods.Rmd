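---
title: "Functional diffusion maps from longitudinal DWI: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional diffusion maps from longitudinal DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A solid tumor under chemotherapy does not respond uniformly: parts of a
lesion may necrose (water diffusion rises), other parts may remain viable or
swell (diffusion falls).  A single lesion-averaged apparent diffusion
coefficient (ADC) can hide these opposing changes.  The functional diffusion
map (fDM) resolves them voxelwise: after coregistering a posttreatment ADC
map to the pretreatment map, each lesion voxel is labelled *red*
(significant ADC increase), *blue* (significant decrease) or *green*
(unchanged), and the three fractions summarize spatially heterogeneous
response.  `fdmap` implements this analysis for longitudinal multi-b-value
diffusion-weighted MRI (DWI) of lung lesions — two duplicate baseline
sessions plus follow-ups at one, two and six weeks — together with the
cohort statistics used to relate fDM read-outs to CT-based RECIST response,
and a synthetic phantom that makes every stage testable with known ground
truth.

## From signals to ADC maps

DWI signal at diffusion weighting $b$ follows, to good approximation over
the range used here, a mono-exponential decay

$$S(b) = S_0 \, e^{-b \cdot \mathrm{ADC}},$$

acquired at $b = 100, 600, 800\ \mathrm{s/mm^2}$.  The non-zero lower
b-value deliberately suppresses perfusion contributions, and the package
never extrapolates to $b = 0$; $S_0$ is not reported.  `fit_adc_map()`
estimates ADC per voxel by ordinary least squares of $\ln S(b)$ on $b$
(ADC $= -$slope, reported in $10^{-3}\ \mathrm{mm^2/s}$).  With three
b-values a log-linear fit is exact on noiseless data, deterministic, and
numerically trivial; nonlinear refinement buys little and is out of scope.
Voxels with any signal below `min_signal` (default 1 signal unit, i.e.
anything that would make $\ln S$ undefined or meaningless) are marked
invalid in a fit-validity mask.  Invalid voxels propagate as `NA` through
every downstream statistic: they never enter lesion means, thresholds, or
fDM denominators.

## Registration

All sessions are aligned to the first pretreatment ADC map with a
12-parameter affine transform estimated coarse-to-fine over a Gaussian
pyramid (3 levels, downsampling factor 2, smoothing SD 1 voxel).  At each
level the linearized brightness constraint is solved by iteratively
reweighted least squares under a Geman–McClure robust error norm, so that
genuine treatment-induced signal change — which violates the
brightness-constancy assumption focally — is downweighted instead of
dragging the global alignment.  Numerical choices that matter:

* **Robust scale.** The Geman–McClure scale is set each iteration to the
  90% quantile of the absolute intensity residuals, floored at 2% of the
  reference SD.  A MAD-based scale collapses when a large portion of the
  volume already matches exactly (residuals identically zero), which would
  zero the weights of precisely the informative edge voxels; the quantile
  rule instead behaves like least squares while the volumes are grossly
  misaligned and robustifies as the bulk of the volume comes into
  agreement.
* **Parameterization and convergence.** The affine is parameterized about
  the volume centre for conditioning.  Iterations stop when the scaled
  update norm (translations measured relative to the volume half-extent)
  falls below $10^{-4}$, or after 50 iterations per level; each step is
  halved (up to a small number of times) if it does not decrease the
  robust cost.
* **Interpolation.** Intensities are resampled trilinearly; validity masks
  conservatively — an output voxel is valid only if *all* contributing
  source voxels were valid — and binary ROI masks by nearest neighbour.
  The erosion prevents partial-volume contamination of lesion statistics.
* **Quality control and fallback.** The Pearson correlation between the
  two volumes over the whole grid (on the intersection of validity masks)
  is reported before and after registration.  If registration would lower
  it by more than `qc_tol` (default 0.01), the identity transform is
  returned with a warning: the contract is that coregistration never
  silently degrades the data.
* **Eddy-current correction.** Within a session, higher-b volumes are
  affinely aligned to the lowest-b volume.  Because b-value images differ
  by an (approximately monotone) contrast map, the moving volume is first
  quantile-matched to the reference, making the similarity
  correlation-like and contrast-insensitive; the estimated transform is
  then applied to the original signals.

A practical identifiability note: on a near-symmetric lesion against a
flat background, the full affine is weakly identified — errors in the
linear part trade off against translation with little effect on the actual
displacement field, and trilinear interpolation slightly biases parameter
estimates at sharp edges.  Transform-recovery accuracy is therefore stated
(and tested) two ways: per-axis sub-quarter-voxel translation recovery on
smooth textured fields, and mean displacement below half a voxel plus QC
improvement on the sharp lesion phantom.

## The repeatability-limit threshold

What counts as a *significant* voxelwise ADC change is calibrated per
lesion from the duplicate baseline scans.  Treating each valid ROI voxel as
a subject measured twice, one-way ANOVA gives the within-subject variance

$$s_w^2 = \frac{1}{n}\sum_i \frac{d_i^2}{2},$$

with $d_i$ the between-replicate difference at voxel $i$, and the
significance threshold is the repeatability limit $2.77\,s_w$ — the change
magnitude exceeded by chance only 5% of the time for two replicates (the
standard Bland–Altman repeatability coefficient; the literal constant 2.77
is used).  The scope is per lesion by default, with per-patient pooling
available in the pipeline configuration, since determining the threshold
directly in each tumor is the more accurate variant of the method.

Classification uses a strict inequality: $\Delta\mathrm{ADC}$ must *exceed*
the limit ($\Delta > +\tau$ red, $\Delta < -\tau$ blue, otherwise green).
A change exactly at the limit is not significant.  Because $\tau$ is a 95%
limit, about 5% of genuinely unchanged voxels will exceed it by chance;
the cluster-size filter exists to remove most of these: connected
components are computed separately for red and blue voxels and components
smaller than 6 voxels are relabelled green.  Connectivity is
26-neighbourhood in 3D by default (lesions span few thick slices, so
in-plane diagonal contact should connect), configurable to 6 or 18; the
filter never touches green voxels and can only reduce the significant
fraction.  fDMs are computed on the intersection of the baseline ROI and
the (coregistered) posttreatment ROI, and the three fractions always sum
to one over valid intersection voxels.

## Cohort statistics

* `recist_classify()`: percent diameter change from CT;
  partial response requires a decrease *exceeding* 30%, so a decrease of
  exactly 30% is classified stable disease (the boundary is undefined in
  the usual "<30% / >30%" phrasing; no real lesion in the bundled tables
  sits on it).
* `wilcoxon_signed_rank_exact()`: exact two-sided paired test by full
  enumeration of the $2^n$ sign assignments (generating-function
  convolution with doubled ranks, so mid-ranks from ties are handled
  exactly) for $n \le 20$; tie-corrected normal approximation with
  continuity correction above.  Zero differences are dropped before
  ranking, Wilcoxon's original treatment.
* `rm_anova()`: classical univariate repeated-measures decomposition (one
  within factor, time; one between term) fitted via `stats::aov` with
  `Error(unit/time)` strata.  The size term enters either as a centred
  continuous covariate or as the dichotomized RECIST class.  Mauchly's
  sphericity test (via `stats::mauchly.test` on the orthonormal-contrast
  covariance) accompanies every fit, and when it rejects at 0.05 a
  Greenhouse–Geisser-corrected p-value is reported next to the
  uncorrected one.
* `patient_weighted_mean()`: patients with several lesions contribute
  lesion-size-weighted means; the default weight is the baseline CT
  diameter (the natural reading of "weighted by size"), with
  area-proportional (diameter$^2$) weighting as a configuration option.
* `pfs_correlation()`: Pearson correlation of per-patient week-1
  parameters with the progression-free interval, after dropping excluded
  patients (e.g. death unrelated to progression).  The published
  correlation for this cohort depends on an unstated weighting/parameter
  convention and is deliberately not treated as a reference value.

The bundled per-lesion CT and ADC tables reproduce the cohort's worked
results when fed through `run_pipeline(list(mode = "stats"))`; the test
suite asserts the group mean relative ADC changes, the RECIST split, the
exact Wilcoxon p-value and the repeated-measures p-values at their printed
precision.

## The phantom

`phantom_spec()` defaults encode a realistic lung-DWI acquisition rather
than convenient test settings: $2\times2$ mm in-plane voxels with 6 mm slices,
b = 100/600/800 s/mm², an ellipsoidal lesion a few centimetres across,
baseline lesion ADC $1.4\times10^{-3}\ \mathrm{mm^2/s}$ with a smooth
Gaussian-random-field texture (SD 0.15, correlation length 6 mm — the
texture model is a stand-in for unknown intratumoral structure, not a
biological claim), low-signal background with a distinct ADC so masking
errors are detectable, and $S_0 = 1000$ with Rician noise
$\sigma = 55$.  That noise level was chosen by propagating the Rician
noise through the log-linear fit so that the implied per-lesion
repeatability threshold lands near the middle of the range reported for
lung tumors at 1.5 T (around $0.6\times10^{-3}\ \mathrm{mm^2/s}$).
Treatment effect is applied from week 1 onwards as piecewise-constant
blocks of at least 8 contiguous voxels (so true labels survive the
6-voxel cluster filter) covering 25% of lesion voxels with an ADC increase
of $1.2\times10^{-3}$ and 10% with the corresponding decrease; a flag can
inject isolated single-voxel changes to exercise the filter.  Both
baselines share one true ADC field and differ only by noise and optional
misalignment (a single affine per session; noise is added after
resampling, as acquisition noise would be).  Generation is a pure function
of the spec and seed, and the returned truth record carries everything
needed for recovery tests: per-session true ADC fields, the voxel label
volume, the true fractions, and the applied transforms.

What the phantom does *not* emulate: k-space/EPI distortion, partial
Fourier, respiratory motion within a session, lesion shrinkage between
sessions, or cavitation.  Passing recovery tests therefore demonstrates
the correctness of the pipeline's computations under the stated forward
model, not robustness to every artifact of in-vivo lung DWI.

## Problem sizes and noise regimes used in the tests

The shipped tests run the phantom at $40\times40\times12$ voxels
(registration-oriented tests use $24^3$–$32^3$ isotropic grids) with 10
Monte-Carlo seeds for recovery and QC properties, and 1000 replicates for
the repeated-measures ANOVA type-I/power simulation — sizes at which every
property is stable yet the whole suite completes in a couple of minutes.
Fraction-recovery checks run at $\sigma = 20$ with the default change
magnitude, satisfying the supra-threshold condition (change $\ge 2\times$
the resulting threshold) under which voxel misclassification is rare.  At
the full study-like $\sigma = 55$, the post-treatment signal at
$b = 800$ in strongly responding voxels (ADC
$\approx 2.6\times10^{-3}\ \mathrm{mm^2/s}$) approaches the Rician noise
floor; the resulting ADC bias shrinks measured changes and red fractions
are under-recovered by a few percentage points.  This is a genuine
limitation of fDM analysis at low SNR, not an implementation artefact,
and it motivates the duplicate-baseline threshold: the threshold and the
classification errors scale together with noise.

## Known limitations

* Affine-only registration: regressing tumors deform non-affinely; the
  assumption that regression proceeds periphery-to-centre (which justifies
  intersecting ROIs) is an approximation.
* No IVIM/kurtosis modelling; perfusion suppression relies entirely on
  the b = 100 floor.
* The repeatability threshold assumes exchangeable replicate noise across
  baseline sessions; scanner drift between the two baseline acquisitions
  would inflate it.
* Pure-R connected components and resampling are sized for lesion-scale
  volumes, not whole-body data.

```{r}
library(fdmap)
report <- run_pipeline(list(mode = "stats"))
print(report)
```
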