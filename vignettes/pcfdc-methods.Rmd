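---
title: "Lesion network mapping with principal-component refined seeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion network mapping with principal-component refined seeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfdc)
```

## The problem

A focal brain lesion disrupts function far beyond its borders, through the
long-range connections that pass through or terminate in the damaged tissue.
Lesion network mapping estimates this *indirect functional disconnection*
without any patient fMRI: the binary lesion mask is embedded as a seed region
in a normative cohort of healthy resting-state runs, the seed's mean BOLD
time-course is correlated with every brain voxel, and the per-subject maps
are Fisher-z transformed and averaged into an *r-map*.

The weak point of this baseline (here called FDC, functional disconnection)
is the seed itself. A typical stroke lesion straddles grey matter, where BOLD
fluctuations are strong and network-specific, and white matter, where the
BOLD amplitude is roughly a quarter to a half of its grey-matter level and
largely non-specific. Averaging the raw signal over the whole lesion dilutes
the coherent grey-matter signal with low-SNR white-matter voxels, inflating
widespread weak connectivity and blurring network topography.

## The PC-FDC refinement

The refinement implemented by this package selects the coherent lesion
compartment *before* seeding:

1. For each normative subject, compute all pairwise Pearson correlations
   among the lesion voxels' time-series, Fisher-z transform them, and average
   each voxel's correlations to the *other* lesion voxels. This gives each
   voxel's mean within-lesion connectivity strength (`within_lesion_strength()`).
2. Stack these vectors over the m normative subjects into an n × m strength
   matrix (`build_strength_matrix()`), n being the lesion voxels.
3. Exclude subjects whose global absolute strength deviates from the sample
   mean by more than 3 SD (`exclude_outlier_subjects()`): PCA is sensitive to
   single outlying brains.
4. Run a PCA with subjects as observations and voxels as variables
   (`pc1_coefficients()`). The first component is the main within-lesion
   connectivity axis; its loadings — one per voxel — are projected back into
   lesion space.
5. Keep the voxels whose absolute coefficients strictly exceed the 20th
   percentile of the coefficient distribution (`threshold_seed()`); the
   result is the refined seed mask.

Voxels that share a coherent signal co-vary across subjects and dominate the
leading eigenvector, while incoherent voxels receive near-zero loadings, so
the retained seed concentrates on the grey-matter compartment. Everything
downstream (r-maps, t-maps, atlas assignment, behaviour prediction) is
identical between FDC and PC-FDC except the seed.

## Conventions and numerical choices

* **Within-lesion averages exclude the diagonal.** A voxel's self-correlation
  is r = 1, infinite after the z-transform; including it would make every row
  average infinite. Off-diagonal perfect correlations (duplicate series) are
  clipped to |r| = 1 − 1e-7 with a warning.
* **Covariance PCA, variables centred across subjects, no scaling.** Scaling
  voxels to unit variance would discard exactly the amplitude information
  that separates coherent from incoherent voxels. The component sign is fixed
  so the coefficients correlate non-negatively with the subject-mean strength
  vector; absolute values drive thresholding, so results are sign-invariant,
  but a fixed convention keeps runs bit-reproducible.
* **Percentiles interpolate linearly between order statistics** (R's default
  quantile type 7), and the seed keeps voxels *strictly above* the cutoff.
  With all-tied coefficients the seed would be empty; that is an error, not a
  silent fallback. The sweep values 5/10/20/50/80 are supported for
  sensitivity analysis.
* **Voxel validity is harmonized by intersection**: a lesion voxel that is
  flat or outside the brain mask for any normative subject is dropped for
  all, keeping the strength matrix rectangular with one shared voxel order
  (lexicographic over array axes, axis 3 fastest, 1-based).
* **Grids are never silently resampled.** Every volume must match the
  analysis grid exactly (affines equal within 1e-6); an explicit
  nearest-neighbour utility exists for binary masks only. Misaligned lesions
  are a known silent failure mode of this family of methods, so misalignment
  here is a loud error.
* **Zero-variance voxels** in a run get z = 0 with a warning in correlation
  maps; voxels with zero SD across subjects get t = 0 (zero mean) or a signed
  sentinel excluded from the permutation maximum (non-zero mean).

## Permutation inference

t-maps use the one-sample t statistic over subject maps with a sign-flipping
null, and both group comparisons and the behaviour-covariate regression use
label permutation. Family-wise error is controlled with the max-statistic
distribution across voxels: each permutation contributes the maximum
|t|, and a voxel's FWE p is the fraction of permutations whose maximum
reaches its observed statistic. The identity permutation is always included,
so p ≥ 1/n_perm and the test is never anti-conservative by construction.
This package deliberately performs *voxelwise* max-statistic correction and
no cluster enhancement: threshold-free cluster enhancement depends on a
cluster-integration step that is out of scope here, while the max-statistic
procedure is exact for the same exchangeability null. Paired contrasts are
reported one-sided at α = 0.025 per direction, matching a two-tailed 0.05.
The covariate regression uses the Freedman–Lane scheme: data are residualized
against the nuisance-only model (lesion volume + intercept), residuals are
permuted, the nuisance fit is added back, and the full model is refit.

## Atlas assignment

`nci()` correlates an r-map with every canonical template over the domain
mask (the whole brain mask by default; templates are treated as intensities,
binary ones as 0/1). The winner-take-all network confidence index is

NCI = sc(winner) / mean(sc(losers)),

a specificity score: high when the map matches one canonical network much
better than the rest. The paper-level edge cases are handled explicitly —
winner ties break by atlas order, and a non-positive losing mean makes the
ratio undefined (flagged, winner still reported). On strongly
network-specific synthetic maps the losing correlations are often negative,
so the undefined flag is common there; the winner identity is the robust
quantity.

## Behaviour prediction

Subject r-maps are reduced by PCA (subjects as observations, brain voxels as
variables), keeping the smallest leading set of components reaching 95%
cumulative variance. Component scores are z-normalized with one global
mean/SD pair for the whole matrix (population SD; per-column scaling would
distort the relative importance of components). Ridge weights use the closed
form W = (XᵀX + λI)⁻¹XᵀY with no intercept — both features and outcome are
centred by their normalization. λ is tuned over 100 log-spaced values in
[1e-5, 1e5] by exact leave-one-out error (the ridge hat-matrix identity
e = (y − ŷ)/(1 − h) makes this a closed form, verified against brute-force
refitting to 1e-8 in the tests).

The cross-validation is *nested*: each outer leave-one-out fold tunes λ by an
inner leave-one-out loop over its n − 1 training subjects, so every
prediction is strictly out of sample. Accuracy is the coefficient of
determination with the **prediction-mean denominator**,
R² = 1 − Σ(Y − Y′)² / Σ(Y − mean(Y′))², implemented literally as the original
framework defines it; it can be negative and differs from the textbook
convention, which is available behind `conventional = TRUE` but never
silently substituted. Significance permutes the outcome across subjects
(10 000 times at full scale), reruns the entire nested pipeline per
permutation, and counts strictly better null R² values — the plain
`b/n_perm` rule as defined, with the `(b+1)/(n_perm+1)` correction behind a
flag. Reliable weights are found by t-testing each component's fold-weight
distribution against the pooled null fold weights (harvested from the same
permutation runs, avoiding a second pass), Benjamini–Hochberg across
components, and back-projecting survivors through the transposed loadings.

## The synthetic generator

`make_normative_cohort()` plants disjoint networks on a template grid. Voxel
v of subject s follows

x_v(t) = a_v ℓ_k(t) + g(t) + ε_v(t),

with ℓ_k the network's latent time-course (white Gaussian, sd 1 by default),
a_v = 1 in grey matter and `wm_signal_scale` (default 0.35, inside the
physiological ¼–½ range) in white matter, g an optional brain-wide shared
signal, and ε tissue-specific white noise (sd 1). White latent signals keep
every expected correlation in closed form — two grey-matter members of one
network correlate at (s² + γ²)/(s² + γ² + σ²), reducing to s²/(s² + σ²)
without the global term — which is what the generator's tests assert.

The global component (γ = 0.3 in the canned `demo_cohort()`, i.e. ~9% of the
noise variance) emulates the non-specific global/physiological signal of real
BOLD. It matters for one result family: whole-lesion seeds average many
incoherent voxels, so the shared component survives while specific signal is
diluted, giving FDC maps their widespread weak positive correlations — FDC
then leads on the mean over all positive z while PC-FDC leads above
z > 0.2, the crossover the map-comparison statistics quantify. A closed-form
sketch with s = σ = 1, γ = 0.3 and a half-coherent 40-voxel lesion puts the
FDC background z near 0.15 versus 0.08 for PC-FDC, and the in-network z near
0.87 versus 0.91, which is exactly the pattern the replicate tests observe.

What the generator does *not* emulate: haemodynamic autocorrelation, motion
and physiological noise spectra, scanner drift, overlapping networks, and
spatial smoothness. Passing tests therefore demonstrate the estimators'
internal correctness and the direction of tissue-SNR-driven effects, not
performance on real MRI.

## Problem sizes used in tests and the reproduction script

All validation runs on scaled-down study conditions chosen to keep the full
suite in a few minutes on one core, while preserving each mechanism:

* **Seed selectivity**: 50 lesions (20 coherent GM + 20 pure-noise WM voxels)
  against cohorts of 24 subjects × 150 timepoints under the network-specific
  model (γ = 0). First-component fidelity is an eigenvector-estimation
  problem, so this is the one scenario where the normative cohort cannot be
  shrunk too far: with very few subjects the PC1 loadings of noise voxels are
  no longer negligible. 24 subjects — about a seventh of a realistic
  normative sample — is the smallest size that leaves a comfortable margin.
* **Crossover, atlas assignment**: 20 and 30 lesions on a 12-subject,
  150-timepoint cohort with the global component (γ = 0.3), 12³ grid at 2 mm.
* **Prediction**: 60 subjects, behaviour = Σ_v w(v)·map(v) + noise with
  noise sd set to half the signal sd (SNR ≈ 2), 500 outcome permutations;
  null calibration with 50 × 200 permutations and 100 null t-map simulations
  at 200 permutations.

## Known limitations

* The NCI denominator uses losing correlations as-is; with non-positive
  losing means the index is undefined rather than clamped.
* The percentile convention (absolute coefficients, strict inequality,
  linear interpolation) is one reasonable reading of the method's
  description; both the reference distribution and the interpolation rule
  are configurable at the call sites where it matters.
* Second-component seeds are available by passing `component = 2`, but no
  PC2-specific pipeline exists.
* The prediction framework supports generic feature concatenation but no
  structural-plus-functional fusion logic, and only ridge regression — no
  alternative learners or non-linear dimensionality reduction.
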