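---
title: "Mapping CSF waterways from low b-value diffusion MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping CSF waterways from low b-value diffusion MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfpsi)
```

## The signal model and what MΨ measures

At low diffusion weightings (b ≲ 350 s/mm²) the CSF signal retains most of
its magnitude and its attenuation is dominated by slow, incoherent fluid
motion. The per-voxel model is the monoexponential tensor form

$$ S(b, \mathbf{g}) = S_0 \exp(-b\, \mathbf{g}^\top \Psi\, \mathbf{g}), $$

where the apparent tensor Ψ decomposes as Ψ ≈ (τ_d/2) V + D: a
velocity-distribution covariance term V (pseudorandom laminar/mixing flow)
plus the molecular diffusion tensor D, with τ_d the diffusion time of the
sequence. The scalar currency of the whole pipeline is the mean
pseudo-diffusivity MΨ = tr(Ψ)/3 (mm²/s): under stable temperature and
viscosity it indexes the flow-velocity variance within a voxel. Because τ_d
is sequence-dependent and rarely recorded in public metadata, the V/D
decomposition (`velocity_covariance`) takes τ_d as a user input and no
downstream stage depends on it.

`fit_pseudo_tensor` estimates (ln S_0, Ψ) by ordinary least squares on the
log signal against the 7-parameter design. We use the log-linear rather than
a weighted or nonlinear estimator deliberately: at low b the attenuation is
small (high effective SNR in CSF), the linearization bias is negligible, and
the estimator is deterministic — important because every downstream stage is
validated by exact recovery tests. Design choices the data cannot decide:

* multiple b = 0 volumes are averaged into one reference before fitting;
* nonpositive samples (possible under noise) are floored to 10⁻⁶·S_0 and the
  voxel flagged, rather than dropped, keeping the design identical across
  voxels;
* fitted tensors are stored without eigenvalue clamping; a `nonphysical`
  flag marks voxels with a negative eigenvalue so problems stay diagnosable.
  FA is computed from rotational invariants with the 0/0 case at the zero
  tensor defined as 0.

The per-shell normalized RMSE (`nrmse`) — residual RMS between model and
measurement on one b-shell divided by the voxel's mean shell signal — is a
proxy for temporal (cardiac/respiratory) variability in ungated
acquisitions; the phantom exposes a `pulsatility` option (per-volume tensor
jitter) that reproduces the expected monotone relationship.

## The CSF analysis domain

The two-tissue step segments CSF from parenchyma using only diffusion
contrast (high MD / low FA vs low MD / higher FA), a two-class bivariate
Gaussian-mixture EM on standardized (FA, MD) features, initialized by
k-means under a fixed seed so results are reproducible; the class with the
higher mean MD is CSF and posteriors serve as partial-volume fractions. The
pseudo-T1 image is the fixed linear contrast 2·WM + 1·CSF, used only to give
registration tools a T1-like target.

The group CSF mask keeps a voxel iff its CSF fraction exceeds 0.7 in
strictly more than 65 % of subjects — both inequalities strict, following
the rule's wording literally; a fraction of exactly 0.7 never counts.
In-mask voxels below the fraction threshold are filled with the mean of
their 26-connected satisfactory neighbours, iteratively so that newly
filled voxels become donors; voxels with no donor path are flagged rather
than invented. Smoothing uses a Gaussian kernel with σ = FWHM/√(8 ln 2)
per axis (default FWHM 3 mm), with weights restricted to the mask and
renormalized to sum to one at each voxel — computed exactly as the ratio of
separable convolutions of x·m and m — so constants are preserved and no
out-of-mask signal bleeds in. Whether the fill should precede or follow
group-mask construction is ambiguous in a purely verbal description; this
package fills after the group mask exists, because donors are then defined
on the common domain.

## Seed-based covariance mapping

`seed_correlation` computes, across subjects, the Pearson correlation
between an ROI's mean MΨ and every in-mask voxel, with two-sided p-values
from the t transform at N − 2 degrees of freedom (sidedness is a choice;
two-sided is the conservative default). For multiple seed ROIs the
correction is one BH procedure over the pooled voxel p-values of all maps —
the strictest defensible reading of "corrected for k ROIs" — with a
per-ROI Bonferroni option (`bonferroni_rois`) behind a flag.

## Orthonormal projective NMF

The parcellation stage factorizes the nonnegative voxels × subjects matrix
X (CSF MΨ maps stacked as columns) as X ≈ W H with W ≥ 0 and *projective*
coefficients H = WᵀX, so the objective is ‖X − W WᵀX‖_F and the
orthonormality WᵀW ≈ I emerges from the geometry of the projector rather
than an explicit constraint. Fitting uses the multiplicative update
W ← W ⊙ (XXᵀW) ⊘ (W WᵀXXᵀW), always evaluated as X(XᵀW) so the D × D Gram
matrix is never formed.

Two numerical choices matter and were settled empirically:

* **Normalization.** Rescaling W per iteration by a single scalar (its
  spectral norm) and normalizing columns only on output reaches the
  parts-based near-orthonormal solution from nndsvd, random and even
  indicator initializations. Per-iteration *column* normalization — an
  obvious alternative — creates stable non-orthonormal fixed points in
  which one column stays global (‖WᵀW − I‖ ≈ 0.3 and reconstruction error
  far above the parts optimum), and was rejected.
* **Monotonicity.** The multiplicative update has no general descent
  guarantee. The fitter therefore damps the step geometrically (a
  fractional power of the update ratio) whenever a full step would increase
  the recorded objective; on all test fixtures the damped trace is
  non-increasing while converging to the same solutions.

Initialization defaults to nndsvd (deterministic nonnegative double SVD);
exact zeros in the initializer are lifted to 10⁻⁶·mean(X) because
multiplicative updates cannot reactivate a zero. Convergence is declared
when the relative objective change falls below `tol` (default 10⁻⁶) or the
objective reaches 10⁻⁹·‖X‖_F — the latter because on noiseless data the
error decays geometrically toward zero and a purely relative test never
fires. Orthonormality at convergence is tight (‖WᵀW − I‖_max ≤ 10⁻³) on
data that satisfy the parts model exactly; with measurement noise the soft
constraint deviates at the noise scale (∼10⁻²), which is expected behaviour
and not a failure of the optimizer. Two limits are intrinsic: for
K > rank(X) no nonnegative near-orthonormal basis exists inside X's column
space, so rank-deficient (e.g. noiseless) inputs should only be fit at
K ≤ rank; and like all NMF variants the objective is non-convex, so the
reconstruction-error-versus-K curve can show small local-minimum bumps.

Hard labels take the argmax over basis columns per voxel, ties broken
toward the lowest column index and flagged — a deterministic rule needed to
compare solutions by ARI and to export a reproducible atlas.

## Split-half stability selection

For each of `n_boot` (default 20) replicates the subjects are split into
covariate-balanced halves (an exchange-heuristic approximation to
anticlustering over standardized means/proportions of the balance
covariates), each half is resampled with replacement, opNMF is fit on both
halves for every K in `k_range` (default 2–25), and the ARI between the two
hard label maps is recorded. A fresh split is drawn per replicate so the
procedure exercises both split and sampling variability; a fixed-split
variant is available (`fixed_split = TRUE`). K is selected as the
reproducibility optimum (highest mean ARI); when the reliability optimum
(lowest ARI SD) disagrees, the candidate with the lower full-data
reconstruction error wins. With `n_boot = 1` the SD is undefined and is
reported as 0 with a warning.

The ARI itself uses the standard pair-counting contingency form,
(Index − E)/(Max − E), with the 0/0 case (two identical single-cluster
partitions) defined as 1; it is validated against a brute-force O(n²)
oracle.

## Cohort statistics

Pattern-wise mean MΨ values per subject form the substrate of all
group-level models. Values beyond 1.5 × IQR (type-7 interpolated quartiles)
are excluded per outcome before modelling. Determinant models are OLS on
z-standardized outcome and predictors — binary predictors coded 0/1 before
standardization — so coefficients are standardized effect sizes; multi-cohort
aggregation uses a random-intercept linear mixed model (REML, Satterthwaite
p-values), and in both cases p-values are FDR-adjusted across the whole
pattern × predictor family of the model. Aberrant CSF flow is flagged per
subject when (i) any pattern deviates by strictly more than 3 SD from its
stratum mean, or (ii) at least two patterns deviate by strictly more than
2 SD; strata are cohorts by default since population SDs differ across
acquisition protocols, with a pooled option. Enrichment of external
findings among aberrant subjects uses the Fisher exact test (two-sided by
default; on tables with an empty cell in the non-aberrant row the one- and
two-sided versions coincide, which the test suite verifies by brute-force
enumeration).

One caveat recorded rather than hidden: 1.5 × IQR exclusion is not
mathematically idempotent — on heavy-tailed data a second pass can exclude
further values because the quartiles tighten. On the near-normal
per-pattern means this pipeline produces, a second pass removes nothing,
and the test suite checks exactly that regime.

## The phantom: what it emulates and what it does not

`make_phantom_population` plants K nonnegative spatial patterns (disjoint
blocks by default; Gaussian blobs and midline-mirrored blobs are available
to emulate overlapping and bilaterally symmetric geographies), draws
per-subject pattern coefficients, embeds the resulting MΨ fields in a
parenchyma background with realistic diffusion contrast (CSF MD ≈ 3×10⁻³,
parenchyma ≈ 0.8×10⁻³ mm²/s; optional prolate parenchyma tensors with
closed-form FA), and synthesizes DWI through the forward model with Rician
noise — the correct magnitude-MRI noise model, with Gaussian as an option.

Coefficients are built so that stated covariate effects are *standardized*
effects: the latent per-subject score is Σ β_c z_c + ε with the noise
variance set to 1 − Σβ² (unit total variance), hence a planted β is exactly
the standardized regression coefficient the GLM stage should recover, and
recovery is unbiased rather than attenuated. Scores enter multiplicatively
at a 20 % coefficient of variation around a positive mean. Outlier subjects
shift a chosen pattern's coefficient by a stated number of SDs. Covariates
follow an aging-cohort profile (age 45–90; BPF declining ≈ 0.0025/year
around 0.82 with SD 0.05; ventricular volume and CBF trending with age) —
the BPF noise is deliberately large enough that age and BPF are correlated
(r ≈ 0.5) but not collinear, as in real aging cohorts.

Default study conditions, used by the recovery tests: 20×20×20 voxel grid
(2 mm), 40 subjects, K = 4 disjoint block patterns, Rician σ = 0.02·S_0,
one b = 0 plus seven directions at b = 50–350 s/mm². The reference-scale
analyses behind the method (hundreds of subjects, ~10 patterns, template
space) are not reproducible at desk scale; the phantom demonstrates
*recovery of planted structure*, not the anatomy-specific findings. The
phantom deliberately omits susceptibility/eddy artifacts, registration
error, cardiac gating waveforms and realistic neuroanatomy, so passing
tests certify the estimators and selection machinery, not robustness to
acquisition physics.

Problem sizes in the test suite and acceptance script (bootstrap count 20,
K range 2–6, the 200-replicate null-FDR study, the 10³-voxel GLM phantom
with N = 500) were chosen as the smallest sizes at which each property is
cleanly identified; all randomness is seeded and every size is stated where
it is used.

## Known limitations

* The tensor fit assumes monoexponential decay over the fitted b-range; no
  multi-compartment (IVIM-type) separation is attempted.
* Subjects are assumed co-registered to a common grid; template
  construction and registration are out of scope.
* opNMF inherits NMF non-convexity: different initializations can reach
  different local optima, which is precisely why the split-half stability
  machinery — not the reconstruction error alone — selects K.
* The aberrant-flow criteria are z-score rules within a stratum; they
  presume roughly unimodal pattern distributions and at least ~10 subjects
  per stratum.
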