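---
title: "Methods: the ICH radiomics prediction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ICH radiomics prediction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models and procedures, the parameters that matter, the numerical choices made
where the design was genuinely open, and the limits of what the synthetic
test bed can show. All empirical statements below are computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from external data.

## The prediction problem

After spontaneous intracerebral haemorrhage, two outcomes dominate early
decision making: *haematoma expansion* — volumetric growth of the haematoma
by more than 6 mL or more than 33% of baseline on the follow-up scan — and
*poor functional outcome*, a modified Rankin scale of 4–6 at day 90. Both are
predicted here from the baseline noncontrast CT alone. The haematoma is
segmented (the package consumes voxel-aligned label masks; it does not
segment), a large battery of quantitative features is extracted from the
haematoma region, and a penalised logistic model maps features to risk.

## Image standardisation and the filter bank

CT volumes arrive with anisotropic voxels (thick axial slices). All volumes
and masks are resampled to 1 mm isotropic before feature extraction:
intensities trilinearly, masks per label with a 0.5 fraction rule (each
output voxel takes the label with the largest interpolated indicator, which
reduces to thresholding at 0.5 where one label is present). The output grid
is voxel-centre aligned and covers the input extent half-open on the far
edge, so a 20×20×4 volume at 0.5×0.5×5 mm becomes 10×10×20 at 1 mm. The
interpolation scheme for this family of pipelines is rarely reported;
trilinear-plus-threshold was chosen because it is deterministic and gives
smoother region boundaries than nearest-neighbour.

Texture is computed not only on the intensities but on filtered versions of
the scan, 13 images in total with a frozen naming contract
(`Intensities`, `LoG-05` … `LoG-35`, `Wavelet-LLL` … `Wavelet-HHH`):

* **Laplacian of Gaussian** at σ ∈ {0.5, 1.5, 2.5, 3.5} mm, scale-normalised
  by σ², highlighting blob- and edge-like structure at increasing scales.
  The kernels are sampled Gaussian second derivatives corrected to exact
  zero sum, so constants map to exactly zero; boundaries reflect.
* **Stationary (undecimated) wavelet subbands**, one level, separable over
  the three axes, letter *i* of the subband name giving the low/high-pass
  filter along axis *i*. The transform is undecimated so every subband is
  voxel-aligned with the mask. Default kernel is the 6-tap Coiflet-1 pair
  under the stationary normalisation (per-filter scaling by 1/√2), which
  makes the low-pass taps sum to 1 — the `LLL` response of a constant is
  that constant — and makes the eight subband energies sum exactly to the
  input energy under periodic boundaries (checked numerically in the test
  suite). Reflection is the default boundary for analysis; the periodic
  option exists because the Parseval identity is only exact there.

The wavelet family and the decimation question are genuinely open in this
literature; both are configurable (`coif1`, `db2`, `sym4`, `haar`), and the
undecimated default is a deliberate alignment-over-speed choice.

## The 754-entry feature catalogue

Per subject the catalogue is: 56 features for each of the 13 images
(18 first-order, 12 GLCM, 11 GLRLM, 10 GLSZM, 5 NGTDM), 24 shape features of
the haematoma mask, and the perihaematomal oedema and intraventricular
haemorrhage volumes in mL — `13 × 56 + 24 + 2 = 754`, asserted at
configuration load. The published feature list behind this total is not
available in full, so the family composition is config-frozen here and the
count is the contract.

Conventions that matter when comparing against other radiomics software:

* Discretisation is fixed-bin-number, `Ng = 32`, over the ROI intensity
  range of *each image separately* (filter outputs are not in Hounsfield
  units); level k covers `[min + (k−1)w, min + kw)`, maximum mapped to Ng.
  Fixed bin number keeps texture comparable across HU-shifted filtered
  images, which is why it was preferred over fixed bin width.
* First-order: population variance; Pearson (non-excess) kurtosis, i.e. a
  Gaussian scores ≈ 3; percentiles by linear interpolation between order
  statistics; entropy/uniformity on the 32-level discretisation.
* GLCM: 13 unique 3-D directions at distance 1, counts symmetrised and
  normalised per direction, matrices averaged over directions with at least
  one pair. GLRLM: matrices per direction, features averaged. GLSZM zones
  and NGTDM neighbourhoods use 26-connectivity. Degenerate cases are pinned
  by tests (constant ROIs give zero contrast/complexity; correlation of a
  constant texture is defined as 1; NGTDM coarseness with a zero
  denominator is reported as 1e6).
* Shape: axis lengths are `4·sqrt(λ)` of the population covariance
  eigenvalues of voxel-centre coordinates; elongation and flatness are
  `sqrt(λ2/λ1)` and `sqrt(λ3/λ1)`; degenerate regions (< 4 voxels or
  rank-deficient covariance) report axis features as 0 with a warning.

**Surface mesh.** Sphericity `(36π V²)^{1/3}/A` needs an accurate surface
area. A mesh taken directly on the binary mask at the 0.5 iso-level
systematically overestimates the area of smooth bodies (the voxel staircase
adds ~8% for marching cubes and more for marching tetrahedra), which would
push a digital ball's sphericity to ~0.92 — an artefact of the estimator,
not the shape. The package therefore anti-aliases the indicator with a 3³
mean filter before triangulating with marching tetrahedra; on a radius-20
digital ball this yields area within ~1% of 4πr² and sphericity ≈ 0.982
(test-asserted within [0.97, 1.005]). The cost is that sharp corners are
slightly rounded; shape features of genuinely polyhedral regions will be
biased smooth, which is acceptable for haematomas.

## Batch harmonisation

Slice thickness induces location–scale batch effects in radiomics features.
Subjects are binned into three acquisition batches (thickness < 2 mm,
2–4 mm, ≥ 4 mm) and harmonised by parametric empirical-Bayes ComBat: per
feature, batch means and covariate effects (age, gender) are estimated by
least squares; data are standardised by the pooled residual scale; per-batch
location/scale effects are shrunk toward method-of-moments priors (normal
for locations, inverse-gamma for squared scales) by iterating the
conditional posteriors to a relative tolerance of 1e-4 (max 100 iterations);
the adjustment restores the grand intercept and covariate effects. The
implementation was cross-validated against the reference Bioconductor
implementation to < 1e-4 on shared designs.

Two semantics are frozen as contracts:

* **Train-then-apply.** All parameters are estimated on the training table
  and serialised (`combat_model_to_json()`); test subjects are adjusted with
  stored parameters only, and unseen batch levels are an error. Reference
  implementations differ here; this package never lets test data update the
  model.
* **Single batch = identity.** With one batch level there is nothing to
  adjust; the table passes through unchanged.

Empirical-Bayes shrinkage makes harmonisation *not exactly idempotent*: on
an already-harmonised table the residual sampling noise in the per-batch
scale estimates is shrunk again, changing values by ~0.5% of a standard
unit per pass at n = 200/batch. The tests therefore assert that the change
is small and contracts across passes, rather than an unattainable exact
fixed point.

Instead of judging batch mixing from an embedding plot, the package scores
it: `batch_mixing_score()` is the mean silhouette of the batch labels on
standardised features. Three cleanly separated batches score > 0.5; randomly
permuted labels score ≈ 0; the score strictly decreases across
harmonisation in the injected-shift simulation.

## Feature selection and the elastic net

Redundancy is removed by an iterative correlation filter on the training
set: while any pair of retained features has |Pearson r| > 0.9, take the
largest-|r| pair (ties: lexicographically first), remove the member with the
larger mean absolute correlation to all other retained features (ties:
the later-indexed), and recompute. One pair per iteration with recomputation
is the literal reading of the procedure; zero-variance columns are dropped
first with a warning. The filter is a function of the training table only —
test tables are subset to the retained ids.

The classifier is elastic-net logistic regression: minimise mean log-loss
plus `λ(α‖β‖₁ + (1−α)/2 ‖β‖₂²)` on standardised features. The penalised
solver is glmnet; the package owns standardisation (training means/SDs,
binary columns treated like continuous ones), the λ path (100 log-spaced
values spanning 4 decades below the data-driven λ_max, with α floored at
0.001 for the ridge end), outcome-stratified 10-fold cross-validation from
an explicit seed, AUC scoring of out-of-fold predictions, and the selection
rule: maximise mean CV AUC; ties prefer the larger λ, then the smaller α.
The winner is refit on the full training data and stored with its scaling
parameters, so training predictions reproduce exactly from raw inputs.

Variable importance is `100·|b_j| / Σ|b_k|` over standardised coefficients,
intercept excluded — the normalisation that reproduces, to one decimal, the
published importance percentages when applied to the published coefficient
column for the expansion model (45.9% and 15.3%; asserted in the tests).

A practical behaviour worth knowing: at the CV-AUC-optimal (α, λ), lasso
retains uninformative covariates more often in small samples. In the
package's recovery simulation (n = 1000, 5 informative of 50 features) an
appended uninformative binary covariate — the treatment-allocation analogue —
is zeroed in 90% of seeds, but at n = 300 with 10 features only about half
the seeds zero it. Conclusions about "the model discarded covariate X"
should therefore always be read jointly with the sample size.

## Split, thresholds and reported metrics

The cohort is split 70/30 by a stratified draw within
gender × age-quintile × outcome cells, re-drawn (up to 100 attempts) until
age (two-sided rank-sum) and gender (chi-square) differ between sets at
p > .05 — an explicit operationalisation of an age- and gender-matched
semi-random split. The split is a pure function of cohort and seed.

The decision threshold maximises Youden's J (sensitivity + specificity − 1)
on the *training* predictions; candidates are the unique scores and the
midpoints between consecutive unique scores, classification is positive at
score ≥ threshold, and numerically tied maxima resolve to the lowest
threshold. The same threshold is then applied to the test set.

AUC uses the rank (Mann–Whitney) formulation with tie correction; its
confidence interval uses the DeLong variance with a normal approximation
(z = qnorm(0.975), matching the reference implementation to ~1e-6).
Proportion metrics (sensitivity, specificity, PPV, NPV, prevalence) carry
Wald intervals `p ± 1.96·sqrt(p(1−p)/n)` with n the metric's own
denominator, clipped to [0, 1] — with z fixed at 1.96 because that choice
reproduces the published interval bounds exactly at the printed precision.
Metrics with empty denominators are reported as undefined (NA), never as 0.
The threshold-analysis table adds the F-β family
(`F_β = (1+β²)·PPV·sens / (β²·PPV + sens)` for β ∈ {0.5, 1, 2}).

## The synthetic test bed

`generate_phantom()` builds CT-like volumes: a brain ellipsoid
(52×62×45 mm semi-axes) with ventricles, a spherical haematoma (default
radius 15 mm) with a 4 mm oedema shell and optional intraventricular blood,
tissue intensities at standard CT values (brain 30±5, acute blood 65±8,
oedema 18±4, CSF 8±3 HU, air −1000), and acquisition simulated by averaging
z-slabs to the requested slice thickness (1, 3 or 5 mm; labels by majority
vote) with anisotropic spacing stored.

`generate_cohort()` produces either image-level cohorts (phantoms through
the real extraction path) or fast feature-level cohorts: Gaussian features
with a near-duplicate block (pairwise r = 0.95, exercising the correlation
filter), clinical covariates at the study's population scale (age 69±13,
56% male, 1:1 treatment allocation, three thickness batches), injectable
per-batch location/scale effects, and outcomes from a known generative
model — log-normal haematoma growth
`v24 = v0·exp(g)`, `g ~ N(μ + xᵀβ_g, σ_g²)` with a baseline-volume
coefficient, labelled by the clinical expansion rule; and Bernoulli poor
outcome through a logistic model with an age effect. Intercepts are
calibrated by root finding so expected prevalences hit 0.27 (expansion) and
0.50 (poor outcome), the cohort marginals of the study population. All
generators are pure functions of (spec, seed).

What this does and does not show: passing tests demonstrate that every
algorithmic stage does what it claims under known generative conditions —
batch effects of the assumed location–scale form are removed, sparse signal
is recovered, thresholds and intervals are computed correctly. The phantoms
contain no real anatomy, no scanner physics (beam hardening, kernels), no
segmentation error, and the feature-level cohorts bypass imaging entirely;
synthetic discrimination results (e.g. the pipeline AUCs around 0.85–0.91)
characterise the *generator*, not any clinical population, and no clinical
performance figure should be inferred from them.

## Problem sizes used by the tests

The default suite and acceptance script use: one full phantom extraction
(~130³ mm at 1 mm resampling, ~30 s), texture oracle checks on 100 random
6³ ROIs, 200 random 12-feature tables for the correlation-filter oracle,
500 datasets of n ≤ 12 for AUC pair-counting, harmonisation at 200
subjects/batch × 20 features, and model recovery at n = 1000 × 50 features
over 10 seeds (plus 20 seeds for the covariate pass-through check). These
sizes were chosen as the smallest at which each property is comfortably
identifiable; all are set in code, not by environment.

## Known limitations

* The catalogue's family composition (which 56 per-image features) is a
  package convention pinned by tests, not a published list.
* Mask resampling by label-fraction argmax can, in principle, erase a label
  that is everywhere locally minoritary; with the anatomically nested
  labels used here this does not occur.
* ComBat assumes location–scale batch effects and exchangeable features;
  batch effects that change feature correlations are out of model.
* The matched split uses quintile strata and a p > .05 acceptance rule — a
  reasonable operationalisation, but not the only one.
* `pipeline_cli` functionality is exposed as the exported R functions and
  `run_pipeline()` with YAML configs; there is no shell executable, as the
  package's audience drives analyses from R.
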