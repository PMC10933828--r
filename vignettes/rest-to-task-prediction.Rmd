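---
title: "Predicting individual task activation from resting-state modes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting individual task activation from resting-state modes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its model, the choices behind its
defaults, and what its synthetic validation does and does not establish.

## The modelling problem

Individual task contrast maps decompose into a group-typical part and a
subject-unique part: `y = a T + b`, where `T` is the group-average map, `a`
a per-subject amplitude, and `b` a variation map orthogonal to `T`. Rest
mode maps decompose the same way against the group-average mode maps. The
framework learns the mapping between *variation maps only*: training on
residuals keeps the model from spending capacity reproducing the group
average, and makes evaluation interpretable, because the test-retest
reliability of residual maps is a noise ceiling for residual prediction.

With residual signal scale `sigma_b` (per-voxel RMS) and session-noise scale
`sigma_eps`, the reliability of residual maps across two sessions is
approximately `sigma_b^2 / (sigma_b^2 + sigma_eps^2)`, while a *perfect*
shape prediction correlates `sigma_b / sqrt(sigma_b^2 + sigma_eps^2)` with a
measured residual map — higher, because the prediction carries no session
noise. The package's evaluation module measures both, and the synthetic
generator is constructed so these identities hold by design.

## Models

**Baseline.** One multiple regression per training subject of the task
variation map on the k rest variation maps (no intercept — all inputs are
residualised and the generative form has none), averaged across subjects.
Assumes the rest modes span the task variation space with coefficients
shared across subjects. Rank-deficient bases fall back to the minimum-norm
pseudoinverse solution with a warning.

**Sparse.** Each mode's variation maps are concatenated across training
subjects and reduced by cross-subject spatial ICA to `d` components; the
per-mode mixing matrices concatenate into an N×(dk) matrix of subject
coordinates. Targets are either the task matrix's own ICA mixing
(`p` components) or raw voxels (identity mode). One Lasso per target column
with its own penalty allows differential regularisation across targets.
Unseen subjects are projected onto the training sources by least squares.
This model can exploit cross-subject structure the baseline ignores, at the
cost of having to estimate a coordinates-to-coordinates map from N training
samples.

**Ensemble.** Per voxel, ordinary least squares of the training task matrix
on the baseline-fitted and sparse-fitted values at that voxel, with no
intercept, optionally extended with principal-component scores of the k rest
amplitudes. On training data the stacked fit's RSS can never exceed either
constituent's — that is an algebraic property of least squares and is
asserted as an invariant.

**Amplitude.** Task amplitude is regressed on the k rest amplitudes with an
intercept (amplitudes centre near 1, not 0, so a no-intercept fit would be
misspecified). Predicted amplitudes scale the group map when recomposing
full-map predictions.

## The cross-validation driver

`runCrossval()` holds every learned quantity to training folds: group
templates are training-fold means, residualisation of test subjects uses
those training templates, and ICA sources, Lasso penalties, amplitude
models, PCA loadings and ensemble coefficients all derive from training rows
only. A poisoning test (sentinel values in test rows) asserts that no fitted
parameter changes. Rest-side ICA reductions are shared across contrasts
within a fold, since rest features do not depend on the contrast; task-side
reductions and all model fits are per contrast.

Two driver-level choices deserve explanation:

- **Predictions are re-orthogonalised against the training-fold group task
  map.** Training targets are exactly orthogonal to that template by
  construction of no-intercept residualisation, so predictions should live
  in the same subspace; projecting them there removes components the models
  cannot be rewarded for.
- **The stacker configuration is selected by nested cross-validation.** The
  per-voxel ensemble regression has two (plus q) parameters per voxel; with
  hundreds of thousands of training subjects its estimation variance is
  negligible, but at small N it can push the stack below its best
  constituent out of sample. The driver therefore compares, on cross-fitted
  constituent predictions (each inner fold predicted by constituents trained
  without it), the per-voxel stack at each candidate q against the two
  constituent-only configurations, and keeps the one with the best held-out
  mean spatial correlation — the framework's primary performance measure,
  deliberately used instead of SSE, which would favour shrunk predictions
  that correlation ignores. The ensemble fit itself remains plain per-voxel
  OLS.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `folds` | 3 | outer CV folds; every subject is predicted exactly once |
| `d` | 10 | ICA components per rest mode (cohort-scale studies use hundreds to full rank) |
| `p` | `NULL` | task ICA components; `NULL` keeps raw voxels as targets |
| `qGrid` | 0,1,2,3,5 | candidate numbers of amplitude PCs in the ensemble |
| `nestedFolds` | 3 | folds for Lasso-penalty and stacker selection |
| `nLambda`, `lambdaMinRatio` | 30, 1e-3 | per-column penalty grid, log-spaced down from the column's `lambda_max` |
| `seed` | 1 | master seed; identical configuration and seed reproduce every output bit for bit |

## Numerical conventions

- **Voxel order.** Masked vectors use C order over the grid (last axis
  fastest), fixed package-wide and asserted by an ordering test.
- **Lasso objective.** `||y − Xw||² + λ||w||₁`, unscaled (no 1/2N factor);
  under this convention the all-zero solution is optimal exactly at
  `λ ≥ 2·max|Xᵀy|`, which anchors the penalty grid. Coordinate descent
  converges on a 1e-8 maximum coefficient change (1e-5 for CV scoring paths;
  the final refit is tight), with active-set sweeps between full sweeps.
  Predictor columns are scaled to unit Euclidean norm without centering
  (keeping the no-intercept objective exact) and each target column is
  solved at unit norm — both scalings are undone on output. Penalty ties in
  CV resolve to the larger (sparser) penalty.
- **ICA.** Fixed-point iteration with the tanh contrast, deflation scheme,
  at most 500 iterations, tolerance 1e-6, seeded initial vectors. Sources
  are unit-variance over voxels; each source's sign is fixed so its
  largest-magnitude value is positive; components are ordered by explained
  variance. Non-convergence falls back to the PCA basis for that stack with
  a warning — on nearly Gaussian inputs (e.g. smooth random fields) this is
  common and harmless, since the fitted subspace is identical.
- **Residualisation.** No intercept by default, making
  residualise/recompose an exact inverse pair and residuals exactly
  orthogonal to templates; an intercept flag exists. Templates with norm
  below `1e-12·sqrt(V)` are rejected as degenerate.
- **Fisher transform.** Correlations are clipped to `±(1 − 1e-12)` before
  `atanh`; clip events are reported.
- **Identification.** Requires a strict row maximum on the diagonal; ties
  count as failures and are reported separately.
- **Folds.** Subjects are sorted by identifier, shuffled once under the
  seed, and assigned round-robin, so fold membership follows identity, and
  fits are equivariant to row permutations.
- **Degenerate inputs.** Constant Lasso targets get zero coefficients (with
  a message); collinear per-voxel ensemble designs use the minimum-norm
  pseudoinverse (count reported once); constant rows make correlations
  undefined and raise an error naming the subject.

## The synthetic generator

`simulateCohort()` draws, per subject j and mode i, the observed rest map
`a_ji G_i + R_ji` with `a ~ N(1, sigma_a²)` and `R` a Gaussian-filtered
random field orthogonalised against the template and scaled to norm
`sigma_b·sqrt(V)`; the task residual is the coupling-weighted sum of the
rest residuals (orthogonalised against the group task map), the task
amplitude is `1 + Σ w_ci (a_ji − 1) + N(0, sigma_c²)`, and each session adds
a fresh smooth noise field of norm `sigma_eps·sqrt(V)`. All latents are
recorded in `truth`.

Why these defaults:

- `smooth_len = 1.5` voxels matches the spatial smoothing used on
  volumetric biobank-style data (Gaussian sigma 3 mm on a 2 mm grid);
  session noise is smooth at the same length scale because white session
  noise would make denoising unrealistically easy.
- `sigma_b = sigma_eps = 0.01` against unit-norm templates keeps the
  group-average component dominant in each subject's map (residual norm
  roughly 0.45 of the group map at V = 2000), the regime real task contrast
  maps are in; it also puts the residual test-retest reliability at its
  midpoint value 0.5, which is the most informative place to check the
  noise-ceiling algebra.
- The default coupling matrix has unit-norm columns so the task residual's
  expected norm equals `sigma_b·sqrt(V)` and the reliability law holds
  without calibration.
- `sigma_c` (amplitude noise, default 0.05) exists so the amplitude model
  has an estimation problem rather than an identity to recover.

What the generator does *not* emulate: anatomy and real spatial covariance
(residuals are isotropic smooth fields on a virtual grid), hemodynamics and
task design, registration error, rest-session noise in the mode maps, and
subject overlap structure beyond linear coupling. Passing tests therefore
establish that the machinery is correct and behaves as the theory predicts
under its own assumptions — not that any particular accuracy will be reached
on real data.

One consequence of desk scale is worth stating plainly: on a small grid,
smooth fields have few effective degrees of freedom, so cross-subject
structure is weak and the sparse model — whose value on real cohorts comes
from tens of thousands of training subjects — is at a disadvantage relative
to the baseline. The ensemble's nested-CV guard exists precisely so the
final prediction degrades gracefully to the best constituent in that regime.

## Problem sizes

The test suite runs on cohorts of 20–60 subjects and 343–2000 voxels; the
noise-ceiling and recovery checks use N = 150–200, V = 2000, k = 8, d = 10,
p = 24, and the bundled study script (`scripts/acceptance.R`) runs N = 200,
V = 2000, k = 8, two contrasts, two sessions under 3-fold cross-validation.
These sizes were chosen so the whole validation cycle runs in minutes on a
single CPU while keeping every statistical regime (noise ceiling midpoint,
noiseless recovery, low-noise identification) represented.

## Known limitations

- Volumetric NIfTI-1 and delimited matrices only; surface/CIFTI
  grayordinate data must be supplied as matrices.
- The residualising regression has no intercept by default; whether an
  intercept is preferable on real, non-zero-mean data is a user decision
  (`intercept = TRUE` is available throughout).
- Per-column Lasso ignores correlations between target columns by design
  (grouped or multivariate penalties are deliberately out of scope).
- The amplitude model is linear; amplitude prediction quality on real data
  is known to be modest, and recomposed-map accuracy is dominated by the
  group template regardless.
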