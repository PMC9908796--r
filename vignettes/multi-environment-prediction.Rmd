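---
title: "Methods: multi-environment genomic prediction with environmental covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-environment genomic prediction with environmental covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the numerical choices, and
the design decisions behind `enviroGP`, in the order data flows through the
pipeline. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Genotypes: QC, encoding, and the genomic relationship matrix

Genotypes enter in HapMap format (11 metadata columns plus one column per
line); both the diploid two-letter dialect (`AG`) and IUPAC single-letter
heterozygote codes (`R`, `Y`, `S`, `W`, `K`, `M`) are accepted, and `NN`,
`N`, `-` are read as missing.

Markers are filtered on three statistics computed **once** on the input and
applied jointly: missing fraction > 20%, minor allele frequency < 5%
(allele counts, heterozygotes contributing one copy of each allele), or
heterozygous-call fraction > 10% (all strict inequalities). Joint
single-pass application, rather than sequential filtering, makes the
result independent of any filter order and the operation idempotent —
sequential removal could change allele frequencies between steps.

Retained markers are encoded 0 / 0.5 / 1 (major homozygote / heterozygote /
minor homozygote). The panel-major allele defines the 0 state; when both
alleles are equally frequent the alphabetically first allele wins. The
choice is deliberately immaterial: after centering, flipping a marker's
orientation flips the sign of its centered column, which leaves
`G = XXᵀ/p` unchanged — an invariance asserted by the test suite on a hand
example and on simulated panels.

Missing dosages are mean-imputed per marker **before** centering and
standardization (sample standard deviation, `n − 1` denominator, stated
for bit-reproducibility). Mean imputation adds no spurious covariance: an
imputed entry equals the column mean, hence contributes exactly zero to
the centered cross-product. PCA scores come from the SVD of the
standardized matrix.

## 2. Stage-1 trial adjustment

Each trial is analyzed with the base mixed model `y = Xb + Zu + e`
(replicate fixed, genotype random, i.i.d. residuals). The restricted
likelihood is profiled over the single variance ratio
`λ = σ²_e/σ²_g`: a 41-point log-spaced grid on `λ ∈ [10⁻⁶, 10⁶]`
brackets the optimum, which `stats::optimize()` then refines. This is
deliberately a one-dimensional search — the model has exactly one free
ratio — and the tests verify it against a brute-force 2000-point grid
evaluation of the restricted likelihood and against an independent REML
fitter. Broad-sense heritability is `H² = σ²_g/(σ²_g + σ²_e)`; genotype
BLUPs are the adjusted phenotypes passed to stage 2.

Unreplicated trials cannot separate the two variances; their raw values
are passed through (centered on the trial mean) and `H²` is reported as
undefined, which mirrors how such trials are handled in practice.

Spatial AR1⊗AR1 residual models are intentionally out of scope: the
downstream genomic models consume only adjusted phenotypes, and the grid
can equally be loaded directly from a file of adjusted values.

Between-environment Pearson correlations use pairwise-complete lines with
a minimum overlap of 10 shared lines (pairs below it are reported
undefined; the default is a judgement call — correlations on a handful of
lines are noise). Environments are clustered on `d = 1 − r` with average
linkage. The G × E ANOVA is the standard two-way decomposition; with one
observation per cell the interaction is the residual and its F test is
flagged unavailable.

## 3. Weather to environmental covariates

Daily weather (TMIN, TMAX, TM, DPT, RH, PP, APAR, CPAR) is augmented with
three derived variables, computed from self-contained standard formulas so
no external service or package is needed:

* `TR = TMAX − TMIN`;
* `VPD` (kPa): Tetens saturation vapor pressure
  `es(T) = 0.61078·exp(17.27·T/(T + 237.3))`, with
  `VPD = (es(TMIN) + es(TMAX))/2 − es(DPT)`, floored at 0;
* `PET` (mm/d): Hargreaves–Samani,
  `0.0023·(TM + 17.8)·√TR·Ra/λ`, with `Ra` the FAO-56 extraterrestrial
  radiation from latitude and day of year and `λ = 2.45` MJ/kg, floored
  at 0.

The season splits into three phenology windows: vegetative (transplanting
→ earliest flowering), reproductive (earliest → latest flowering,
inclusive on both ends), ripening (after latest flowering → harvest).
Flowering dates are `seeding date + days-to-flowering` because flowering
time is recorded from seeding while the field season starts at
transplanting. A degenerate reproductive window (all lines flowering the
same day) is widened to one day with a warning. Whole-season aggregation
runs transplanting → harvest; where a protocol is ambiguous about whether
the season starts at seeding or transplanting, transplanting was adopted,
because the weather record itself starts there.

Eight covariates × three windows give 24 covariate × phase variables per
environment. Every covariate is aggregated by the **mean** within each
window — including precipitation — because window lengths differ between
environments and the columns are standardized afterwards; a sum would
mostly encode season length. The day-count-weighted mean of the three
phase means equals the whole-season mean exactly (a conservation property
in the tests).

Standardized covariates (`W`, column z-scores across environments;
constant columns dropped with a warning) define the environmental kernel
`Ω = WWᵀ/q`. The division by the number of columns `q` fixes the
"proportional to WWᵀ" constant so the kernel diagonal sits near 1, on the
same scale as `G` — variance components on the two kernels are then
comparable, and `Ω` is invariant to duplicating the covariate set.

## 4. The multi-kernel models and the Gibbs sampler

Cells are laid out environment-major (all lines of environment 1, then
environment 2, ...) so that `K_e = Z_eZ_eᵀ` is block-diagonal of ones and
`K_ge = K_g ∘ K_e` is block-diagonal with one `G` block per environment —
the structure is directly inspectable. The seven models (`G`, `GE`, `GW`,
`GEW`, `GE-GxE`, `GW-GxW`, `GEW-GxE-GxW`) differ only in which of the five
kernels (`g`, `e`, `w`, `ge`, `gw`) they include; positive
semi-definiteness of the Hadamard products is the Schur product theorem
and is also checked numerically on every build.

The sampler fits `y = μ + Σ_k u_k + ε`, `u_k ~ N(0, σ²_k K_k)`,
`ε ~ N(0, σ²_ε I)`:

* Each kernel is eigendecomposed once; eigenvalues below `10⁻⁸` of the
  largest are truncated (the `K_e`, `K_w` and `Ω`-derived kernels are
  low-rank by construction, so truncation is the rule, not the
  exception). Writing `K = BBᵀ` with `B` scaled eigenvectors, the effect
  is `u = Bα` with `α ~ N(0, σ²_k I)`.
* A second, one-time orthogonal rotation diagonalizes `B_obsᵀB_obs`, so
  the full conditional of the rotated coefficient block is independent
  Gaussian and is drawn in a single vectorized operation per kernel per
  iteration — no per-coefficient loops and no per-iteration matrix
  factorizations.
* All variances carry scaled-inverse-χ² priors, degrees of freedom 5,
  with scales set so the prior **modes** split the observed phenotypic
  variance equally between the terms and the residual. This mirrors the
  documented default prior construction of the standard Bayesian
  regression software for these models, so results on real data are
  comparable.
* `μ` has a flat prior; masked cells are predicted as the posterior mean
  of `μ + Σ_k u_k`, with each `u_k` extended to all cells through its
  eigenbasis conditional on the observed ones.
* Default chain settings are 25,000 iterations, 5,000 burn-in, thinning
  10. The test suite runs 3,000/500/5 (and shorter for pure contract
  tests); a chain-length robustness test doubles the iterations and
  checks predictions move by well under the assertion tolerances.
  Effective sample sizes (initial-positive-sequence estimator) are
  reported per variance, with a warning below 50.
* Seeds are explicit inputs and recorded in the fit; every
  cross-validation replicate derives its own seed deterministically from
  the master seed.

With `fix_variances`, the sampler freezes the variance components and
draws only effects; the posterior mean prediction then converges to the
closed-form mixed-model-equation BLUP at those variances, which the tests
assert against an independently coded dense-algebra oracle (±0.02 over 3
seed-averaged chains on a 20-cell instance). `kernel_blup()` provides the
deterministic closed form directly.

### Prediction for untested environments

For a fully unobserved target environment, `K_e` and `K_ge` connect the
target cells to no observed cell, so their contribution to the target's
predictions is *identically zero* — predictions flow only through `K_g`
(always) and through `Ω` (`K_w`, `K_gw`). Consequently `GE` and `GE-GxE`
give identical predictions for an untested environment at equal shared
variance components. This closed-form fact, asserted exactly in the
tests, is the mechanism behind the empirical observation that interaction
models do not outperform main-effect models for untested environments
unless the interaction is covariate-mediated.

## 5. The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions under which the pipeline is validated.

* **Genotypes**: biallelic markers, minor allele frequencies uniform on
  [0.05, 0.5], 2% residual heterozygosity (an inbred elite panel),
  monomorphic realizations redrawn. Markers violating each QC rule can be
  injected, with their identities recorded, to test the filters against
  constructed truth.
* **Environments**: covariate vectors multivariate normal with a common
  between-covariate correlation (0.3 by default — weather variables are
  correlated); environment main effects are a linear function of the
  standardized covariates plus configurable noise (`ec_noise`, default
  0.2), so covariate distance predicts environment-effect similarity —
  the assumption the covariate-selected CV design exploits. With
  `emit_weather = TRUE` the generator instead writes a daily weather
  series per environment (piecewise constant within phenology phases)
  and derives the covariates by running the package's own aggregation,
  so the weather pipeline is exercised end to end and the round trip is
  exact by construction.
* **Allocation**: per-environment line counts uniform on a configurable
  range (default: 35% of the panel up to all of it), always including a
  core set observed everywhere (default 30% of lines), emulating sparse
  testing with a common check panel.
* **Phenotypes**: `y_ij = μ + g_i + e_j + w_j + ge_ij + gw_ij + ε_ij`
  with `g` from additive marker effects on the centered standardized
  genotypes, `w` an EC-driven environment-level effect, `ge` an i.i.d.
  line × environment deviation — deliberately matching the `K_ge` model
  class and therefore *non-transferable* to new environments — and `gw` a
  sum of marker-driven genetic slopes on the covariate columns,
  *transferable* through `Ω`. That separation is exactly what makes the
  untested-environment findings testable. Every component is rescaled to
  hit its target variance exactly over the observed cells, so the
  realized components stored in the truth object equal the targets and
  recovery checks are against a known quantity.
* **Default variance targets** (`g = 1, e = 2, w = 0.5, ge = gw = 0.25,
  ε = 0.5`): environment main effects dominating the genetic signal, with
  modest interactions — the regime multi-environment trials of this kind
  typically show. Default sizes (150 lines, 500 markers, 10 environments,
  8 covariates) keep a full test run within minutes on one CPU.

What passing tests on synthetic data show — and what they do not: the
generator draws independent marker genotypes (no linkage disequilibrium,
no pedigree structure), Gaussian covariates, and interactions that are
exactly of the two modeled classes. Success here demonstrates that the
estimation and validation machinery is correct and that the qualitative
mechanisms (transferability of `gw`, non-transferability of `ge`) behave
as derived; it does not demonstrate that real weather covariates capture
real G × E, which is an empirical question for real data.

## 6. Cross-validation designs

`CV-RAN` samples 4 training environments uniformly per target (50
replicates by default; the tests and the acceptance script use 6 at
reduced size), `CV-SEL` takes the 4 nearest environments by Euclidean
distance on whole-season standardized covariates (one run per target, as
there is nothing to replicate), `CV-LOEO` trains on all remaining
environments. Leave-one-line-out masks one fully observed line
everywhere; its predictive ability is computed per line (across
environments) and per environment (across the assembled left-out
predictions of **all** swept lines, not per fit). No-leakage is enforced
by construction — the target's cells are masked before the kernels are
built — and audited in the tests.

Model comparison: Fisher z-transform (`|r|` clamped at `1 − 10⁻⁶` with a
warning, since perfect correlations otherwise map to infinity), one-way
ANOVA with model as factor, Tukey HSD at 5%, compact letter display by the
standard insert-and-absorb algorithm, means back-transformed to the
correlation scale by `tanh`. Ties in nearest-environment selection break
lexicographically; all leaf orders and seeds are deterministic.

## 7. Identifiability of the environment-level variance split

A limitation worth stating precisely. `K_e = Z_eZ_eᵀ` and
`K_w = Z_eΩZ_eᵀ` act on the same `m`-dimensional environment space (`m` =
number of environments). With `m` around 10–15, the likelihood carries
only `m` environment-level observations to split between `σ²_e` and
`σ²_w`, and `Ω = WWᵀ/q` approaches the identity as `q` grows — the two
kernels then become nearly collinear. The posterior for the *sum* of the
environment-level variance is well behaved, but the split wanders:
per-dataset estimates of `σ²_e` and `σ²_w` individually can be off by a
factor of two in either direction even at 200 lines × 10 environments,
while `σ²_g` and `σ²_ε` (informed by hundreds of effective dimensions)
recover within a few percent. The heavy right tail of the
scaled-inverse-χ²(5) prior additionally pulls weakly identified variances
upward. The test suite therefore asserts exact recovery where it is
statistically possible (all components under the matching `GE` model;
`σ²_g` and `σ²_ε` under the full `GEW` model) and the package reports
effective sample sizes so users see when the split is poorly determined.
Genomic heritability `h²_g = σ²_g/(σ²_g + σ²_ε)` is built from the two
well-identified components, which is one reason it is the summary of
choice.

## 8. Other known limitations

* No spatial field-trend modeling, no augmented-design check adjustment,
  and no multi-trait models in stage 1.
* Cluster trees carry no bootstrap support values; topology only.
* The rule by which a handful of lines may have been dropped from a real
  panel upstream of the genotype file is not re-derived; line sets are
  taken as given by the input.
* Weather is consumed from local files; no retrieval service is bundled.
* The CLI configuration file is YAML; flags override file values.
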