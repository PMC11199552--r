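---
title: "Spatial mixed linear effect models for family cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial mixed linear effect models for family cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilevc)
```

## The problem

Family-based variance-component studies partition the variance of a disease
outcome into genetic and environmental parts by regressing phenotypic
similarity among relatives on their expected genetic relatedness. When
unmeasured environmental risk factors are shared by families living in the
same community — air pollution, climate, sociodemographic context — the
extra phenotypic correlation among family members living together is
falsely attributed to genetics, inflating heritability estimates. smilevc
implements a spatial mixed linear effect model that adds a
spatially correlated, location-level random effect to the classical
nuclear-family variance-component model, so that community-level
environment is estimated jointly with heritability rather than absorbed by
it. A two-stage instrumental-variable extension then uses long-term wind
patterns as instruments to estimate causal effects of location-level
exposures (PM2.5, NO2) on binary disease outcomes.

## The model

For a cohort of nuclear families indexed by location, the observed 0/1
disease status vector is modeled linearly as

$$Y = X\pi + u_g + Z_s u_s + Z_{par} u_{par} + Z_{child} u_{child} + \epsilon$$

with four independent random effects:

* **Genetic** `u_g ~ N(0, sigma_g^2 blkdiag(G_f))`, where `G_f` is the
  per-family expected relatedness matrix: diagonal 1, father–mother 0,
  parent–child and sibling pairs 0.5. Families are genetically unrelated to
  each other. The same rules extend to single-parent families and
  arbitrary numbers of children.
* **Parent-shared environment** `Z_par u_par`: the two parents of a family
  load on one shared iid effect, each child on its own, so the component
  contributes variance `sigma_par^2` to everyone but covariance only
  between the two parents.
* **Child-shared environment** `Z_child u_child`: mirror image — all
  children of a family share one effect, parents have their own.
* **Community-level spatial** `Z_s u_s`: one effect per location (county or
  metropolitan area in the motivating application), with covariance on the
  location adjacency graph following one of three structures: independent
  (IND, `sigma_s^2 I`), conditional autoregressive (CAR), or simultaneous
  autoregressive (SAR). With `W` the 0/1 border adjacency, `W_+` its
  row-normalized form, and `M = diag(1/n_i)` the inverse neighbour counts,

$$\Sigma_{CAR} = \sigma_s^2\left(M^{-1/2}(I - \rho M^{-1/2} W_+ M^{1/2})M^{-1/2}\right)^{-1},
\qquad
\Sigma_{SAR} = \sigma_s^2\left((I-\rho S) M^{-1} (I-\rho S)\right)^{-1},$$

  where `S = M^{-1/2} W_+ M^{1/2}` is symmetric with entries
  `W_ij / sqrt(n_i n_j)`. Algebraically the CAR precision simplifies to the
  classical sparse form `(diag(n_i) - rho W)/sigma_s^2`, positive definite
  for `|rho| < 1`, with nonzeros only on the diagonal and graph edges —
  this is what makes the likelihood sparse. At `rho = 0` both CAR and SAR
  reduce to `sigma_s^2 M`.

Because the CAR/SAR covariance has unequal diagonal entries, the raw
`sigma_s^2` is not comparable across graphs. The package reports the
**Gower-standardized** spatial variance — the averaged variance of the
spatial effects across individuals after centering,
`tr[(I - 11'/N) Z_s \Sigma_s Z_s'] / (N-1)` — as the phenotypic variance
contributed by community-level environment. (Written with the centering
matrix acting on the individual-level covariance; the two trivial checks —
a single location gives 0, one individual per location with
`Sigma = sigma^2 I` gives `sigma^2` — pin the convention down.)

**Isolated locations.** Row normalization is undefined for locations with
no neighbours; they are retained as independent components with variance
`sigma_s^2` and zero covariance with all other locations. This preserves
positive definiteness without discarding data.

## Estimation

Binary outcomes are fitted by plain maximum likelihood of the Gaussian
linear model on the observed 0/1 scale — the standard computationally
efficient choice for large cohorts — and converted to the liability scale
afterwards. The likelihood never forms the dense `N x N` covariance:
the family-level terms form small per-family blocks (families with the
same role composition share one block, inverted once), and the spatial
term enters by the Woodbury identity through the sparse CAR/SAR precision.
Since each family sits in a single location, the inner matrix is the
spatial precision plus a diagonal, factored with a sparse Cholesky — one
likelihood evaluation is `O(N)` plus a sparse `L x L` factorization.

* Variances are optimized on the log scale, the autocorrelation as
  `atanh(rho)` with `|rho|` capped at 0.99 (the row-normalized operator
  guarantees positive definiteness on `(-1, 1)`); `rho` is optimized
  jointly with the variances.
* Fixed effects are profiled out by generalized least squares at every
  evaluation, so the optimizer works in at most six dimensions. This
  replaces joint quasi-Newton iteration over `(log sigma^2, atanh rho, pi)`
  with an exactly equivalent but lower-dimensional and more robust search;
  the maximizer is identical because the Gaussian likelihood is quadratic
  in `pi`.
* Three deterministic starts are scored (equal split across components;
  residual-dominant; spatial- or genetic-dominant), the best is polished by
  `nlminb`, and the remaining starts serve as fallbacks on failure. Nested
  sub-models are warm-started from the full-model estimates in
  `smile_models()`.
* Convergence requires the optimizer's relative-tolerance criterion
  (`1e-9`) or a central-difference gradient infinity-norm below `1e-5`
  (bounds-active coordinates excluded); fits failing both are flagged, not
  errored.
* Standard errors come from the inverse observed information (numerical
  Hessian on the transformed scale, delta method back); estimates on the
  zero boundary are flagged and their one-sided standard errors reported
  as missing.
* ML (not REML) is used so BIC comparisons across sub-models are coherent;
  `BIC = -2 logLik + p log(N)` with `N` the number of individuals and `p`
  counting variance parameters, `rho`, and fixed effects. The canonical
  comparison set is GPC+S, GP+S, GC+S, GPC, PC+S, PC, G+S, S, with ties
  broken toward fewer parameters.

Location-level best linear unbiased predictors of the spatial effect are
`u_hat = \Sigma_s Z_s' V^{-1}(Y - X\hat\pi)`; `blup_correlations()`
regresses them on external community-level risk factors, screening traits
at 2% prevalence and 2% spatial variance by default.

## Liability-scale conversion

The generating model for a binary trait is a liability threshold: disease
occurs when a latent standard-normal liability exceeds `qnorm(1-K)` at
prevalence `K`. Observed-scale components must be mapped back to that
scale. The classical first-order factor `K(1-K)/z^2` (with `z` the normal
density at the threshold) is exact only when pair covariances are small;
in nuclear families the relevant liability correlations (0.2–0.35 for
siblings at realistic parameter values) inflate the observed-scale
covariance well beyond the linear approximation at low prevalence, so the
multiplier substantially overstates components in a round-trip simulation
at `K = 0.05`.

The default conversion is therefore **component-wise tetrachoric**: the
fitted observed-scale fractions imply a covariance for each pair class —
father–mother (`par + s`), parent–child (`g/2 + s`), sibling–sibling
(`g/2 + child + s`), unrelated same-location (`s`) — and each class
covariance is inverted exactly through the bivariate-normal upper-orthant
probability (computed by univariate quadrature). The liability components
are then recomposed from the class system, which is triangular in
`(s, g, child, par)`. This inversion is exact for any normally distributed
shared effect; its remaining approximations are the use of a single
Gower-standardized value for the heterogeneous spatial variances and the
assumption that the fitted observed-scale model reproduces the class
covariances. The first-order multiplier remains available as
`method = "multiplier"`. No ascertainment correction is applied: the
motivating data are population claims records, not case-enriched samples.

## The synthetic-cohort generator

`sim_scenario()` fixes the study conditions; `sim_study()` executes them.
What the generator emulates, and the defaults:

* **Cohort geometry.** Quad families (two parents, two children) by
  default, optionally sizes 3–6 with user probabilities. Families are
  allocated to lattice locations with a heavy-tailed log-normal
  distribution calibrated to a median of ~15 families per location and an
  IQR of roughly (5, 50), matching the demographic shape of the motivating
  claims cohort; when no lattice dimensions are given, per-location counts
  are drawn directly from that distribution.
* **Liability.** Components default to `g = 0.3`, `par = 0.1`,
  `child = 0.1`, `s = 0.1` (CAR, `rho = 0.6`), residual taking the
  complement to 1 — values representative of complex-trait analyses.
  The scenario's `s` is the Gower-standardized (per-individual average)
  spatial variance; the raw CAR/SAR parameter is rescaled per cohort so
  that the realized components genuinely sum to 1. Prevalence defaults to
  5%; binary status is the liability thresholded at `qnorm(1-K)`.
* **Exposures and instruments.** Wind speed and direction vary smoothly
  over the graph (autoregressive fields, `field_rho = 0.6`); each
  pollutant is 50% instrument-driven signal (through the circular encoding
  `sin θ, cos θ, speed, speed·sin θ, speed·cos θ`), 25% a spatially smooth
  confounder shared between pollutants, 25% noise. The confounder also
  shifts the liability (`confounder_effect = 0.15` per SD, its variance
  deducted from the residual), creating endogeneity of the raw exposure
  while the instruments remain exogenous by construction. These weights
  put the first-stage F statistic well into the strong-instrument range
  (tens at ~200 locations), the regime in which two-stage inference is
  calibrated and which matches the motivating application, where wind
  strongly predicts pollution over thousands of locations. Substantially
  smoother fields or weaker instruments at desk scale collapse the
  effective number of independent locations and produce the classical
  weak-instrument size distortion in *any* two-stage method.
* **Causal effects.** Effects are specified as a relative risk `RR` at +1
  SD of exposure and converted to a liability shift
  `qnorm(1-K) - qnorm(1 - RR*K)`; odds ratios are reported from the
  observed-scale effect at the trait's prevalence.
* **Robustness perturbations.** `inject_relationship_errors()` relabels a
  fraction of children as biological while severing their true genetic
  sharing (step/adopted children coded as biological);
  `add_measurement_noise()` perturbs pollutant levels and wind speed
  proportionally to their SD and wind direction by `noise_sd * 60` degrees,
  wrapped.

What the generator does **not** emulate: real county adjacency (a lattice
stands in; any adjacency file can substitute), enrollment dynamics and
billing-code error processes, time-varying exposures, and the empirical
correlation structure of real sociodemographic covariates. Passing tests
therefore demonstrate correctness of the estimators under the stated
generating process, not robustness to every feature of claims data.

## Desk-scale study sizes

The validation experiments (in `tests/testthat/test-acceptance.R`) use
problem sizes chosen as the package's own desk-scale study conditions:

* Variance-component recovery: 2,000 quad families on a 10×10 lattice, 50
  replicates, full GPC+S/CAR truth; each converted component is checked
  against its generating value within two Monte-Carlo standard errors.
  The same replicates fitted as GPC (no S) demonstrate the upward
  heritability bias, which grows when the generating spatial variance is
  doubled.
* Two-stage causal studies: 300 quad families on a 15×15 lattice at 5%
  prevalence. The geography — cohort placement, pollution, wind and
  confounder maps — is drawn once per scenario and held fixed, as when
  families are resampled from a real landscape; replicates redraw the
  liabilities. The causal liability carries the genetic and
  family-environment components plus the fixed location-level confounder
  and no free spatial effect, mirroring the design of the causal
  simulations the model is meant for (a per-replicate random spatial field
  would be location-level noise that the second stage deliberately does
  not model, and would distort size for *any* two-stage method at desk
  scale). 400 null replicates for type-I error; 200 replicates at RR = 1.2
  for power and mean-squared error against the IND-FE comparator
  (ordinary least squares on the unrelated parents).
* BIC selection: the eight-model comparison at 5,000 and 25,000 families
  (lattices 18×18 and 40×40, keeping the families-per-location shape),
  four replicates each; the selection fraction for the generating model
  must increase with cohort size. Quantitative selection rates comparable
  to a full-scale analysis (tens of percent at hundreds of thousands of
  families) require cluster-scale computation and are out of desk scope.
* Liability round trip: genetics-only design (`h2 = 0.4`), 1,500 families,
  15 replicates at each prevalence in {0.01, 0.05, 0.2}, isolating the
  observed-to-liability conversion from multi-component estimation.

## Numerical choices and degenerate inputs

* Variances are bounded in log space at `[-25, 10]`; a variance below
  `1e-7` is reported as a boundary estimate.
* An all-zero family-level variance set is rejected as non-positive
  definite; prevalence exactly 0 or 1 is a domain error; rank-deficient
  fixed-effect designs are rejected with the collinear columns named.
* Duplicate adjacency edges and reversed duplicates collapse idempotently;
  self-loops are dropped with a warning.
* The dense spatial covariance path (used for the Gower factor, BLUPs and
  oracle checks) is intended for moderate location counts; the likelihood
  itself only ever factors the sparse precision.
* Ties in BIC (to machine precision) resolve to the model with fewer
  parameters.

## Known limitations

* The observed-scale linear model is an approximation for binary data;
  its variance components are interpretable through the liability
  conversion, which itself treats the spatial variance as homogeneous
  across locations at the conversion step.
* `rho` is a single scalar per trait and is weakly identified at small
  location counts; heritability is insensitive to this (fits under IND,
  CAR and SAR agree closely), but `rho` itself should not be
  over-interpreted at desk scale.
* Second-stage standard errors do not propagate first-stage uncertainty
  (standard two-stage practice; flagged in the output), and the second
  stage omits the spatial random effect exactly as the two-stage model is
  specified — the predicted exposure is itself location-level.
* Multi-generation pedigrees, inbreeding, genotype-based relatedness, and
  generalized (logistic/probit) mixed models are out of scope.
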