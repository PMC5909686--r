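---
title: "Transferring negative-binomial abundance models between reef systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring negative-binomial abundance models between reef systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reeftransfer)
```

## The problem

Underwater visual censuses count fish along fixed-area transects — a handful
per site, a few sites per reef — and are expensive enough that most reef
systems are under-surveyed. A model of abundance fitted where data are rich
would be valuable wherever data are poor, *if* it transfers. This package
implements that question as a pipeline: fit a fixed candidate set of count
models in a reference system under several data scenarios, validate them
in-system, apply them to a target system's predictor grid, and score the
transferred predictions against the target's own model and observations.

## The count model and its assumptions

Site-level pooled counts are modelled as NB2 negative binomial with log link:

$$N_{ij} \sim \mathrm{NB}(\mu_{ij}, \theta), \qquad
\operatorname{Var}(N) = \mu + \mu^2/\theta, \qquad
\log \mu_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta + \alpha_i, \qquad
\alpha_i \sim \mathcal{N}(0, \sigma_\alpha^2),$$

with $i$ indexing reefs and $j$ sites. The assumptions, in decreasing order
of importance:

* **Overdispersion is real and NB2-shaped.** A Poisson test model is fitted
  first and its Pearson dispersion statistic (`dispersion_statistic()`,
  sum of squared Pearson residuals over residual df) must sit well above 1.
* **Within-reef correlation is exchangeable.** Several sites share a reef
  (and often a single predictor-grid cell), so they are pseudo-replicates at
  the predictors' resolution; one scalar random intercept per reef absorbs
  this. No residual spatial correlation structure beyond the reef level is
  modelled; the Moran's I correlogram is the diagnostic for whether that was
  enough.
* **Effects are log-linear with at most quadratic curvature**, and only for
  the four predictors given second-order polynomials (`coast`, `barrier`,
  `depth`, `sst_av`).

Estimation is by maximum likelihood: `MASS::glm.nb()` for plain GLMs and
`glmmTMB` (nbinom2 family, Laplace approximation for the scalar random
intercept) for the mixed fits — one scalar random effect per group is exactly
the regime where the Laplace approximation is adequate, and adaptive
quadrature would buy little at 3–20 sites per reef. When the $\theta$ MLE
diverges (under- or equidispersed subsamples, which arise routinely inside
cross-validation folds), the fit falls back to the NB's Poisson limit with
$\theta$ pinned at $10^7$; the parameter count still charges one slot for
$\theta$ so that AICc comparisons stay fair.

The parameter count used by AICc is $k = p + 1 (+1)$: fixed effects, the
dispersion, and the variance component when present. AICc weights, marginal
and conditional R² (with the lognormal distribution-variance approximation
$\ln(1 + 1/\lambda + 1/\theta)$; a trigamma variant is available via
`r2_nakagawa(..., dist_variance = "trigamma")`), percent deviance explained
for GLM fits, and weight-averaged standardized effect sizes summarize the
candidate set.

## The candidate set

`model_set()` returns the twelve models. They partition the predictors by
theme (boundaries, physical, sediment, nutrients, oxygen/salinity,
productivity, temperature, light) precisely so that collinear predictors
never co-occur: the three sediment fractions get one model each, and the
system-specific editions drop nitrate from the full model and carbonate from
the sediment model where they are collinear in the target system. Model 12 is
the intercept-only null; its Akaike weight (`null_support()`) is the guard
against over-interpreting rankings among uniformly poor models. Model 13
(quadratic rugosity) exists only for systems with transect-level rugosity
measurements.

Raw polynomials on mean-centred predictors are used rather than orthogonal
polynomials: coefficients stay interpretable in the original units and
centering removes most of the linear–quadratic collinearity. The centering
constants and per-predictor calibration ranges are first-class outputs of
`build_predictor_set()` because transfer depends on them (below).

## Scenarios and transect downscaling

`scenario_specs()` fixes seven datasets: A = 2003–2007, B/C = 2007–2013,
D/E = 2007, F/G = 2013, with C, E and F downscaled. Multi-year windows
average the per-site pooled counts across years and integerize half-up in one
final step — the count likelihood needs integers, and rounding once avoids
compounding rounding error.

Downscaling converts counts from long transects to the target system's
shorter ones (50 m → 25 m, ratio 2). Within each site, the average increase
in cumulative count per added transect is estimated by randomizing the order
in which transects are added (`estimate_transect_increment()`); each
transect's count is then reduced by that average increase divided by the
length ratio, floored at zero (`downscale_counts()`). Because the cumulative
sum telescopes, the mean step increment of *every* ordering equals the site
mean count, so the randomized estimator equals the analytic shortcut exactly
— the function computes both and the tests assert their identity. The
procedure uses only the site's own transects: no information is shared across
sites or reefs.

Two conventions the survey literature leaves open are settled here and
exposed as switches: transects are pooled by **sum** within sites
(`pool_transects_to_site(statistic = )`), and multi-year scenarios average
**after** pooling.

## Transfer: centering, clipping, and the four metrics

A fitted model's coefficients only mean anything in the coordinates it was
fitted in, so the target system's predictors are centred with the *reference*
system's constants (`build_predictor_set(..., centers = )`), never re-centred
locally. Any grid cell where a predictor used by the model falls outside the
reference calibration range is clipped — no prediction, mandatorily
(`predict_grid_clipped()`): extrapolating a quadratic log-linear model
outside its fitted range produces confident nonsense.

The transferred grid is compared with the target's own reference predictions
by four metrics (`transfer_report()`): direct validation R²/p at surveyed
sites; mean ± SD absolute grid-cell difference with the percentage form
normalized by the **reference** prediction (the comparison is "how far from
what the local model says", not a symmetric distance); percent of cells
within a 15% relative tolerance (boundary inclusive, zero-reference cells
excluded and counted); and high-versus-low pattern agreement after min-max
rescaling to the reference range. High/low classes are relative to each
grid's own **median** (ties count low); a midrange variant is available since
no convention is universal. By default, summary tables flag as `included`
only transfers whose reference fit validated significantly in-system with
null-model weight ≤ 0.1 — a transferred model that failed at home is not
evidence about transferability.

## Validation choices

* **Cross-validation** (`kfold_cv()`): site-level 10-fold, stratified by reef
  (round-robin within reef after a seeded shuffle) so every training set
  retains every reef where sizes allow and the variance component stays
  estimable. Held-out sites are predicted in population mode. The percentage
  error divides each fold's mean absolute error by that fold's mean observed
  count; absolute and percentage forms are both reported because the
  denominator convention is not standardized.
* **Direct validation** (`direct_validation()`): OLS of observed on
  predicted, reporting 100·R² and the slope's two-sided p. Constant
  predictions make the regression undefined; that is returned as an `NA` row
  with a note so ranking tables can carry it.
* **Correlograms** (`moran_correlogram()`): binary distance-band weights,
  Moran's I with Cliff–Ord normality moments per band. Deviance residuals by
  default (Pearson by switch). Default band width is the first decile of the
  pairwise-distance distribution — with no principled neighbourhood scale
  available, this guarantees a well-populated first band at any survey
  extent. Distances are planar equidistant-cylindrical kilometres anchored at
  the domain's mean latitude; at sub-degree extents the projection error is
  negligible and only relative distances matter.

## What the synthetic generator does and does not emulate

`generate_system()` reproduces the features the pipeline is sensitive to:
reef-clustered sites (Gaussian scatter around uniform reef centroids),
smooth environmental gradients on a regular grid (random linear gradients
plus low-frequency sinusoids, rescaled into configured ranges), partially
non-overlapping covariate ranges between systems (`make_target_system()`),
NB2 counts with a log-link linear predictor on midpoint-centred covariates,
reef random intercepts, family-specific dispersion, and an equal-probability
multinomial split of site counts across transects. Defaults mirror the study
design this pipeline was built around: 46 reefs × 3 sites × five 50 m
transects surveyed over 2003–2013 (odd years after 2005) in the reference
system, 27 reefs × 3 sites × three 25 m transects in 2013 in the target;
the generative intercept (log 300 per site), effect sizes (nitrate,
temperature with concave quadratic, distance to coast), $\sigma_\alpha$ = 0.5
and $\theta$ = 5 were chosen once as ecologically plausible magnitudes —
strong reef clustering and substantial overdispersion — and are not tuned.

Deliberately *not* emulated: real species composition, bathymetry,
satellite-product noise and gaps, within-site spatial structure (the
equal-multinomial split is a stand-in; the survey design gives no
within-site structure to copy), temporal trends (years are independent NB
draws around a static mean), and observation error beyond NB dispersion.
Passing tests on these data therefore demonstrate the *machinery* —
estimation, selection, validation, transfer arithmetic, clipping — not that
real fish abundance is predictable; the headline scientific result this
pipeline supports is precisely that in-system fit does not guarantee
transfer.

## Numerical conventions and degenerate inputs

* Half-up rounding (`round_half_up()`) at the single final integerization
  step of scenario construction; downscaled counts clamp at zero.
* Nearest-node assignment breaks distance ties (to floating-point slack)
  toward the lowest node id, independent of row order.
* Convergence failures in fitting are errors naming the model; a
  random-intercept variance at the zero boundary is a valid fit, not a
  failure. Rank-deficient designs and constant predictor columns are
  rejected by name.
* All randomness flows through explicit integer seeds (`withr::with_seed`);
  no function touches the global RNG state. Reference runs embed a
  configuration hash in their outputs (`write_run()`).
* Degenerate transfer comparisons (all cells clipped, constant grids,
  zero-reference cells) are routed into the report as `NA`s with notes
  rather than raised, so a sweep over scenarios and families never dies on
  one bad combination.

## Problem sizes

The bundled test-suite fixtures use 8–12 reefs × 3 sites with a coarse
0.25° grid; the full-scale run in `scripts/acceptance.R` uses the complete
study design above (138 reference sites, 81 target sites, ~10,000 grid
nodes, 12 models × 7 scenarios × 2 responses plus 10-fold CV per top model).
These sizes were chosen so a complete run stays comfortably within a few
minutes on a single core while keeping every estimator in its asymptotically
sensible regime.

## Known limitations

* No zero-inflation, crossed/nested random effects, or spatially correlated
  residual models; if the correlogram shows structure the reef intercept
  did not absorb, this package will tell you but not fix it.
* Effect sizes are Akaike-weight-averaged |standardized coefficient|
  magnitudes with absence-as-exclusion; other model-averaging conventions
  (absence-as-zero shrinkage) would give smaller values for rarely selected
  predictors.
* The choice to centre target predictors with reference constants is a
  modelling commitment, not a mathematical necessity; its alternative
  (local re-centering) answers a different question and is intentionally
  not offered.
* Grid predictions are population-mode: conditional modes exist only for
  reefs seen during fitting and a prediction grid has none.
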