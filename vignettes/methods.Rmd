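---
title: "Estimating protected-area impacts on forest loss under mixed land tenure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protected-area impacts on forest loss under mixed land tenure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

`forestatt` estimates the causal effect of formal protection on the
probability that a 30 m forest pixel was cleared over a multi-year study
window, in a landscape where land is held under different tenure regimes
(communal *ejidos*, private property, and parceled ejidos — former ejidos
divided into individual holdings). Protected areas are not placed at random:
they sit preferentially on remote, steep, high-biomass land that would have
faced little clearing pressure anyway. A naive comparison of clearing rates
inside and outside protected areas therefore confounds the effect of
protection with the effect of location.

The package's estimand is the average treatment effect on the treated (ATT):
the mean difference between a treated pixel's observed outcome and the
outcome it would have had without treatment. For a binary clearing outcome
this is a risk difference in `[-1, 1]`; negative values mean the treatment
reduced the probability of forest loss.

Four comparison designs are built in (`run_comparison()`):

* **A** — protected vs fully unprotected pixels, any tenure;
* **B** — protected vs fully unprotected pixels within one tenure regime,
  with controls never drawn from the treated pixel's own property;
* **C** — pixels under one tenure regime vs another, within a protection
  stratum (so the tenure contrast is not confounded by protection itself);
* **spillover** — pixels in the *unprotected* parts of partially protected
  properties vs pixels in fully unprotected properties of the same tenure.
  A positive spillover ATT indicates leakage: clearing displaced from the
  protected to the unprotected portion of the same property.

## Matching estimator

Each comparison proceeds as: propensity estimation, trimming to common
support, nearest-neighbour matching with replacement, bias adjustment, and
matched-sample variance estimation.

**Propensity and trimming.** A logistic regression of the treatment
indicator on all covariates yields fitted probabilities and the linearized
score (log-odds). Treated units outside the `[min, max]` range of control
scores, or (default caliper, 0.25 SD of the score) with no control score
nearby, are dropped from the treated set; controls are never dropped. The
caliper width is a package choice — only "trimming based on a propensity
score" is prescribed by the design this pipeline implements — and is
configurable.

**Metrics.** Two candidate metrics: Mahalanobis distance over the
covariates, and the same distance over the covariates augmented with the
linearized propensity score as one extra coordinate ("propensity-score
augmented"). The pooled covariance is computed over treated plus control
pool within the comparison, regularized by adding `1e-8 x trace` to the
diagonal. Matching is always within forest biome; ties in distance break
towards the lowest control id so reruns are identical. The metric actually
used is chosen by post-match balance: the candidate with the smallest
maximum absolute normalized difference wins (ties: smallest mean, then
declaration order).

**Balance.** The normalized difference
`(mean_t - mean_c) / sqrt((var_t + var_c)/2)` uses unbiased variances;
matched control moments are weighted by control reuse counts, matching the
with-replacement semantics. `|nd| > 0.25` flags imbalance. If every
covariate stays flagged after matching the comparison is reported `NA`
("very unbalanced covariate distributions") rather than estimated.

**Bias adjustment.** Matching on many covariates leaves residual covariate
gaps inside pairs. A linear model of the outcome on the matching covariates,
fit among the matched controls, provides `mu(x)`; each pair effect is
corrected by `mu(x_treated) - mu(x_control)`. This is the standard
regression-adjustment form; the precise published formulas behind the
analysis this package generalizes are not reproduced anywhere, so the
standard form is adopted and stated here.

**Variance.** Plain mode:
`se^2 = sum((tt_i - ATT)^2) / (n(n-1)) + sum_j K_j(K_j - 1) sigma2_c / n^2`,
where `K_j` are control reuse counts. With no reuse this is exactly
`sd(tt)/sqrt(n)`. For bias-adjusted effects, `sigma2_c` is the residual
variance of the adjustment regression (the marginal control variance would
overstate the reuse penalty once covariate effects are removed).
Heteroscedasticity-corrected mode estimates per-unit conditional variances
from each unit's nearest same-group neighbour,
`sigma2_i = (y_i - y_nn(i))^2 / 2`, and combines them as
`se^2 = [sum_T sigma2_i + sum_C K_j^2 sigma2_j] / n^2`. Both are standard
matched-sample forms; the heteroscedasticity mode omits the
effect-heterogeneity term of the full asymptotic variance, which is
conservative in the designs tested here. Confidence intervals are normal at
90/95/99%.

## Effect heterogeneity along the biomass gradient

Pair effects `tt_i` are modelled as
`tt_i = alpha + x_i beta + f(z_i) + eps_i`, with `z` the woody biomass of
the treated pixel (tC/ha, a proxy for old-growth vs secondary forest) and
`x` the linear controls. Estimation is by the double-residual (Robinson)
method: `tt` and each column of `x` are smoothed on `z` with a Gaussian
local-linear smoother; the residualized outcome is regressed on the
residualized covariates for `beta`; `f` is the local-linear smooth of
`tt - x beta` on `z`, centred to mean zero over the sample (the
identification constraint), with `alpha` absorbing the mean. The default
bandwidth is Silverman's rule of thumb on `z`; no bandwidth is prescribed by
the analysis design, so the default is explicit and overridable. Pairs are
unweighted by default, with a reuse-weighted option.

Pointwise 95% bands come from a wild-t bootstrap: residuals are multiplied
by two-point Mammen weights (mean 0, variance 1), the model is refit per
resample (the fixed-design smoother matrices are precomputed once, so each
refit is a few matrix-vector products), and the *symmetric* studentized
quantile of `|f* - f_hat|/se*` is applied to the plug-in kernel standard
error of the original fit. The symmetric variant is used because, at the
modest resample counts this analysis runs at, equal-tailed percentile-t
quantiles are attenuated toward zero and under-cover; the symmetric
quantile restores near-nominal pointwise coverage (about 94% at n = 1,000
with 199 resamples in the validation study). The analysis default of
`B = 50` resamples is retained as a compatibility default; tests use larger
`B`. `significance_profile()` reads off the maximal biomass
intervals where the bands exclude zero — the reading rule for the effect
curves. Bands are pointwise, not simultaneous, by design.

## Extrapolation to avoided deforestation and carbon

`avoided_area()` converts an ATT into hectares over the whole study area as
`|ATT| x n_mc x 0.09 ha x 100`, where `n_mc` is the matched-control count,
0.09 ha is the 30 m pixel area and 100 inverts the 1% sampling fraction;
the result is signed positive for avoided loss. This operative form exactly
reproduces every published worked example this package was validated
against; a literal variant that additionally multiplies by the
matched-control deforestation rate is provided (`mode = "literal"`) because
the prose description of the recipe mentions that factor, but it reproduces
none of the published values — the discrepancy is documented rather than
resolved. Carbon is area times mean matched-control biomass.
`net_effect()` sums signed areas over entries significant at the 10% level.

## The synthetic landscape generator

`generate_landscape()` emulates the statistical structure the estimators
assume, with a stored counterfactual giving ground truth:

* **Covariates** are Gaussian random fields: white noise convolved (FFT, on
  the torus) with a Gaussian kernel of the stated correlation range, scaled
  to each covariate's mean and SD and truncated to physical bounds. Default
  magnitudes are loosely calibrated to a seasonally dry tropical forest
  frontier (biomass ~50 +- 22 tC/ha, clearing over the window ~15% outside
  protection); they are not claimed to match any specific published summary
  table.
* **Properties** are a nearest-seed (Voronoi) tessellation; tenure is
  assigned to whole properties with area shares of roughly 62/21/17%
  ejido/private/parceled, mimicking a cadastre dominated by communal land.
* **Protection** is assigned at property granularity: properties are scored
  by remoteness and biomass plus noise and protected from the top until the
  target coverage (default 8%) is met; about half the selected properties
  are only partially protected (a contiguous chunk around the property
  seed), so spillover pools exist. The placement noise SD (default 1.5)
  controls endogeneity; it is set so that placement is clearly confounded
  yet common support survives — with near-deterministic placement no
  observational estimator (and no real-world study design) could proceed.
* **Outcomes**: clearing probability is logistic in standardized covariates;
  under protection the true effect `tau(z)` is added *on the probability
  scale*, so for constant `tau` the ground-truth ATT equals `tau` exactly.
  The counterfactual `y0_loss` uses the same uniform draws with protection
  removed (common random numbers), making `y - y0` a low-variance oracle.
  The baseline coefficients are deliberately moderate (intercept -1.7,
  standardized slopes |b| <= 0.15) so that baseline probabilities stay away
  from the `[0, 1]` boundary: an additive risk difference is only
  well-defined where it does not clip, and the generator is kept inside
  that regime by construction.
* **Leakage**: within partially protected properties, each
  protection-suppressed clearing is displaced, with the configured
  probability, onto a random still-standing unprotected pixel of the same
  property. With full leakage, total clearings in those properties match
  the no-protection counterfactual up to displacement slots running out.

What the generator does *not* emulate: real geography (roads, rivers,
towns), yearly loss dynamics, within-property tenure heterogeneity, and
measurement error in the satellite outcome. Passing recovery tests on these
landscapes shows the estimators are correct under the assumed structure —
selection on observables with smooth confounders — not that the assumption
holds in any particular real dataset.

## Sampling frame

`build_frame()` applies the forest definition (tree cover strictly above
10%, 25% as a sensitivity cutoff), draws a uniform random sample of
forested pixels, and enforces a minimum spacing by greedy thinning in
seeded random order, interpreting "within 30 m" as the 8-neighbourhood of
the 30 m grid (Chebyshev distance <= 1 pixel). Sampling precedes thinning;
the original analysis does not state its order, and sample-then-thin is the
cheaper choice. Exclusion rules (urban, water, mangrove, post-2000
protection, comunidades, named properties) run in declared order with a
reconciling log; pixels in unprotected parts of protected properties are
not discarded but routed to the spillover pool, where the spillover design
needs them as treated units.

## Numerical choices and degenerate inputs

* Distance ties in matching break to the lowest control id; sampling and
  thinning are seeded — whole-pipeline runs are byte-reproducible from the
  manifest.
* Near-singular pooled covariances are ridge-regularized
  (`1e-8 x trace`); exactly collinear bias-adjustment columns are dropped
  with a warning.
* Perfect separation in the propensity model (non-convergence or vanishing
  deviance) is an error surfaced to the caller; numerically extreme fitted
  probabilities alone are tolerated because trimming handles them.
* A constant smoothing covariate, an empty arm, a treated unit with no
  admissible control, or a single pair each produce a specific error or an
  `NA` estimate with a reason string, never a silent fallback.
* Degenerate local-linear designs (no spread of `z` inside the kernel
  window) fall back to the local-constant estimate at that point.

## Problem sizes used in validation

The recovery studies in the test suite and acceptance script use a 300x300
landscape (90,000 pixels) with a 12% sampling fraction over 100 seeds for
constant-effect recovery, a 250x250 landscape with 50% leakage for the
spillover contrast, n = 3,000 pairs for PLM parameter recovery, and 80
replicates x 199 bootstrap resamples at n = 1,000 for pointwise band
coverage.
These sizes give Monte-Carlo standard errors small enough for 2-SE
assertions while keeping the full validation run in the minutes range on a
single core.

## Known limitations

* The matching search is exact but quadratic in pool size per stratum; it
  is sized for sampled frames (10^3–10^5 rows), not for full rasters.
* The heteroscedasticity variance omits the effect-heterogeneity term; the
  plain mode's reuse inflation assumes homoscedastic control outcomes.
* Wild-t bands are pointwise; reading a significance profile across many
  grid points carries the usual multiplicity caveat.
* The extrapolation's unit conventions follow the published worked
  examples; the documented prose-vs-arithmetic discrepancy in the recipe
  (and an unresolved carbon unit ambiguity in the published figures) is
  inherited, not repaired.
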