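# forestatt

Matching-based impact evaluation of protected areas on pixel-level forest
loss under mixed land-tenure regimes.

## The problem

Protected areas, communal tenure (*ejidos*), private property, and parceled
ejidos (former ejidos divided into individual holdings) coexist on tropical
forest frontiers, and none of them is assigned at random: protection tends
to sit on remote, high-biomass land that faced little clearing pressure to
begin with. Comparing raw deforestation rates across tenure or protection
strata therefore says little about causal effect. `forestatt` implements the
quasi-experimental pipeline used to untangle this: for each 30 m forest
pixel under treatment, find an observationally similar untreated pixel and
contrast their binary clearing outcomes.

The package is for analysts evaluating conservation interventions on
pixel-level land-cover data, and for methodologists who want a tested,
ground-truthed implementation of the estimator stack.

## What it computes

The estimand is the average treatment effect on the treated,

    ATT = E[ Y(1) - Y(0) | D = 1 ],

a risk difference on the binary clearing outcome; negative values mean the
treatment reduced the probability of forest loss. The stack:

* **Sampling frame** — forest definition (cover > 10%, strict), random
  sampling with 8-neighbourhood spacing, ordered exclusion rules with a
  reconciling log (`build_frame()`).
* **Matching** — nearest-neighbour with replacement, within forest biome,
  under a Mahalanobis metric or a propensity-augmented variant; logit
  propensity scores with common-support trimming and a configurable
  caliper; the metric is selected by post-match covariate balance
  (smallest maximum |normalized difference|, flag at 0.25); regression
  bias adjustment and matched-sample variances with reuse correction
  (`run_comparison()`).
* **Designs** — average protection effects, within-tenure effects,
  tenure-vs-tenure contrasts within protection strata, and spillover
  (leakage) contrasts using the unprotected parts of protected properties.
* **Heterogeneity** — a partially linear model of pair effects,
  `tt_i = alpha + x_i beta + f(z_i) + eps_i`, with `f` estimated by
  Robinson's double-residual method over the biomass gradient `z` and
  pointwise 95% wild-t bootstrap bands (`fit_plm()`,
  `wild_bootstrap_bands()`, `significance_profile()`).
* **Impact accounting** — avoided deforestation
  `|ATT| x n_mc x 0.09 ha x 100`, avoided carbon, and net direct-plus-
  spillover balances over significant entries (`avoided_area()`,
  `net_effect()`).
* **Ground truth** — a synthetic-landscape generator with spatially
  autocorrelated covariates, a property tessellation, endogenous protection
  placement, within-property leakage, and stored counterfactual outcomes
  (`generate_landscape()`, `oracle_att()`), used to validate every
  estimator in the test suite.

## Worked example

```r
library(forestatt)

cfg <- landscape_config(
  grid_width = 300, grid_height = 300, n_properties = 300,
  effect_curve_params = list(type = "constant", value = -0.05),
  leakage_rate = 0, seed = 42
)
land <- generate_landscape(cfg)
land
#> <synthetic_landscape> 300x300 pixels, 300 properties, seed 42
#>   protected: 7277 pixels (8.1%), clearing rate 0.154

oracle_att(land, subset = biome == "dry")   # ground truth for this draw
#> [1] -0.05674487

frame <- build_frame(land$pixels, fraction = 0.12, seed = 43)
est <- run_comparison(frame$sample, question = "A", biome = "dry",
                      spillover_pool = frame$spillover_pool)
est
#> <att_estimate> question A [dry]
#>   raw ATT -0.087; bias-adjusted ATT -0.083 (se 0.047, 95% CI [-0.176; 0.01])
#>   n_t=195, n_mc=91, n_cp=2893; mahalanobis_trimmed, plain variance
```

The generator planted a constant protection effect of −0.05 on the clearing
probability; the realized ground truth for this draw's dry-forest treated
pixels is −0.057, and the bias-adjusted matching estimate recovers
−0.083 ± 0.047 — within one standard error. `n_t`, `n_mc`, `n_cp` count
treated pixels on support, distinct matched controls, and the control pool.
A single landscape is a noisy experiment by design; averaged over 100
generator seeds the estimator is unbiased to within Monte-Carlo precision
(see the acceptance script below). `tidy()` and `glance()` return the
estimate as tibbles, `autoplot()` draws effect curves and landscapes, and
`run_pipeline()` drives the whole flow from a YAML config to a directory of
CSV artifacts plus a manifest.

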