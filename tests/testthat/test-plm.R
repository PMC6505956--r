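plm_sim <- function(n, seed, f = function(z) -2e-4 * z^2, beta1 = 0.5,
                    noise = 0.3) {
  set.seed(seed)
  tibble::tibble(
    x1 = rnorm(n),
    x2 = rnorm(n),
    biomass_tc_ha = runif(n, 0, 150),
    tt = beta1 * x1 + f(biomass_tc_ha) + rnorm(n, 0, noise)
  )
}

test_that("pair effects carry treated covariates and reuse weights", {
  inst <- random_match_instance(8, 20, seed = 2)
  m <- suppressWarnings(match_nearest_neighbor(
    inst[inst$arm == 1, ], inst[inst$arm == 0, ], c("x1", "x2"),
    same_biome = FALSE
  ))
  pe <- pair_effects(m)
  expect_equal(nrow(pe), nrow(m$pairs))
  expect_equal(pe$tt, m$pairs$tt)
  expect_equal(pe$x1, m$treated$x1)
  expect_equal(sum(pe$K[!duplicated(pe$control_id)]), nrow(m$pairs))
  # hand values: tt = y_t - y_c per pair
  lk_t <- m$treated$y_loss
  lk_c <- m$matched_controls$y_loss
  expect_equal(pe$tt, lk_t - lk_c)
})

test_that("double-residual PLM recovers linear and smooth components", {
  d <- plm_sim(3000, seed = 42)
  fit <- fit_plm(d, c("x1", "x2"))
  b1 <- fit$beta[fit$beta$term == "x1", ]
  expect_lt(abs(b1$estimate - 0.5), 2 * b1$std_error)
  true_f <- -2e-4 * fit$grid^2
  true_f <- true_f - mean(-2e-4 * d$biomass_tc_ha^2)
  expect_gt(stats::cor(fit$f_hat, true_f), 0.9)
  # identification: f_hat has mean zero over the sample
  expect_lt(abs(mean(fit$f_sample)), 1e-8)
})

test_that("PLM agrees with an independent GAM cross-check", {
  skip_if_not_installed("mgcv")
  d <- plm_sim(1500, seed = 7)
  fit <- fit_plm(d, c("x1", "x2"))
  gam <- mgcv::gam(tt ~ x1 + x2 + s(biomass_tc_ha), data = d)
  expect_lt(abs(fit$beta$estimate[1] - stats::coef(gam)[["x1"]]), 0.05)
  gam_f <- stats::predict(gam, type = "terms")[, "s(biomass_tc_ha)"]
  expect_gt(stats::cor(fit$f_sample, gam_f), 0.95)
})

test_that("with no smooth signal the PLM collapses to least squares", {
  d <- plm_sim(2000, seed = 9, f = function(z) 0 * z)
  fit <- fit_plm(d, c("x1", "x2"))
  ols <- stats::lm(tt ~ x1 + x2, data = d)
  b1 <- fit$beta[fit$beta$term == "x1", ]
  expect_lt(abs(b1$estimate - stats::coef(ols)[["x1"]]), 2 * b1$std_error)
})

test_that("infinite bandwidth reduces beta to the partial-linear-in-z fit", {
  d <- plm_sim(800, seed = 13)
  fit <- fit_plm(d, c("x1", "x2"), bandwidth = 1e6)
  ols <- stats::lm(tt ~ x1 + x2 + biomass_tc_ha, data = d)
  expect_equal(fit$beta$estimate[1], stats::coef(ols)[["x1"]], tolerance = 1e-3)
  expect_equal(fit$beta$estimate[2], stats::coef(ols)[["x2"]], tolerance = 1e-3)
})

test_that("degenerate smoothing covariate is rejected", {
  d <- plm_sim(100, seed = 3)
  d$biomass_tc_ha <- 50
  expect_error(fit_plm(d, c("x1", "x2")), "plain linear model")
})

test_that("wild bootstrap bands are deterministic and honest about zero noise", {
  d <- plm_sim(400, seed = 5)
  fit <- fit_plm(d, c("x1", "x2"))
  b1 <- wild_bootstrap_bands(fit, B = 40, seed = 77)
  b2 <- wild_bootstrap_bands(fit, B = 40, seed = 77)
  expect_identical(b1$bands, b2$bands)
  b3 <- wild_bootstrap_bands(fit, B = 40, seed = 78)
  expect_false(identical(b1$bands, b3$bands))
  # bands contain the point estimate
  expect_true(all(b1$bands$lower <= b1$bands$f_hat + 1e-12))
  expect_true(all(b1$bands$upper >= b1$bands$f_hat - 1e-12))

  # noiseless data: residuals vanish and the bands have zero width
  d0 <- plm_sim(300, seed = 6, beta1 = 0, noise = 0, f = function(z) 0 * z)
  d0$tt <- 0
  fit0 <- fit_plm(d0, c("x1", "x2"))
  expect_lt(max(abs(fit0$residuals)), 1e-10)
  bands0 <- wild_bootstrap_bands(fit0, B = 20, seed = 1)$bands
  expect_lt(max(bands0$upper - bands0$lower), 1e-8)

  expect_warning(wild_bootstrap_bands(fit, B = 5, seed = 1), "unreliable")
})

test_that("significance profile reads the bands correctly", {
  # bands everywhere containing zero: empty profile
  f1 <- structure(list(bands = tibble::tibble(
    z = 1:10, f_hat = 0, lower = -1, upper = 1
  )), class = "plm_fit")
  expect_equal(nrow(significance_profile(f1)), 0)

  # negative at mid-z only: a single negative interval
  z <- seq(0, 100, length.out = 21)
  lower <- rep(-0.2, 21)
  upper <- ifelse(z >= 30 & z <= 60, -0.05, 0.1)
  f2 <- structure(list(bands = tibble::tibble(
    z = z, f_hat = (lower + upper) / 2, lower = lower, upper = upper
  )), class = "plm_fit")
  prof <- significance_profile(f2)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$sign, "negative")
  expect_gte(prof$z_lo, 25)
  expect_lte(prof$z_hi, 65)

  expect_error(significance_profile(fit_plm(plm_sim(200, 1), c("x1", "x2"))),
               "wild_bootstrap_bands")
})

test_that("an effect vanishing at high biomass is localized by the profile", {
  # direct simulation of matched-pair effects whose mean is negative only
  # below mid-biomass, mirroring the dry-forest reading
  d <- plm_sim(2500, seed = 23, beta1 = 0.2,
               f = function(z) -0.12 * exp(-((z - 30) / 25)^2),
               noise = 0.25)
  fit <- fit_plm(d, c("x1", "x2"))
  fit <- wild_bootstrap_bands(fit, B = 60, seed = 4)
  prof <- significance_profile(fit)
  neg <- prof[prof$sign == "negative", ]
  expect_gt(nrow(neg), 0)
  # the significant region excludes the top of the biomass range
  expect_lt(max(neg$z_hi), 0.8 * max(fit$grid))
})

test_that("autoplot draws the effect curve", {
  d <- plm_sim(300, seed = 2)
  fit <- wild_bootstrap_bands(fit_plm(d, c("x1", "x2")), B = 20, seed = 1)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
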