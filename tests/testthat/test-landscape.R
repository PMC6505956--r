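test_that("identical config and seed give bit-identical landscapes", {
  a <- tiny_landscape(seed = 5)
  b <- tiny_landscape(seed = 5)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$properties, b$properties)
  c <- tiny_landscape(seed = 6)
  expect_false(identical(a$pixels$y_loss, c$pixels$y_loss))
})

test_that("landscape satisfies its structural invariants", {
  land <- tiny_landscape(seed = 2)
  px <- land$pixels
  expect_true(all(px$y_loss %in% 0:1))
  expect_true(all(px$y0_loss %in% 0:1))
  # every pixel maps to exactly one property, and the property table's
  # protected fraction reconciles with the pixel raster
  expect_true(all(px$property_id %in% land$properties$property_id))
  derived <- tapply(px$protected, px$property_id, mean)
  tab <- land$properties[land$properties$n_pixels > 0, ]
  expect_equal(as.numeric(derived[as.character(tab$property_id)]),
               tab$protected_fraction, tolerance = 1e-12)
  # tenure is constant within property
  expect_true(all(tapply(px$tenure, px$property_id,
                         function(v) length(unique(v))) == 1))
})

test_that("config validation rejects malformed inputs", {
  expect_error(landscape_config(grid_width = 4), "at least 8")
  expect_error(landscape_config(tenure_shares = c(ejido = 0.5, private = 0.2)),
               "sum to 1")
  expect_error(landscape_config(pa_coverage = 1.2), "pa_coverage")
  expect_error(landscape_config(leakage_rate = -0.1), "leakage_rate")
})

test_that("null effect gives oracle ATT indistinguishable from zero", {
  land <- generate_landscape(landscape_config(
    grid_width = 200, grid_height = 200, n_properties = 150,
    effect_curve_params = list(type = "none"), leakage_rate = 0, seed = 31
  ))
  px <- land$pixels[land$pixels$protected == 1, ]
  diffs <- px$y_loss - px$y0_loss
  mc_se <- stats::sd(diffs) / sqrt(nrow(px))
  expect_true(is.finite(mc_se))
  expect_lt(abs(oracle_att(land)), max(2 * mc_se, 1e-12))
})

test_that("constant effect is recovered by the oracle over replicate draws", {
  oracles <- vapply(1:25, function(s) {
    oracle_att(generate_landscape(landscape_config(
      grid_width = 200, grid_height = 200, n_properties = 150,
      effect_curve_params = list(type = "constant", value = -0.05),
      leakage_rate = 0, seed = s
    )))
  }, numeric(1))
  se <- stats::sd(oracles) / sqrt(length(oracles))
  expect_lt(abs(mean(oracles) - (-0.05)), 2 * se)
})

test_that("oracle ATT reproduces hand-enumerated values", {
  px <- tibble::tibble(
    pixel_id = 1:6, protected = c(1, 1, 1, 1, 0, 0),
    y_loss  = c(0L, 1L, 0L, 1L, 1L, 0L),
    y0_loss = c(1L, 1L, 0L, 0L, 1L, 0L)
  )
  # treated diffs: -1, 0, 0, +1 -> mean 0
  expect_equal(oracle_att(px), 0)
  px$y0_loss[1] <- 0L  # diffs: 0, 0, 0, 1 -> 0.25
  expect_equal(oracle_att(px), 0.25)
  expect_equal(oracle_att(dplyr::mutate(px, y0_loss = y_loss)), 0)
  expect_error(oracle_att(px, subset = pixel_id > 90), "no treated")
})

test_that("effect increasing in biomass orders subgroup oracles", {
  land <- generate_landscape(landscape_config(
    grid_width = 200, grid_height = 200, n_properties = 150,
    effect_curve_params = list(type = "linear", intercept = -0.10, slope = 0.001),
    leakage_rate = 0, seed = 12
  ))
  zmed <- stats::median(land$pixels$biomass_tc_ha[land$pixels$protected == 1])
  hi <- oracle_att(land, subset = biomass_tc_ha > zmed)
  lo <- oracle_att(land, subset = biomass_tc_ha <= zmed)
  expect_gt(hi, lo)
})

test_that("full leakage conserves clearings within partially protected properties", {
  land <- generate_landscape(landscape_config(
    grid_width = 150, grid_height = 150, n_properties = 80,
    effect_curve_params = list(type = "constant", value = -0.08),
    leakage_rate = 1, pa_coverage = 0.15, partial_frac = 0.8, seed = 21
  ))
  partial <- land$properties$property_id[
    land$properties$protected_fraction > 0 & land$properties$protected_fraction < 1
  ]
  px <- land$pixels[land$pixels$property_id %in% partial, ]
  observed <- sum(px$y_loss)
  counterfactual <- sum(px$y0_loss)
  # equal up to displacement slots exhausted within a property
  expect_lt(abs(observed - counterfactual),
            max(3, 0.05 * counterfactual))
})

test_that("effect curve helper evaluates each family", {
  expect_equal(effect_curve(c(1, 5), list(type = "none")), c(0, 0))
  expect_equal(effect_curve(c(1, 5), list(type = "constant", value = -0.04)),
               c(-0.04, -0.04))
  expect_equal(effect_curve(2, list(type = "linear", intercept = 1, slope = 2)), 5)
  bump <- list(type = "bump", tau_max = -0.08, center = 40, width = 30)
  expect_equal(effect_curve(40, bump), -0.08)
  expect_lt(abs(effect_curve(150, bump)), 0.08 * exp(-9) + 1e-12)
})

test_that("autoplot renders the landscape panels", {
  p <- ggplot2::autoplot(tiny_landscape(seed = 3, nx = 40, ny = 40))
  expect_s3_class(p, "ggplot")
})
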