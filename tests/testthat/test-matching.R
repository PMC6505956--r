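test_that("mahalanobis distance matches hand values", {
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(mahalanobis_distance(c(0, 0), c(3, 4), diag(2)), 5)
  S <- matrix(c(4, 0, 0, 1), 2)
  expect_equal(mahalanobis_distance(c(2, 0), c(0, 0), solve(S)), 1)
  expect_error(pooled_cov_inv(matrix(c(1, 1, 2, 2), 2), regularize = 0),
               "singular")
})

test_that("nearest-neighbour matching equals the brute-force oracle", {
  for (seed in 1:12) {
    inst <- random_match_instance(n_t = 25, n_c = 80, seed = seed)
    treated <- inst[inst$arm == 1, ]
    controls <- inst[inst$arm == 0, ]
    for (metric in c("mahalanobis_trimmed", "ps_augmented")) {
      for (diff_prop in c(TRUE, FALSE)) {
        m <- suppressWarnings(match_nearest_neighbor(
          treated, controls, c("x1", "x2", "x3"), metric = metric,
          same_biome = TRUE, different_property = diff_prop
        ))
        bf <- brute_force_pairs(treated, controls, c("x1", "x2", "x3"),
                                metric = metric, same_biome = TRUE,
                                different_property = diff_prop)
        got <- dplyr::arrange(m$pairs, treated_id)
        want <- dplyr::arrange(bf, treated_id)
        expect_equal(got$treated_id, want$treated_id)
        expect_equal(got$control_id, want$control_id)
        expect_equal(got$distance, want$distance, tolerance = 1e-8)
      }
    }
  }
})

test_that("an identical control is matched at distance zero, subject to constraints", {
  inst <- random_match_instance(5, 20, seed = 3)
  treated <- inst[inst$arm == 1, ][1, ]
  controls <- inst[inst$arm == 0, ]
  clone <- treated
  clone$pixel_id <- 999L
  clone$property_id <- treated$property_id + 1L
  controls2 <- dplyr::bind_rows(controls, clone)
  m <- match_nearest_neighbor(treated, controls2, c("x1", "x2", "x3"),
                              same_biome = FALSE)
  expect_equal(m$pairs$control_id, 999L)
  expect_equal(m$pairs$distance, 0)

  # same-property distance-0 control is inadmissible: next nearest chosen
  clone$property_id <- treated$property_id
  controls3 <- dplyr::bind_rows(controls, clone)
  m2 <- match_nearest_neighbor(treated, controls3, c("x1", "x2", "x3"),
                               same_biome = FALSE, different_property = TRUE)
  expect_false(m2$pairs$control_id == 999L)
  expect_gt(m2$pairs$distance, 0)
})

test_that("raw ATT is the mean pair effect", {
  inst <- random_match_instance(3, 10, seed = 4)
  treated <- inst[inst$arm == 1, ]
  controls <- inst[inst$arm == 0, ]
  m <- match_nearest_neighbor(treated, controls, c("x1", "x2"), same_biome = FALSE)
  expect_equal(raw_att(m), mean(m$pairs$tt))
  # hand pairs: (1-0), (0-1), (0-0) -> mean 0
  m0 <- m
  m0$pairs <- m0$pairs[1:3, ]
  m0$pairs$tt <- c(1, -1, 0)
  expect_equal(raw_att(m0), 0)
  m0$pairs$tt <- c(0, 0, 0)
  expect_equal(raw_att(m0), 0)
})

test_that("bias adjustment is inert under exact matching", {
  inst <- random_match_instance(20, 40, seed = 6)
  treated <- inst[inst$arm == 1, ]
  controls <- treated
  controls$pixel_id <- controls$pixel_id + 500L
  controls$property_id <- controls$property_id + 90L
  m <- match_nearest_neighbor(treated, controls, c("x1", "x2", "x3"),
                              same_biome = FALSE)
  expect_equal(m$pairs$distance, rep(0, 20), tolerance = 1e-10)
  expect_equal(bias_adjust(m), raw_att(m), tolerance = 1e-10)
})

test_that("bias adjustment shrinks confounding bias in most replicates", {
  # linear outcome-covariate confounding with deliberately coarse matching:
  # the treated are shifted in x, the outcome depends linearly on x, and the
  # true effect is zero
  wins <- vapply(1:200, function(s) {
    set.seed(s + 4000)
    n_t <- 80; n_c <- 30  # sparse control pool forces coarse matches
    x_t <- rnorm(n_t, 2, 1)
    x_c <- rnorm(n_c, 0, 1)
    d <- tibble::tibble(
      pixel_id = 1:(n_t + n_c),
      property_id = rep(1:2, c(n_t, n_c)),
      x1 = c(x_t, x_c),
      y_loss = 0.3 * c(x_t, x_c) + rnorm(n_t + n_c, 0, 0.03),
      arm = rep(c(1L, 0L), c(n_t, n_c))
    )
    m <- match_nearest_neighbor(d[d$arm == 1, ], d[d$arm == 0, ], "x1",
                                same_biome = FALSE)
    abs(bias_adjust(m)) < abs(raw_att(m))
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("adjustment can move an insignificant raw estimate to a significant one", {
  # residual covariate gaps after coarse matching mask a real negative effect
  set.seed(88)
  n_t <- 120; n_c <- 30
  x_t <- rnorm(n_t, 1.4, 1)
  x_c <- rnorm(n_c, 0, 1.3)
  tau <- -0.09
  d <- tibble::tibble(
    pixel_id = 1:(n_t + n_c),
    property_id = rep(1:2, c(n_t, n_c)),
    x1 = c(x_t, x_c),
    y_loss = 0.15 * c(x_t, x_c) + tau * rep(c(1, 0), c(n_t, n_c)) +
      rnorm(n_t + n_c, 0, 0.06),
    arm = rep(c(1L, 0L), c(n_t, n_c))
  )
  m <- match_nearest_neighbor(d[d$arm == 1, ], d[d$arm == 0, ], "x1",
                              same_biome = FALSE)
  raw <- raw_att(m)
  tt_adj <- forestatt:::bias_adjust_tt(m)
  ci_raw <- att_variance(m, "plain")$ci
  ci_adj <- att_variance(m, "plain", tt = as.numeric(tt_adj),
                         sigma2_c = attr(tt_adj, "sigma2_resid"))$ci
  # adjusted estimate is closer to the truth than the raw one
  expect_lt(abs(mean(tt_adj) - tau), abs(raw - tau))
  # raw interval spans zero, the adjusted interval excludes it
  raw95 <- ci_raw[ci_raw$level == 0.95, ]
  adj95 <- ci_adj[ci_adj$level == 0.95, ]
  expect_gt(raw95$upper, 0)
  expect_lt(adj95$upper, 0)
})

test_that("matched-sample variance has the classical closed form without reuse", {
  inst <- random_match_instance(15, 60, seed = 9)
  treated <- inst[inst$arm == 1, ]
  controls <- treated
  controls$pixel_id <- controls$pixel_id + 500L
  controls$property_id <- controls$property_id + 90L
  controls$y_loss <- rbinom(15, 1, 0.5)
  m <- match_nearest_neighbor(treated, controls, c("x1", "x2", "x3"),
                              same_biome = FALSE)
  expect_true(all(m$weights$K == 1))
  v <- att_variance(m, "plain")
  expect_equal(v$se, stats::sd(m$pairs$tt) / sqrt(nrow(m$pairs)),
               tolerance = 1e-12)
  # constant pair effects: zero SE and degenerate intervals
  m2 <- m
  m2$pairs$tt <- rep(0, nrow(m2$pairs))
  m2$matched_controls$y_loss <- m2$treated$y_loss
  v2 <- att_variance(m2, "plain")
  expect_equal(v2$se, 0)
  expect_true(all(v2$ci$lower == 0 & v2$ci$upper == 0))
  # nested confidence intervals, both variance modes
  for (mode in c("plain", "hc")) {
    ci <- att_variance(m, mode)$ci
    expect_true(all(diff(ci$upper) >= 0) && all(diff(ci$lower) <= 0))
  }
  # single pair: undefined
  m3 <- m
  m3$pairs <- m3$pairs[1, ]
  expect_error(att_variance(m3, "plain", tt = m3$pairs$tt[1]), "single pair")
})

test_that("plain-variance confidence intervals attain nominal null coverage", {
  covered <- vapply(1:300, function(s) {
    set.seed(s + 9000)
    n_t <- 150; n_c <- 300
    d <- tibble::tibble(
      pixel_id = 1:(n_t + n_c),
      property_id = rep(1:3, length.out = n_t + n_c),
      x1 = rnorm(n_t + n_c), x2 = rnorm(n_t + n_c),
      y_loss = rbinom(n_t + n_c, 1, 0.15),
      arm = rep(c(1L, 0L), c(n_t, n_c))
    )
    m <- suppressWarnings(match_nearest_neighbor(
      d[d$arm == 1, ], d[d$arm == 0, ], c("x1", "x2"), same_biome = FALSE
    ))
    ci <- att_variance(m, "plain")$ci
    ci95 <- ci[ci$level == 0.95, ]
    ci95$lower <= 0 && ci95$upper >= 0
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("estimator selection minimizes the worst normalized difference", {
  inst <- random_match_instance(40, 120, seed = 10)
  treated <- inst[inst$arm == 1, ]
  controls <- inst[inst$arm == 0, ]
  # identical candidates: the first declared wins
  sel <- select_estimator(treated, controls, c("x1", "x2"),
                          metrics = c("mahalanobis_trimmed", "mahalanobis_trimmed"),
                          same_biome = FALSE)
  expect_equal(sel$metric, "mahalanobis_trimmed")
  expect_true(is.na(sel$reason))

  # a confounder visible only through the propensity score: make lps carry a
  # covariate that is excluded from the plain Mahalanobis metric
  set.seed(11)
  n_t <- 80; n_c <- 400
  u_t <- rnorm(n_t, 1.5, 0.6); u_c <- rnorm(n_c, 0, 1)
  d <- tibble::tibble(
    pixel_id = 1:(n_t + n_c),
    property_id = rep(1:2, c(n_t, n_c)),
    x1 = rnorm(n_t + n_c),
    hidden = c(u_t, u_c),
    lps = c(u_t, u_c),
    y_loss = rbinom(n_t + n_c, 1, 0.2),
    arm = rep(c(1L, 0L), c(n_t, n_c))
  )
  sel2 <- select_estimator(d[d$arm == 1, ], d[d$arm == 0, ],
                           covariates = c("x1", "hidden"),
                           metrics = c("mahalanobis_trimmed", "ps_augmented"),
                           same_biome = FALSE)
  expect_true(sel2$candidates$feasible[2])
  expect_lte(sel2$candidates$max_abs_nd[2], sel2$candidates$max_abs_nd[1])

  # infeasible: empty control pool in every stratum
  sel3 <- select_estimator(treated, controls[0, ], c("x1", "x2"),
                           same_biome = FALSE)
  expect_true(is.na(sel3$metric))
  expect_match(sel3$reason, "NA")
})

test_that("bookkeeping counts distinct controls and respects the pool", {
  inst <- random_match_instance(50, 70, seed = 12)
  m <- suppressWarnings(match_nearest_neighbor(
    inst[inst$arm == 1, ], inst[inst$arm == 0, ], c("x1", "x2", "x3")
  ))
  expect_equal(m$n_mc, dplyr::n_distinct(m$pairs$control_id))
  expect_lte(m$n_mc, m$n_cp)
  expect_equal(m$n_cp, 70)
  expect_equal(sum(m$weights$K), nrow(m$pairs))
  expect_equal(m$n_t + m$n_dropped, 50)
})
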