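# shared fixtures and independent oracles

# small landscape used across tests (kept cheap; regenerated per call so
# tests cannot leak state through it)
tiny_landscape <- function(seed = 11, nx = 80, ny = 80, ...) {
  generate_landscape(landscape_config(
    grid_width = nx, grid_height = ny, n_properties = 40, seed = seed, ...
  ))
}

# landscape with strongly endogenous protection placement: large pre-matching
# covariate imbalance between protected and unprotected arms
confounded_fixture <- function() {
  generate_landscape(landscape_config(
    grid_width = 120, grid_height = 120, n_properties = 40, seed = 19,
    placement_noise_sd = 0.5, pa_coverage = 0.12
  ))
}

# hand-rollable pixel table for frame tests
toy_pixel_table <- function(n = 20) {
  tibble::tibble(
    pixel_id = seq_len(n),
    row = rep(seq_len(ceiling(n / 5)), each = 5, length.out = n) * 3,
    col = rep(1:5, length.out = n) * 3,
    biome = rep(c("dry", "moist"), length.out = n),
    tenure = rep(c("ejido", "private", "parceled", "ejido"), length.out = n),
    property_id = rep(1:4, each = 5, length.out = n),
    protection_class = c(rep("unprotected_part_of_protected_property", 4),
                         rep("fully_unprotected", n - 4)),
    forest_cover_pct = 80,
    y_loss = rep(c(0L, 1L), length.out = n)
  )
}

# independent brute-force nearest-neighbour oracle: direct double loop over
# the exported scalar distance, no whitening shortcut
brute_force_pairs <- function(treated, controls, covariates,
                              metric = "mahalanobis_trimmed",
                              same_biome = TRUE, different_property = TRUE) {
  match_cols <- if (metric == "ps_augmented") c(covariates, "lps") else covariates
  out <- list()
  strata <- if (same_biome) unique(treated$biome) else "all"
  for (s in strata) {
    tr <- if (same_biome) treated[treated$biome == s, ] else treated
    co <- if (same_biome) controls[controls$biome == s, ] else controls
    if (nrow(tr) == 0 || nrow(co) == 0) next
    co <- co[order(co$pixel_id), ]
    sinv <- pooled_cov_inv(as.matrix(rbind(tr[, match_cols], co[, match_cols])))
    for (i in seq_len(nrow(tr))) {
      best_d <- Inf
      best_j <- NA_integer_
      for (j in seq_len(nrow(co))) {
        if (different_property && co$property_id[j] == tr$property_id[i]) next
        dij <- mahalanobis_distance(as.numeric(tr[i, match_cols]),
                                    as.numeric(co[j, match_cols]), sinv)
        if (dij < best_d - 1e-12) {
          best_d <- dij
          best_j <- j
        }
      }
      if (!is.na(best_j)) {
        out[[length(out) + 1]] <- tibble::tibble(
          treated_id = tr$pixel_id[i], control_id = co$pixel_id[best_j],
          distance = best_d
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# random matching instance on a common schema
random_match_instance <- function(n_t, n_c, p = 3, seed = 1) {
  set.seed(seed)
  n <- n_t + n_c
  covs <- matrix(stats::rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("x", seq_len(p))))
  tibble::as_tibble(covs) |>
    dplyr::mutate(
      pixel_id = seq_len(n),
      property_id = sample(1:max(3, n %/% 8), n, replace = TRUE),
      biome = sample(c("dry", "moist"), n, replace = TRUE),
      y_loss = stats::rbinom(n, 1, 0.2),
      lps = stats::rnorm(n),
      arm = rep(c(1L, 0L), c(n_t, n_c))
    )
}
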