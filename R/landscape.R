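#' Configure a synthetic forest landscape
#'
#' Builds the parameter set for [generate_landscape()]. The defaults emulate
#' the structure of a tropical forest mosaic under mixed land tenure: smooth
#' (spatially autocorrelated) biophysical covariates, a cadastre-like property
#' tessellation with tenure assigned at the property level, protected areas
#' placed preferentially on remote, high-biomass land (endogenous placement),
#' a binary 2000-2014 clearing outcome driven by a logistic baseline model,
#' and a protection effect that varies along the woody-biomass gradient.
#'
#' @param grid_width,grid_height Grid dimensions in 30 m pixels (>= 8).
#' @param n_properties Number of properties in the Voronoi tessellation.
#' @param tenure_shares Named numeric vector of property-level tenure
#'   probabilities; must sum to 1. Names become the `tenure` labels.
#' @param pa_coverage Fraction of pixels placed under formal protection.
#' @param covariate_field_params Named list; one entry per covariate with
#'   elements `mean`, `sd`, `range` (spatial correlation range, pixels) and
#'   optional `min`, `max` truncation bounds.
#' @param baseline_logit_coefs Named vector of coefficients of the clearing
#'   logit on standardized covariates; must include `(Intercept)`.
#' @param effect_curve_params List describing the true treatment effect
#'   \eqn{\tau(z)} on the probability scale as a function of biomass `z`:
#'   `list(type = "constant", value = )`, `list(type = "bump", tau_max = ,
#'   center = , width = )`, or `list(type = "none")`.
#' @param leakage_rate Fraction of protection-suppressed clearings displaced
#'   to an unprotected pixel of the same property (in `[0, 1]`).
#' @param placement_coefs Named vector of coefficients used to score
#'   properties for protection (on standardized property-mean covariates).
#' @param placement_noise_sd Standard deviation of the noise added to the
#'   protection score (larger = protection less endogenous).
#' @param partial_frac Probability that a selected property is only partially
#'   protected (needed for spillover designs).
#' @param dry_share Fraction of pixels in the dry broadleaf biome; the rest
#'   is moist broadleaf apart from `mangrove_frac`.
#' @param mangrove_frac,urban_frac,water_frac Small fractions of pixels
#'   flagged as mangrove biome, urban, or water, to exercise exclusion rules.
#' @param seed Integer seed; the landscape is a deterministic function of the
#'   config including the seed.
#'
#' @return An object of class `landscape_config` (a validated list).
#' @seealso [generate_landscape()], [oracle_att()]
#' @export
landscape_config <- function(grid_width = 200,
                             grid_height = 200,
                             n_properties = 150,
                             tenure_shares = c(ejido = 0.62, private = 0.21, parceled = 0.17),
                             pa_coverage = 0.08,
                             covariate_field_params = default_covariate_fields(),
                             baseline_logit_coefs = default_baseline_coefs(),
                             effect_curve_params = list(type = "bump", tau_max = -0.08,
                                                        center = 40, width = 30),
                             leakage_rate = 0.3,
                             placement_coefs = c(dist_urban_km = 0.6, dist_road_km = 0.5,
                                                 elevation_m = 0.3, biomass_tc_ha = 0.6,
                                                 pop_density_km2 = -0.4),
                             placement_noise_sd = 1.5,
                             partial_frac = 0.5,
                             dry_share = 0.45,
                             mangrove_frac = 0.01,
                             urban_frac = 0.002,
                             water_frac = 0.002,
                             seed = 1L) {
  abort_if(grid_width < 8 || grid_height < 8, "grid dimensions must be at least 8 pixels")
  abort_if(abs(sum(tenure_shares) - 1) > 1e-9, "tenure_shares must sum to 1")
  abort_if(any(tenure_shares < 0), "tenure_shares must be nonnegative")
  abort_if(is.null(names(tenure_shares)) || any(names(tenure_shares) == ""),
           "tenure_shares must be named")
  abort_if(pa_coverage < 0 || pa_coverage > 1, "pa_coverage must lie in [0, 1]")
  abort_if(leakage_rate < 0 || leakage_rate > 1, "leakage_rate must lie in [0, 1]")
  abort_if(n_properties < 1, "n_properties must be positive")
  abort_if(!"biomass_tc_ha" %in% names(covariate_field_params),
           "covariate_field_params must include biomass_tc_ha (the heterogeneity axis)")
  abort_if(!"(Intercept)" %in% names(baseline_logit_coefs),
           "baseline_logit_coefs must include an (Intercept) term")
  extra <- setdiff(setdiff(names(baseline_logit_coefs), "(Intercept)"),
                   names(covariate_field_params))
  abort_if(length(extra) > 0,
           paste0("baseline_logit_coefs refer to unknown covariate(s): ",
                  paste(extra, collapse = ", ")))
  abort_if(!effect_curve_params$type %in% c("constant", "bump", "linear", "none"),
           "effect_curve_params$type must be one of constant, bump, linear, none")

  structure(
    list(
      grid_width = as.integer(grid_width), grid_height = as.integer(grid_height),
      n_properties = as.integer(n_properties), tenure_shares = tenure_shares,
      pa_coverage = pa_coverage, covariate_field_params = covariate_field_params,
      baseline_logit_coefs = baseline_logit_coefs,
      effect_curve_params = effect_curve_params, leakage_rate = leakage_rate,
      placement_coefs = placement_coefs, placement_noise_sd = placement_noise_sd,
      partial_frac = partial_frac, dry_share = dry_share,
      mangrove_frac = mangrove_frac, urban_frac = urban_frac,
      water_frac = water_frac, seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

#' Default covariate random-field parameters
#'
#' Ten biophysical / socioeconomic covariates: distances (km), climate,
#' terrain, percent tree cover in 2000, population density and woody biomass
#' (tC/ha). Magnitudes are loosely calibrated to a seasonally dry tropical
#' forest frontier; `range` is the spatial correlation range in pixels.
#'
#' @return Named list of per-covariate field parameters.
#' @export
default_covariate_fields <- function() {
  list(
    dist_water_km   = list(mean = 8,    sd = 5,    range = 25, min = 0),
    dist_urban_km   = list(mean = 20,   sd = 12,   range = 30, min = 0),
    dist_road_km    = list(mean = 6,    sd = 4,    range = 20, min = 0),
    temperature_c   = list(mean = 25,   sd = 1.2,  range = 40),
    precipitation_mm = list(mean = 1100, sd = 250, range = 40, min = 300),
    elevation_m     = list(mean = 120,  sd = 80,   range = 35, min = 0),
    slope_deg       = list(mean = 3,    sd = 2.5,  range = 10, min = 0),
    forest_cover_pct = list(mean = 75,  sd = 18,   range = 12, min = 0, max = 100),
    pop_density_km2 = list(mean = 25,   sd = 25,   range = 20, min = 0),
    biomass_tc_ha   = list(mean = 50,   sd = 22,   range = 18, min = 0)
  )
}

#' Default clearing-logit coefficients
#'
#' Coefficients of the baseline (no protection) clearing model on
#' standardized covariates. Accessibility and population pressure raise the
#' clearing odds; remoteness, slope and standing biomass lower them, so that
#' protected-area placement on remote high-biomass land confounds naive
#' comparisons.
#'
#' @return Named numeric vector including `(Intercept)`.
#' @export
default_baseline_coefs <- function() {
  c(`(Intercept)` = -1.7,
    dist_urban_km = -0.15, dist_road_km = -0.12, dist_water_km = -0.03,
    elevation_m = -0.06, slope_deg = -0.09, pop_density_km2 = 0.13,
    precipitation_mm = -0.03, temperature_c = 0.03,
    forest_cover_pct = 0.05, biomass_tc_ha = -0.07)
}

#' True treatment-effect curve
#'
#' Evaluates the generator's ground-truth protection effect \eqn{\tau(z)}
#' (risk difference, probability scale) at biomass values `z`.
#'
#' @param z Numeric vector of biomass values (tC/ha).
#' @param params `effect_curve_params` list as in [landscape_config()].
#' @return Numeric vector of effects, same length as `z`.
#' @export
#' @examples
#' effect_curve(c(10, 40, 120), list(type = "bump", tau_max = -0.08,
#'                                   center = 40, width = 30))
effect_curve <- function(z, params) {
  switch(params$type,
    none     = rep(0, length(z)),
    constant = rep(params$value, length(z)),
    linear   = params$intercept + params$slope * z,
    bump     = params$tau_max * exp(-((z - params$center) / params$width)^2),
    stop("unknown effect curve type: ", params$type, call. = FALSE)
  )
}

# Spatially autocorrelated standard field: white noise convolved (on the
# torus, via FFT) with a Gaussian kernel of sd = range pixels, restandardized.
gaussian_field <- function(nrow, ncol, range) {
  noise <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (range <= 0) return(noise)
  dr <- pmin(0:(nrow - 1), nrow - (0:(nrow - 1)))
  dc <- pmin(0:(ncol - 1), ncol - (0:(ncol - 1)))
  kern <- exp(-outer(dr^2, dc^2, `+`) / (2 * range^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nrow * ncol)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic landscape with a stored counterfactual
#'
#' Simulates a pixel-level forest landscape from a [landscape_config()]:
#' smooth covariate fields, a nearest-seed property tessellation carrying
#' tenure labels, endogenous protected-area placement at property granularity
#' (with partially protected properties), a binary clearing outcome
#' `y_loss` drawn from a logistic baseline plus the probability-scale
#' treatment effect \eqn{\tau(z)}, and the counterfactual outcome `y0_loss`
#' obtained from the same uniform draws with protection removed (common
#' random numbers). A fraction `leakage_rate` of protection-suppressed
#' clearings is displaced onto a random unprotected pixel of the same
#' property, producing within-property spillovers.
#'
#' @param config A [landscape_config()].
#' @return An object of class `synthetic_landscape`: a list with
#'   * `pixels` — tibble, one row per pixel (`pixel_id`, `row`, `col`,
#'     `biome`, `tenure`, `property_id`, `protected`, `protection_class`,
#'     the covariates, `is_urban`, `is_water`, `y_loss`, `y0_loss`);
#'   * `properties` — tibble (`property_id`, `tenure`, `n_pixels`,
#'     `protected_fraction`);
#'   * `config` — the config echo.
#' @export
#' @examples
#' ls <- generate_landscape(landscape_config(grid_width = 40, grid_height = 40,
#'                                           n_properties = 12, seed = 7))
#' oracle_att(ls$pixels)
generate_landscape <- function(config) {
  abort_if(!inherits(config, "landscape_config"),
           "config must be created with landscape_config()")
  set.seed(config$seed)
  nr <- config$grid_height
  nc <- config$grid_width
  npix <- nr * nc
  row_idx <- rep(seq_len(nr), times = nc)
  col_idx <- rep(seq_len(nc), each = nr)

  # covariate fields
  covs <- purrr::imap(config$covariate_field_params, function(p, nm) {
    x <- p$mean + p$sd * gaussian_field(nr, nc, p$range)
    if (!is.null(p$min)) x <- pmax(x, p$min)
    if (!is.null(p$max)) x <- pmin(x, p$max)
    as.vector(x)
  })
  cov_tbl <- tibble::as_tibble(covs)

  # biome from an independent smooth field; mangrove carved from the moist tail
  bfield <- as.vector(gaussian_field(nr, nc, 30))
  biome <- ifelse(bfield <= stats::quantile(bfield, config$dry_share), "dry", "moist")
  if (config$mangrove_frac > 0) {
    biome[bfield >= stats::quantile(bfield, 1 - config$mangrove_frac)] <- "mangrove"
  }
  ufield <- as.vector(gaussian_field(nr, nc, 6))
  is_urban <- config$urban_frac > 0 &
    ufield >= stats::quantile(ufield, 1 - config$urban_frac)
  wfield <- as.vector(gaussian_field(nr, nc, 6))
  is_water <- config$water_frac > 0 &
    wfield >= stats::quantile(wfield, 1 - config$water_frac)

  # nearest-seed (Voronoi) property tessellation
  seeds_r <- stats::runif(config$n_properties, 1, nr)
  seeds_c <- stats::runif(config$n_properties, 1, nc)
  d2 <- outer(row_idx, seeds_r, `-`)^2 + outer(col_idx, seeds_c, `-`)^2
  property_id <- max.col(-d2, ties.method = "first")
  tenure_prop <- sample(names(config$tenure_shares), config$n_properties,
                        replace = TRUE, prob = config$tenure_shares)

  # standardized covariates (empirical moments) used by placement and outcome
  std <- purrr::map(cov_tbl, ~ (.x - mean(.x)) / stats::sd(.x))

  # endogenous protection: score properties by remoteness/biomass, protect
  # from the top until pa_coverage of pixels is reached; some properties only
  # partially (pixels nearest the property seed), so spillover pools exist
  prop_sizes <- tabulate(property_id, nbins = config$n_properties)
  score <- rep(0, config$n_properties)
  for (nm in names(config$placement_coefs)) {
    if (!nm %in% names(std)) next
    pm <- as.vector(tapply(std[[nm]], factor(property_id, seq_len(config$n_properties)),
                           mean, default = 0))
    pm[is.na(pm)] <- 0
    score <- score + config$placement_coefs[[nm]] * pm
  }
  score <- score + stats::rnorm(config$n_properties, sd = config$placement_noise_sd)

  protected <- rep(0L, npix)
  target <- config$pa_coverage * npix
  got <- 0
  for (p in order(score, decreasing = TRUE)) {
    if (got >= target || prop_sizes[p] == 0) break
    frac <- if (stats::runif(1) < config$partial_frac) stats::runif(1, 0.3, 0.9) else 1
    members <- which(property_id == p)
    n_take <- max(1L, round(frac * length(members)))
    # protect the chunk of the property nearest its seed (spatially coherent)
    dd <- (row_idx[members] - seeds_r[p])^2 + (col_idx[members] - seeds_c[p])^2
    take <- members[order(dd)][seq_len(n_take)]
    protected[take] <- 1L
    got <- got + n_take
  }

  # outcome model: logistic baseline + probability-scale effect tau(z) under
  # protection; counterfactual from the same uniform draws with D = 0
  lp <- rep(config$baseline_logit_coefs[["(Intercept)"]], npix)
  for (nm in setdiff(names(config$baseline_logit_coefs), "(Intercept)")) {
    lp <- lp + config$baseline_logit_coefs[[nm]] * std[[nm]]
  }
  p0 <- stats::plogis(lp)
  tau <- effect_curve(cov_tbl$biomass_tc_ha, config$effect_curve_params)
  p1 <- pmin(pmax(p0 + tau, 0), 1)
  u <- stats::runif(npix)
  y0 <- as.integer(u < p0)
  y1 <- as.integer(u < p1)
  y <- ifelse(protected == 1L, y1, y0)

  # leakage: displaced clearing within partially protected properties
  prot_frac <- as.vector(tapply(protected, factor(property_id, seq_len(config$n_properties)),
                                mean, default = 0))
  prot_frac[is.na(prot_frac)] <- 0
  if (config$leakage_rate > 0) {
    partial <- which(prot_frac > 0 & prot_frac < 1)
    for (p in partial) {
      members <- which(property_id == p)
      suppressed <- members[protected[members] == 1L &
                              y0[members] == 1L & y[members] == 0L]
      if (length(suppressed) == 0) next
      n_disp <- stats::rbinom(1, length(suppressed), config$leakage_rate)
      if (n_disp == 0) next
      cand <- members[protected[members] == 0L & y[members] == 0L]
      if (length(cand) == 0) next
      hit <- if (length(cand) == 1) cand else sample(cand, min(n_disp, length(cand)))
      y[hit] <- 1L
    }
  }

  protection_class <- dplyr::case_when(
    protected == 1L ~ "protected",
    prot_frac[property_id] > 0 ~ "unprotected_part_of_protected_property",
    TRUE ~ "fully_unprotected"
  )

  pixels <- dplyr::bind_cols(
    tibble::tibble(
      pixel_id = seq_len(npix), row = row_idx, col = col_idx,
      biome = biome, tenure = tenure_prop[property_id],
      property_id = property_id, protected = protected,
      protection_class = protection_class
    ),
    cov_tbl,
    tibble::tibble(is_urban = is_urban, is_water = is_water,
                   y_loss = as.integer(y), y0_loss = y0)
  )

  properties <- tibble::tibble(
    property_id = seq_len(config$n_properties),
    tenure = tenure_prop,
    n_pixels = prop_sizes,
    protected_fraction = prot_frac
  )

  structure(list(pixels = pixels, properties = properties, config = config),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_landscape> ", cfg$grid_height, "x", cfg$grid_width,
      " pixels, ", cfg$n_properties, " properties, seed ", cfg$seed, "\n", sep = "")
  cat("  protected: ", sum(x$pixels$protected), " pixels (",
      round(100 * mean(x$pixels$protected), 1), "%), clearing rate ",
      round(mean(x$pixels$y_loss), 3), "\n", sep = "")
  invisible(x)
}

#' Ground-truth treatment effect on the treated
#'
#' Computes the oracle ATT of a synthetic landscape: the mean difference
#' between the realized outcome `y_loss` and the stored counterfactual
#' `y0_loss` over treated pixels. This is the recovery target for the
#' matching estimators. Negative values mean protection reduced the
#' probability of clearing.
#'
#' @param data A pixel tibble carrying `y_loss` and `y0_loss` (e.g.
#'   `generate_landscape(cfg)$pixels`), or a `synthetic_landscape`.
#' @param treated Expression (tidy-eval) defining the treated set; defaults
#'   to `protected == 1`. For spillover oracles use
#'   `protection_class == "unprotected_part_of_protected_property"`.
#' @param subset Optional expression restricting the evaluation subgroup.
#' @return A single number: mean(y_loss - y0_loss) over treated pixels.
#' @export
#' @examples
#' ls <- generate_landscape(landscape_config(grid_width = 40, grid_height = 40,
#'                                           seed = 3))
#' oracle_att(ls$pixels, subset = biome == "dry")
oracle_att <- function(data, treated = NULL, subset = NULL) {
  if (inherits(data, "synthetic_landscape")) data <- data$pixels
  require_columns(data, c("y_loss", "y0_loss"))
  treated <- rlang::enquo(treated)
  subset <- rlang::enquo(subset)
  if (!rlang::quo_is_null(subset)) data <- dplyr::filter(data, !!subset)
  if (rlang::quo_is_null(treated)) {
    require_columns(data, "protected")
    data <- dplyr::filter(data, .data$protected == 1)
  } else {
    data <- dplyr::filter(data, !!treated)
  }
  abort_if(nrow(data) == 0, "no treated pixels in the requested subgroup")
  mean(data$y_loss - data$y0_loss)
}

#' Plot a synthetic landscape
#'
#' Tile maps of protection status, tenure, the outcome and biomass.
#'
#' @param object A `synthetic_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_landscape <- function(object, ...) {
  px <- object$pixels
  long <- dplyr::bind_rows(
    dplyr::transmute(px, .data$row, .data$col, panel = "protection",
                     value = as.character(.data$protected)),
    dplyr::transmute(px, .data$row, .data$col, panel = "tenure",
                     value = .data$tenure),
    dplyr::transmute(px, .data$row, .data$col, panel = "forest loss",
                     value = as.character(.data$y_loss)),
    dplyr::transmute(px, .data$row, .data$col, panel = "biome",
                     value = .data$biome)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
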