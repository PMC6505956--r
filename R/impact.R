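#' Percent of forest cleared
#'
#' `100 * deforestation / forest`, rounded half away from zero to 2 decimals
#' for table reproduction.
#'
#' @param deforestation_ha Cleared area (ha), >= 0.
#' @param forest_ha Forest area in 2000 (ha), > 0.
#' @param digits Decimals for the reported value.
#' @return Percent cleared.
#' @export
#' @examples
#' percent_cleared(1399.59, 33739.02)  # 4.15
percent_cleared <- function(deforestation_ha, forest_ha, digits = 2) {
  abort_if(any(forest_ha <= 0), "forest_ha must be positive")
  abort_if(any(deforestation_ha < 0), "deforestation_ha must be nonnegative")
  round_half_out(100 * deforestation_ha / forest_ha, digits)
}

#' Annual deforestation rate
#'
#' Converts a percent cleared over the study window into a signed annual
#' fraction (negative = loss): `-(percent/100)/years`.
#'
#' @param pct_cleared Percent cleared over the window.
#' @param years Window length in years.
#' @param digits Decimals for the reported value; `NULL` for unrounded.
#' @return Fraction per year, negative for loss.
#' @export
#' @examples
#' annual_rate(4.15, digits = 3)   # -0.003
#' annual_rate(11.60, digits = 2)  # -0.01
annual_rate <- function(pct_cleared, years = 14, digits = NULL) {
  abort_if(years <= 0, "years must be positive")
  out <- -(pct_cleared / 100) / years
  if (!is.null(digits)) out <- round_half_out(out, digits)
  out
}

#' Avoided (or induced) deforestation area
#'
#' Converts an ATT (change in clearing probability) into hectares over the
#' whole study area: `|att| * n_mc * pixel_area_ha * scale`, signed positive
#' for avoided loss (att < 0) and negative for induced loss (att > 0).
#' `n_mc` is the matched-control count, `pixel_area_ha` the 30 m pixel area
#' (0.09 ha) and `scale` the inverse sampling fraction (100 for a 1% sample).
#' `mode = "literal"` additionally multiplies by the matched-control mean
#' deforestation rate, an alternative reading of the extrapolation recipe.
#'
#' @param att Signed ATT (probability difference).
#' @param n_mc Number of matched control pixels.
#' @param pixel_area_ha Pixel area in hectares.
#' @param scale Extrapolation factor from the sampling fraction.
#' @param control_rate Matched-control mean deforestation rate (used only in
#'   literal mode).
#' @param mode `"standard"` or `"literal"`.
#' @param digits Decimals for the reported value; `NULL` for unrounded.
#' @return Hectares, signed (positive = avoided loss).
#' @export
#' @examples
#' avoided_area(-0.09, 286)    # 231.7 ha
#' avoided_area(-0.03, 21124)  # 5703.5 ha
avoided_area <- function(att, n_mc, pixel_area_ha = 0.09, scale = 100,
                         control_rate = NULL, mode = c("standard", "literal"),
                         digits = 1) {
  mode <- match.arg(mode)
  abort_if(any(n_mc < 0), "n_mc must be nonnegative")
  out <- -att * n_mc * pixel_area_ha * scale
  if (mode == "literal") {
    abort_if(is.null(control_rate), "literal mode needs control_rate")
    out <- out * control_rate
  }
  if (!is.null(digits)) out <- round_half_out(out, digits)
  out
}

#' Avoided carbon
#'
#' Avoided deforestation area times the mean biomass of the matched control
#' group, in tC.
#'
#' @param area_ha Avoided area (ha), signed.
#' @param mean_biomass_tc_ha Mean biomass (tC/ha), >= 0.
#' @return Avoided carbon (tC), signed like `area_ha`.
#' @export
avoided_carbon <- function(area_ha, mean_biomass_tc_ha) {
  abort_if(any(mean_biomass_tc_ha < 0), "biomass must be nonnegative")
  area_ha * mean_biomass_tc_ha
}

#' Net direct-plus-spillover avoided deforestation
#'
#' Sums the signed avoided areas of the statistically significant entries
#' only (direct and spillover); a negative total means protection caused net
#' induced deforestation through leakage.
#'
#' @param results Tibble with columns `avoided_area_ha` and `significant`
#'   (logical, at the 10% level).
#' @param digits Decimals for the reported value; `NULL` for unrounded.
#' @return Signed hectares.
#' @export
#' @examples
#' net_effect(tibble::tibble(
#'   avoided_area_ha = c(231.66, 253.8, -1138.95),
#'   significant = TRUE
#' ))  # -653.5
net_effect <- function(results, digits = 1) {
  require_columns(results, c("avoided_area_ha", "significant"), "results")
  out <- sum(results$avoided_area_ha[results$significant])
  if (length(out) == 0 || !any(results$significant)) out <- 0
  if (!is.null(digits)) out <- round_half_out(out, digits)
  out
}

#' Extrapolate an ATT estimate to avoided deforestation and carbon
#'
#' @param estimate An `att_estimate` from [run_comparison()].
#' @param pixel_area_ha,scale,mode See [avoided_area()].
#' @param sig_level Significance level (default 10%) used for the
#'   `significant` flag, read off the matching confidence interval.
#' @return One-row tibble: `label`, `biome`, `att`, `n_mc`,
#'   `avoided_area_ha`, `mean_biomass_tc_ha`, `avoided_carbon_tc`,
#'   `significant`.
#' @export
extrapolate_impact <- function(estimate, pixel_area_ha = 0.09, scale = 100,
                               mode = "standard", sig_level = 0.10) {
  abort_if(!inherits(estimate, "att_estimate"), "estimate must be an att_estimate")
  if (!estimate$feasible) {
    return(tibble::tibble(
      label = estimate$label, biome = estimate$biome, att = NA_real_,
      n_mc = NA_integer_, avoided_area_ha = NA_real_,
      mean_biomass_tc_ha = NA_real_, avoided_carbon_tc = NA_real_,
      significant = NA
    ))
  }
  att <- estimate$bias_adjusted_att
  ci <- estimate$ci[abs(estimate$ci$level - (1 - sig_level)) < 1e-9, ]
  significant <- nrow(ci) == 1 && (ci$lower > 0 || ci$upper < 0)
  ctrl <- estimate$matched$matched_controls
  mean_biomass <- if ("biomass_tc_ha" %in% names(ctrl)) {
    mean(ctrl$biomass_tc_ha)
  } else NA_real_
  area <- avoided_area(att, estimate$n_mc, pixel_area_ha, scale,
                       control_rate = estimate$mean_control, mode = mode,
                       digits = NULL)
  tibble::tibble(
    label = estimate$label, biome = estimate$biome, att = att,
    n_mc = estimate$n_mc, avoided_area_ha = area,
    mean_biomass_tc_ha = mean_biomass,
    avoided_carbon_tc = avoided_carbon(area, ifelse(is.na(mean_biomass), 0, mean_biomass)),
    significant = significant
  )
}

#' Descriptive clearing statistics by stratum
#'
#' Per biome x tenure x protection stratum: pixel counts, implied areas,
#' percent cleared and the annual rate, from a pixel table with the outcome
#' coded.
#'
#' @param data Pixel tibble with `biome`, `tenure`, `protection_class`,
#'   `y_loss`.
#' @param pixel_area_ha Pixel area (ha).
#' @param years Study window length.
#' @return A tibble, one row per stratum.
#' @export
descriptive_stats <- function(data, pixel_area_ha = 0.09, years = 14) {
  require_columns(data, c("biome", "tenure", "protection_class", "y_loss"))
  data |>
    dplyr::group_by(.data$biome, .data$tenure, .data$protection_class) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      forest_ha = dplyr::n() * pixel_area_ha,
      deforestation_ha = sum(.data$y_loss) * pixel_area_ha,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_cleared = percent_cleared(.data$deforestation_ha, .data$forest_ha),
      annual_rate = annual_rate(.data$pct_cleared, years = years, digits = 3)
    )
}
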