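#' Normalized difference between two covariate distributions
#'
#' \deqn{(\bar x_t - \bar x_c) / \sqrt{(s^2_t + s^2_c)/2}} with unbiased
#' (n-1) variances. When frequency weights are supplied for the control
#' sample (control reuse counts of matching with replacement), the control
#' moments are weight-adjusted. Values above 0.25 in magnitude are the
#' conventional imbalance flag.
#'
#' @param x_treated,x_control Numeric samples (>= 2 values each).
#' @param weights Optional nonnegative frequency weights for `x_control`.
#' @return A single number; `Inf`/`-Inf` when the pooled variance is zero but
#'   the means differ, 0 when both moments coincide.
#' @export
#' @examples
#' normalized_difference(c(0, 2), c(1, 3))  # -1/sqrt(2)
normalized_difference <- function(x_treated, x_control, weights = NULL) {
  abort_if(length(x_treated) < 2 || length(x_control) < 2,
           "both samples need at least 2 values")
  mt <- mean(x_treated)
  vt <- stats::var(x_treated)
  if (is.null(weights)) {
    mc <- mean(x_control)
    vc <- stats::var(x_control)
  } else {
    abort_if(length(weights) != length(x_control), "weights must align with x_control")
    abort_if(any(weights < 0), "weights must be nonnegative")
    W <- sum(weights)
    mc <- sum(weights * x_control) / W
    vc <- sum(weights * (x_control - mc)^2) / (W - 1)
  }
  pooled <- (vt + vc) / 2
  if (pooled == 0) {
    if (mt == mc) return(0)
    return(sign(mt - mc) * Inf)
  }
  (mt - mc) / sqrt(pooled)
}

#' Covariate balance table
#'
#' One row per covariate with treated/control moments and the normalized
#' difference, either for the unmatched arms (`matched = NULL`) or for the
#' matched sample, where control moments are reuse-weighted.
#'
#' @param treated,controls Tibbles of the two arms (ignored when `matched`
#'   is supplied).
#' @param covariates Covariate column names.
#' @param matched Optional [match_nearest_neighbor()] result.
#' @param threshold Absolute normalized difference above which a covariate is
#'   flagged `imbalanced`.
#' @return A tibble: `covariate`, `mean_treated`, `mean_control`,
#'   `sd_treated`, `sd_control`, `normalized_difference`, `flag`.
#' @export
balance_table <- function(treated = NULL, controls = NULL, covariates,
                          matched = NULL, threshold = 0.25) {
  if (!is.null(matched)) {
    abort_if(!inherits(matched, "matched_sample"), "matched must be a matched_sample")
    treated <- matched$treated
    ctrl_idx <- !duplicated(matched$pairs$control_id)
    controls <- matched$matched_controls[ctrl_idx, , drop = FALSE]
    w <- matched$weights$K[match(matched$pairs$control_id[ctrl_idx],
                                 matched$weights$control_id)]
  } else {
    abort_if(is.null(treated) || is.null(controls),
             "supply treated and controls, or a matched sample")
    w <- NULL
  }
  require_columns(treated, covariates, "covariate")
  require_columns(controls, covariates, "covariate")

  rows <- purrr::map(covariates, function(nm) {
    xt <- treated[[nm]]
    xc <- controls[[nm]]
    nd <- normalized_difference(xt, xc, weights = w)
    if (is.null(w)) {
      mc <- mean(xc)
      sdc <- stats::sd(xc)
    } else {
      mc <- sum(w * xc) / sum(w)
      sdc <- sqrt(sum(w * (xc - mc)^2) / (sum(w) - 1))
    }
    tibble::tibble(
      covariate = nm,
      mean_treated = mean(xt), mean_control = mc,
      sd_treated = stats::sd(xt), sd_control = sdc,
      normalized_difference = nd,
      flag = ifelse(abs(nd) > threshold, "imbalanced", "ok")
    )
  })
  dplyr::bind_rows(rows)
}
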