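#' Fit a treatment-assignment (propensity) model
#'
#' Maximum-likelihood logistic regression of a binary treatment indicator on
#' the covariates, returning per-unit fitted probabilities and the linearized
#' score (log-odds), the quantity used for trimming and for the
#' propensity-augmented matching metric. Perfect separation is surfaced as an
#' error rather than silently regularized.
#'
#' @param data Sample tibble.
#' @param treatment Column name (string) of the 0/1 treatment indicator, or a
#'   tidy-eval expression defining it.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `propensity_fit`: list with `model` (the glm),
#'   `coefficients` (tibble: term, estimate, std_error), `scores` (tibble:
#'   phat, lps aligned with `data` rows), `treatment` (the 0/1 vector),
#'   `converged`.
#' @export
fit_propensity <- function(data, treatment, covariates) {
  require_columns(data, covariates, "covariate")
  if (is.character(treatment) && length(treatment) == 1 && treatment %in% names(data)) {
    d <- as.integer(data[[treatment]])
  } else {
    d <- as.integer(rlang::eval_tidy(rlang::enquo(treatment), data))
  }
  abort_if(anyNA(d) || !all(d %in% c(0L, 1L)), "treatment must be binary 0/1")
  abort_if(sum(d) == 0 || sum(d) == length(d), "both treatment arms must be non-empty")
  abort_if(anyNA(data[, covariates]), "covariates must be complete (no NA)")

  X <- data[, covariates, drop = FALSE]
  fit <- suppressWarnings(
    stats::glm(d ~ ., data = cbind(d = d, X), family = stats::binomial())
  )
  p <- stats::fitted(fit)
  eps <- 1e-10
  # genuine separation: the likelihood has no maximum, so IRLS fails to
  # converge or the deviance collapses to zero; numerically extreme fitted
  # probabilities alone are tolerated (they are handled by trimming)
  separated <- !fit$converged || stats::deviance(fit) < 1e-6
  abort_if(separated,
           "propensity model did not converge (possible perfect separation); drop offending covariates")

  p <- pmin(pmax(p, eps), 1 - eps)
  sm <- summary(fit)$coefficients
  structure(
    list(
      model = fit,
      coefficients = tibble::tibble(
        term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2]
      ),
      scores = tibble::tibble(phat = as.numeric(p), lps = as.numeric(stats::qlogis(p))),
      treatment = d,
      converged = TRUE
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> ", sum(x$treatment), " treated / ",
      sum(1 - x$treatment), " control; ",
      nrow(x$coefficients) - 1, " covariates\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.propensity_fit <- function(x, ...) x$coefficients

#' @importFrom generics glance
#' @export
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$treatment), n_treated = sum(x$treatment),
    converged = x$converged,
    deviance = stats::deviance(x$model), aic = stats::AIC(x$model)
  )
}

#' Trim treated units to the region of common support
#'
#' Removes treated units whose linearized propensity score lies outside the
#' `[min, max]` range of the control scores and, when `caliper_sd > 0`,
#' treated units with no control score within `caliper_sd` standard
#' deviations of the (pooled) linearized score. Controls are never removed.
#'
#' @param data Sample tibble (rows aligned with `fit$scores`).
#' @param fit A [fit_propensity()] result.
#' @param caliper_sd Caliper width in SD units of the linearized score; 0
#'   disables the caliper and leaves the pure min-max support rule.
#' @return A list: `sample` (on-support tibble, with `phat`, `lps` columns
#'   appended), `n_trimmed`, `n_t` (treated remaining on support).
#' @export
trim_common_support <- function(data, fit, caliper_sd = 0.25) {
  abort_if(!inherits(fit, "propensity_fit"), "fit must be a propensity_fit")
  abort_if(nrow(data) != nrow(fit$scores), "fit does not cover all units")
  d <- fit$treatment
  lps <- fit$scores$lps
  ctrl <- lps[d == 0]
  keep <- rep(TRUE, nrow(data))
  on_range <- lps >= min(ctrl) & lps <= max(ctrl)
  keep[d == 1] <- on_range[d == 1]
  if (caliper_sd > 0) {
    w <- caliper_sd * stats::sd(lps)
    ctrl_sorted <- sort(ctrl)
    ti <- which(d == 1 & keep)
    if (length(ti) > 0) {
      pos <- findInterval(lps[ti], ctrl_sorted)
      lo <- ctrl_sorted[pmax(pos, 1)]
      hi <- ctrl_sorted[pmin(pos + 1, length(ctrl_sorted))]
      near <- pmin(abs(lps[ti] - lo), abs(lps[ti] - hi)) <= w
      keep[ti] <- near
    }
  }
  abort_if(sum(d == 1 & keep) == 0, "all treated units trimmed: no common support")
  out <- data[keep, , drop = FALSE]
  out$phat <- fit$scores$phat[keep]
  out$lps <- lps[keep]
  list(sample = out, n_trimmed = sum(!keep), n_t = sum(d == 1 & keep))
}
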