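#' Mahalanobis distance between two covariate vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @param sigma_inv Inverse of the (pooled) covariance matrix; must come from
#'   a positive-definite covariance (see [pooled_cov_inv()]).
#' @return A nonnegative scalar, zero iff `u == v`.
#' @export
#' @examples
#' mahalanobis_distance(c(0, 0), c(3, 4), diag(2))  # Euclidean: 5
mahalanobis_distance <- function(u, v, sigma_inv) {
  d <- u - v
  val <- drop(t(d) %*% sigma_inv %*% d)
  abort_if(val < -1e-8, "sigma_inv is not positive semidefinite")
  sqrt(max(val, 0))
}

#' Regularized inverse of a pooled covariance matrix
#'
#' Covariance over the stacked treated + control covariates, with
#' `1e-8 * trace` added to the diagonal before inversion to guard against
#' near-singularity.
#'
#' @param X Numeric matrix (units x covariates).
#' @param regularize Ridge factor applied as `regularize * trace(S)` on the
#'   diagonal; set 0 to require exact positive definiteness.
#' @return The inverse covariance matrix.
#' @export
pooled_cov_inv <- function(X, regularize = 1e-8) {
  S <- stats::cov(X)
  if (regularize > 0) S <- S + diag(regularize * sum(diag(S)), ncol(S))
  out <- tryCatch(solve(S), error = function(e) NULL)
  abort_if(is.null(out), "singular pooled covariance; increase regularization")
  out
}

# whitening transform so that Mahalanobis distance = Euclidean distance
whiten <- function(X, sigma_inv) {
  U <- chol(sigma_inv)
  X %*% t(U)
}

#' Nearest-neighbour matching with replacement
#'
#' Matches every treated unit to its minimum-distance admissible control
#' (with replacement) under a Mahalanobis metric over the covariates
#' (`metric = "mahalanobis_trimmed"`) or over the covariates augmented with
#' the linearized propensity score as one extra coordinate
#' (`metric = "ps_augmented"`; requires an `lps` column, see
#' [trim_common_support()]). Matching is performed within biome strata, and
#' controls from the treated unit's own property are inadmissible unless
#' disabled. Distance ties are broken towards the lowest control `pixel_id`
#' so reruns are deterministic. Treated units with no admissible control are
#' dropped with a warning and do not count towards `n_t`.
#'
#' @param treated,controls Tibbles of treated units and the control pool;
#'   must carry `pixel_id`, `property_id`, `y_loss`, the covariates, `biome`
#'   (if `same_biome`), and `lps` (if `metric = "ps_augmented"`).
#' @param covariates Character vector of matching covariate columns.
#' @param metric `"mahalanobis_trimmed"` or `"ps_augmented"`.
#' @param same_biome Require treated and control to share `biome`.
#' @param different_property Forbid controls from the treated unit's property.
#' @param k Number of neighbours per treated unit (the pair effect uses the
#'   mean of the k control outcomes). Default 1.
#' @return An object of class `matched_sample`: list with `pairs` (tibble:
#'   `treated_id`, `control_id`, `distance`, `tt`, `biome`), `treated`
#'   (tibble aligned with pairs for k = 1), `controls` (control pool),
#'   `weights` (tibble: `control_id`, `K` reuse counts), `covariates`,
#'   `metric`, `n_t`, `n_mc`, `n_cp`, `n_dropped`.
#' @export
match_nearest_neighbor <- function(treated, controls, covariates,
                                   metric = c("mahalanobis_trimmed", "ps_augmented"),
                                   same_biome = TRUE, different_property = TRUE,
                                   k = 1L) {
  metric <- match.arg(metric)
  base_cols <- c("pixel_id", "property_id", "y_loss", covariates)
  require_columns(treated, base_cols, "treated")
  require_columns(controls, base_cols, "control")
  abort_if(nrow(controls) == 0, "control pool is empty")
  abort_if(nrow(treated) == 0, "treated set is empty")
  match_cols <- covariates
  if (metric == "ps_augmented") {
    require_columns(treated, "lps", "treated")
    require_columns(controls, "lps", "control")
    match_cols <- c(covariates, "lps")
  }

  strata <- if (same_biome) {
    require_columns(treated, "biome", "treated")
    require_columns(controls, "biome", "control")
    sort(unique(treated$biome))
  } else "all"

  pair_list <- list()
  n_dropped <- 0L
  for (s in strata) {
    tr <- if (same_biome) treated[treated$biome == s, , drop = FALSE] else treated
    co <- if (same_biome) controls[controls$biome == s, , drop = FALSE] else controls
    if (nrow(tr) == 0) next
    if (nrow(co) == 0) {
      warning("no controls in stratum '", s, "': ", nrow(tr), " treated dropped")
      n_dropped <- n_dropped + nrow(tr)
      next
    }
    co <- co[order(co$pixel_id), , drop = FALSE]  # tie-break: lowest control id
    Xt <- as.matrix(tr[, match_cols, drop = FALSE])
    Xc <- as.matrix(co[, match_cols, drop = FALSE])
    sinv <- pooled_cov_inv(rbind(Xt, Xc))
    Zt <- whiten(Xt, sinv)
    Zc <- whiten(Xc, sinv)
    cn2 <- rowSums(Zc^2)

    chunk <- max(1L, floor(2e7 / nrow(co)))
    for (start in seq(1L, nrow(tr), by = chunk)) {
      ii <- start:min(start + chunk - 1L, nrow(tr))
      D2 <- outer(rowSums(Zt[ii, , drop = FALSE]^2), cn2, `+`) -
        2 * Zt[ii, , drop = FALSE] %*% t(Zc)
      if (different_property) {
        same <- outer(tr$property_id[ii], co$property_id, `==`)
        D2[same] <- Inf
      }
      if (k == 1L) {
        best <- max.col(-D2, ties.method = "first")
        dist <- sqrt(pmax(D2[cbind(seq_along(ii), best)], 0))
        feasible <- is.finite(dist)
        n_dropped <- n_dropped + sum(!feasible)
        if (any(!feasible)) {
          warning(sum(!feasible), " treated unit(s) had no admissible control and were dropped")
        }
        idx <- which(feasible)
        pair_list[[length(pair_list) + 1L]] <- tibble::tibble(
          treated_id = tr$pixel_id[ii][idx],
          control_id = co$pixel_id[best[idx]],
          distance = dist[idx],
          tt = tr$y_loss[ii][idx] - co$y_loss[best[idx]],
          biome = if (same_biome) s else NA_character_,
          .t_row = ii[idx], .c_row = best[idx], .stratum = s
        )
      } else {
        for (j in seq_along(ii)) {
          drow <- D2[j, ]
          ord <- order(drow)  # stable: ties to lowest control id
          sel <- ord[seq_len(min(k, sum(is.finite(drow))))]
          if (length(sel) == 0) {
            n_dropped <- n_dropped + 1L
            warning("a treated unit had no admissible control and was dropped")
            next
          }
          pair_list[[length(pair_list) + 1L]] <- tibble::tibble(
            treated_id = tr$pixel_id[ii[j]],
            control_id = co$pixel_id[sel[1]],
            distance = sqrt(max(drow[sel[1]], 0)),
            tt = tr$y_loss[ii[j]] - mean(co$y_loss[sel]),
            biome = if (same_biome) s else NA_character_,
            .t_row = ii[j], .c_row = sel[1], .stratum = s
          )
        }
      }
    }
  }
  abort_if(length(pair_list) == 0, "no feasible matches in any stratum")
  pairs <- dplyr::bind_rows(pair_list)

  # aligned treated/control row views (one row per pair)
  treated_aligned <- dplyr::left_join(
    dplyr::select(pairs, "treated_id"),
    treated, by = c(treated_id = "pixel_id")
  )
  treated_aligned$pixel_id <- treated_aligned$treated_id
  controls_aligned <- dplyr::left_join(
    dplyr::select(pairs, "control_id"),
    controls, by = c(control_id = "pixel_id")
  )
  controls_aligned$pixel_id <- controls_aligned$control_id
  pairs <- dplyr::select(pairs, -".t_row", -".c_row", -".stratum")

  weights <- dplyr::count(pairs, .data$control_id, name = "K")
  structure(
    list(
      pairs = pairs,
      treated = treated_aligned,
      matched_controls = controls_aligned,
      controls = controls,
      weights = weights,
      covariates = covariates,
      match_cols = match_cols,
      metric = metric,
      k = as.integer(k),
      n_t = nrow(pairs),
      n_mc = dplyr::n_distinct(pairs$control_id),
      n_cp = nrow(controls),
      n_dropped = n_dropped
    ),
    class = "matched_sample"
  )
}

#' @export
print.matched_sample <- function(x, ...) {
  cat("<matched_sample> ", nrow(x$pairs), " pairs (", x$metric, "); n_t=",
      x$n_t, ", n_mc=", x$n_mc, ", n_cp=", x$n_cp, "\n", sep = "")
  invisible(x)
}

#' Raw average treatment effect on the treated
#'
#' Mean over matched pairs of the per-pair effect
#' `tt_i = y_treated - y_control`. Negative values mean the treatment reduced
#' the probability of forest loss.
#'
#' @param m A [match_nearest_neighbor()] result.
#' @return A single number in `[-1, 1]` for binary outcomes.
#' @export
raw_att <- function(m) {
  abort_if(!inherits(m, "matched_sample"), "m must be a matched_sample")
  abort_if(nrow(m$pairs) == 0, "matched sample has no pairs")
  mean(m$pairs$tt)
}

# regression-adjusted per-pair effects: fit the outcome on the adjustment
# covariates among the matched controls, subtract the model-implied gap
# mu(x_treated) - mu(x_control) from each tt_i
bias_adjust_tt <- function(m, adjustment_covariates = m$covariates) {
  n <- nrow(m$pairs)
  abort_if(n < length(adjustment_covariates) + 2,
           "too few pairs for bias adjustment")
  Xc <- m$matched_controls[, adjustment_covariates, drop = FALSE]
  Xt <- m$treated[, adjustment_covariates, drop = FALSE]
  df <- cbind(y = m$matched_controls$y_loss, Xc)
  fit <- stats::lm(y ~ ., data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    dropped <- names(beta)[is.na(beta)]
    warning("collinear adjustment column(s) dropped: ",
            paste(dropped, collapse = ", "))
    beta[is.na(beta)] <- 0
  }
  gap <- as.matrix(Xt - Xc) %*% beta[colnames(Xc)]
  out <- m$pairs$tt - as.numeric(gap)
  # residual control-outcome variance: the conditional variance relevant to
  # the adjusted estimate's reuse inflation
  attr(out, "sigma2_resid") <- sum(stats::residuals(fit)^2) /
    max(stats::df.residual(fit), 1)
  out
}

#' Bias-adjusted ATT
#'
#' Regression-style post-matching bias correction: a linear model of the
#' outcome on the adjustment covariates is fit among the matched controls and
#' the model-implied covariate gap between each treated unit and its control
#' is subtracted from the pair effect.
#'
#' @param m A [match_nearest_neighbor()] result.
#' @param adjustment_covariates Covariates of the correction model; defaults
#'   to the matching covariates.
#' @return The adjusted ATT (a single number).
#' @export
bias_adjust <- function(m, adjustment_covariates = m$covariates) {
  mean(bias_adjust_tt(m, adjustment_covariates))
}

#' Matched-sample standard error and confidence intervals for the ATT
#'
#' `mode = "plain"`: the matched-pair variance of the pair effects inflated
#' for control reuse,
#' \deqn{se^2 = \frac{\sum_i (tt_i - ATT)^2}{n(n-1)} +
#'   \frac{\sum_j K_j (K_j - 1)\,\hat\sigma^2_c}{n^2},}
#' which reduces to the classical `sd(tt)/sqrt(n)` when no control is reused.
#' `mode = "hc"` (heteroscedasticity-corrected): per-unit conditional
#' variances estimated from each unit's nearest same-group neighbour in the
#' matching space, combined with the reuse weights,
#' \deqn{se^2 = \big[\sum_{i \in T} \hat\sigma^2_i +
#'   \sum_{j \in C} K_j^2 \hat\sigma^2_j\big] / n^2.}
#'
#' @param m A [match_nearest_neighbor()] result.
#' @param mode `"plain"` or `"hc"`.
#' @param tt Optional replacement pair effects (e.g. bias-adjusted) used for
#'   the point estimate and, in plain mode, the pair variance.
#' @param sigma2_c Optional control-outcome variance for the reuse-inflation
#'   term of plain mode; defaults to the marginal variance of the distinct
#'   matched-control outcomes. Bias-adjusted effects pass the residual
#'   variance of the adjustment regression instead.
#' @return A list: `se`, and `ci` — tibble with 90/95/99% bounds.
#' @export
att_variance <- function(m, mode = c("plain", "hc"), tt = m$pairs$tt,
                         sigma2_c = NULL) {
  mode <- match.arg(mode)
  n <- length(tt)
  abort_if(n < 2, "standard error undefined for a single pair")
  att <- mean(tt)
  K <- m$weights$K

  if (mode == "plain") {
    if (is.null(sigma2_c)) {
      sigma2_c <- stats::var(m$matched_controls$y_loss[!duplicated(m$pairs$control_id)])
    }
    if (is.na(sigma2_c)) sigma2_c <- 0
    se2 <- sum((tt - att)^2) / (n * (n - 1)) + sum(K * (K - 1)) * sigma2_c / n^2
  } else {
    sig_t <- nn_conditional_var(m$treated, m$match_cols)
    ctrl_idx <- !duplicated(m$pairs$control_id)
    distinct_ctrl <- m$matched_controls[ctrl_idx, , drop = FALSE]
    sig_c <- nn_conditional_var(distinct_ctrl, m$match_cols, pool = m$controls)
    Kmap <- m$weights$K[match(m$pairs$control_id[ctrl_idx], m$weights$control_id)]
    se2 <- (sum(sig_t) + sum(Kmap^2 * sig_c)) / n^2
  }
  se <- sqrt(se2)
  levels <- c(0.90, 0.95, 0.99)
  z <- stats::qnorm(1 - (1 - levels) / 2)
  list(
    se = se,
    ci = tibble::tibble(level = levels, lower = att - z * se, upper = att + z * se)
  )
}

# sigma_i^2 = (y_i - y_nn(i))^2 / 2 from the nearest same-group neighbour in
# standardized covariate space
nn_conditional_var <- function(units, match_cols, pool = units) {
  if (nrow(pool) < 2) return(rep(0, nrow(units)))
  X <- as.matrix(pool[, match_cols, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  Z <- sweep(X, 2, sds, "/")
  Zu <- sweep(as.matrix(units[, match_cols, drop = FALSE]), 2, sds, "/")
  self <- match(units$pixel_id, pool$pixel_id)
  pn2 <- rowSums(Z^2)
  out <- numeric(nrow(units))
  chunk <- max(1L, floor(2e7 / nrow(pool)))
  for (start in seq(1L, nrow(units), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(units))
    D2 <- outer(rowSums(Zu[ii, , drop = FALSE]^2), pn2, `+`) -
      2 * Zu[ii, , drop = FALSE] %*% t(Z)
    sf <- self[ii]
    has_self <- !is.na(sf)
    D2[cbind(which(has_self), sf[has_self])] <- Inf
    nn <- max.col(-D2, ties.method = "first")
    out[ii] <- (units$y_loss[ii] - pool$y_loss[nn])^2 / 2
  }
  out
}
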