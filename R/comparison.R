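#' Balance-driven choice of matching estimator
#'
#' Runs nearest-neighbour matching under each candidate metric, computes
#' post-match covariate balance, and keeps the metric that minimizes the
#' maximum absolute normalized difference (ties: smallest mean absolute
#' normalized difference, then the first declared candidate). Candidates
#' whose matching is infeasible are skipped; if none is feasible the result
#' marks the comparison `NA` with a reason, mirroring how very unbalanced or
#' tiny samples are reported.
#'
#' @param treated,controls Arm tibbles (post trimming).
#' @param covariates Matching covariate names.
#' @param metrics Candidate metrics, tried in order.
#' @param threshold Imbalance flag threshold for the returned balance table.
#' @param ... Passed to [match_nearest_neighbor()].
#' @return A list: `metric` (label or `NA`), `matched` (the winning
#'   `matched_sample` or `NULL`), `balance` (its post-match balance table),
#'   `candidates` (tibble: metric, max_abs_nd, mean_abs_nd, feasible),
#'   `reason` (`NA` or why no candidate was usable).
#' @export
select_estimator <- function(treated, controls, covariates,
                             metrics = c("mahalanobis_trimmed", "ps_augmented"),
                             threshold = 0.25, ...) {
  abort_if(length(metrics) < 1, "need at least one candidate metric")
  fits <- list()
  summ <- tibble::tibble(metric = metrics, max_abs_nd = NA_real_,
                         mean_abs_nd = NA_real_, feasible = FALSE)
  for (i in seq_along(metrics)) {
    m <- tryCatch(
      suppressWarnings(match_nearest_neighbor(treated, controls, covariates,
                                              metric = metrics[i], ...)),
      error = function(e) NULL
    )
    if (is.null(m)) next
    bal <- balance_table(covariates = covariates, matched = m, threshold = threshold)
    fits[[metrics[i]]] <- list(matched = m, balance = bal)
    summ$max_abs_nd[i] <- max(abs(bal$normalized_difference))
    summ$mean_abs_nd[i] <- mean(abs(bal$normalized_difference))
    summ$feasible[i] <- TRUE
  }
  if (!any(summ$feasible)) {
    return(list(metric = NA_character_, matched = NULL, balance = NULL,
                candidates = summ, reason = "NA: no feasible matching candidate"))
  }
  ok <- which(summ$feasible)
  best <- ok[order(summ$max_abs_nd[ok], summ$mean_abs_nd[ok], ok)][1]
  list(metric = metrics[best],
       matched = fits[[metrics[best]]]$matched,
       balance = fits[[metrics[best]]]$balance,
       candidates = summ,
       reason = NA_character_)
}

# assemble an att_estimate object from a matched sample
build_att_estimate <- function(m, label, biome, variance_mode = "plain",
                               adjustment_covariates = m$covariates,
                               balance = NULL, metric = m$metric) {
  raw <- raw_att(m)
  tt_adj <- bias_adjust_tt(m, adjustment_covariates)
  adj <- mean(tt_adj)
  v_raw <- att_variance(m, mode = variance_mode)
  v_adj <- att_variance(m, mode = variance_mode, tt = as.numeric(tt_adj),
                        sigma2_c = attr(tt_adj, "sigma2_resid"))
  structure(
    list(
      label = label, biome = biome, feasible = TRUE, reason = NA_character_,
      mean_treated = mean(m$treated$y_loss),
      mean_control = mean(m$matched_controls$y_loss),
      raw_att = raw, bias_adjusted_att = adj,
      se_raw = v_raw$se, se = v_adj$se,
      ci_raw = v_raw$ci, ci = v_adj$ci,
      variance_mode = variance_mode, metric = metric,
      n_t = m$n_t, n_mc = m$n_mc, n_cp = m$n_cp,
      balance = balance, matched = m
    ),
    class = "att_estimate"
  )
}

na_att_estimate <- function(label, biome, reason, n_t = NA_integer_,
                            n_cp = NA_integer_) {
  structure(
    list(label = label, biome = biome, feasible = FALSE, reason = reason,
         mean_treated = NA_real_, mean_control = NA_real_,
         raw_att = NA_real_, bias_adjusted_att = NA_real_,
         se_raw = NA_real_, se = NA_real_, ci_raw = NULL, ci = NULL,
         variance_mode = NA_character_, metric = NA_character_,
         n_t = n_t, n_mc = NA_integer_, n_cp = n_cp,
         balance = NULL, matched = NULL),
    class = "att_estimate"
  )
}

#' @export
print.att_estimate <- function(x, digits = 3, ...) {
  cat("<att_estimate> ", x$label,
      if (!is.na(x$biome)) paste0(" [", x$biome, "]"), "\n", sep = "")
  if (!x$feasible) {
    cat("  ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  ci95 <- x$ci[x$ci$level == 0.95, ]
  cat("  raw ATT ", round(x$raw_att, digits),
      "; bias-adjusted ATT ", round(x$bias_adjusted_att, digits),
      " (se ", round(x$se, digits), ", 95% CI [",
      round(ci95$lower, digits), "; ", round(ci95$upper, digits), "])\n",
      "  n_t=", x$n_t, ", n_mc=", x$n_mc, ", n_cp=", x$n_cp,
      "; ", x$metric, ", ", x$variance_mode, " variance\n", sep = "")
  invisible(x)
}

#' @export
tidy.att_estimate <- function(x, ...) {
  if (!x$feasible) {
    return(tibble::tibble(label = x$label, biome = x$biome,
                          term = c("raw_att", "bias_adjusted_att"),
                          estimate = NA_real_, std_error = NA_real_,
                          conf_low_95 = NA_real_, conf_high_95 = NA_real_,
                          reason = x$reason))
  }
  ci95a <- x$ci[x$ci$level == 0.95, ]
  ci95r <- x$ci_raw[x$ci_raw$level == 0.95, ]
  tibble::tibble(
    label = x$label, biome = x$biome,
    term = c("raw_att", "bias_adjusted_att"),
    estimate = c(x$raw_att, x$bias_adjusted_att),
    std_error = c(x$se_raw, x$se),
    conf_low_95 = c(ci95r$lower, ci95a$lower),
    conf_high_95 = c(ci95r$upper, ci95a$upper),
    reason = NA_character_
  )
}

#' @export
glance.att_estimate <- function(x, ...) {
  tibble::tibble(
    label = x$label, biome = x$biome, feasible = x$feasible,
    mean_treated = x$mean_treated, mean_control = x$mean_control,
    raw_att = x$raw_att, bias_adjusted_att = x$bias_adjusted_att,
    se = x$se, n_t = x$n_t, n_mc = x$n_mc, n_cp = x$n_cp,
    metric = x$metric, variance_mode = x$variance_mode, reason = x$reason
  )
}

# treated/control arm definitions for the four comparison designs
comparison_arms <- function(data, spillover_pool, question, biome,
                            tenure = NULL, tenure_treated = NULL,
                            tenure_control = NULL,
                            protection_stratum = c("protected", "unprotected")) {
  protection_stratum <- match.arg(protection_stratum)
  d <- dplyr::filter(data, .data$biome == !!biome)
  pick <- function(x, cls, ten = NULL) {
    out <- dplyr::filter(x, .data$protection_class == cls)
    if (!is.null(ten)) out <- dplyr::filter(out, .data$tenure == ten)
    out
  }
  switch(question,
    A = list(treated = pick(d, "protected"),
             controls = pick(d, "fully_unprotected")),
    B = {
      abort_if(is.null(tenure), "question B needs a tenure")
      list(treated = pick(d, "protected", tenure),
           controls = pick(d, "fully_unprotected", tenure))
    },
    C = {
      abort_if(is.null(tenure_treated) || is.null(tenure_control),
               "question C needs tenure_treated and tenure_control")
      cls <- if (protection_stratum == "protected") "protected" else "fully_unprotected"
      list(treated = pick(d, cls, tenure_treated),
           controls = pick(d, cls, tenure_control))
    },
    spillover = {
      sp <- dplyr::filter(spillover_pool, .data$biome == !!biome)
      if (!is.null(tenure)) sp <- dplyr::filter(sp, .data$tenure == tenure)
      list(treated = sp, controls = pick(d, "fully_unprotected", tenure))
    },
    stop("unknown question: ", question, call. = FALSE)
  )
}

#' Run one matched comparison end to end
#'
#' Orchestrates a full comparison on an estimation sample: arm definition,
#' propensity fit, common-support trimming, balance-driven estimator
#' selection across the candidate metrics, raw and bias-adjusted ATT with
#' matched-sample variance. The four designs are:
#' * `question = "A"` — protected vs fully unprotected pixels, any tenure;
#' * `question = "B"` — protected vs fully unprotected within one `tenure`
#'   (controls come from properties not intersecting a protected area, and
#'   never from the treated unit's property);
#' * `question = "C"` — one tenure vs another within a protection stratum
#'   (`tenure_treated` vs `tenure_control`, `protection_stratum`);
#' * `question = "spillover"` — unprotected parts of protected properties
#'   (the `spillover_pool` of [apply_exclusions()]) vs fully unprotected
#'   properties of the same tenure.
#'
#' All comparisons run within a single forest `biome`. Infeasible designs
#' (empty arm, propensity failure, no balanced candidate) yield an `NA`
#' estimate with a reason instead of an error.
#'
#' @param data Estimation sample (main pool after exclusions).
#' @param question One of `"A"`, `"B"`, `"C"`, `"spillover"`.
#' @param biome Forest biome the comparison is restricted to.
#' @param covariates Matching covariates; default all biophysical covariates
#'   present from [default_covariate_fields()].
#' @param tenure,tenure_treated,tenure_control,protection_stratum See designs.
#' @param spillover_pool Tibble of pixels in unprotected parts of protected
#'   properties (required for `question = "spillover"`).
#' @param metrics Candidate matching metrics for [select_estimator()].
#' @param caliper_sd Propensity caliper for [trim_common_support()].
#' @param variance_mode `"plain"` or `"hc"`.
#' @param min_treated,min_controls Feasibility floors; smaller arms return an
#'   `NA` estimate ("very small treated pool" / "very small control pool").
#' @return An `att_estimate` object (see [tidy()] / [glance()] methods).
#' @export
run_comparison <- function(data, question, biome,
                           covariates = intersect(names(default_covariate_fields()),
                                                  names(data)),
                           tenure = NULL, tenure_treated = NULL,
                           tenure_control = NULL,
                           protection_stratum = "protected",
                           spillover_pool = NULL,
                           metrics = c("mahalanobis_trimmed", "ps_augmented"),
                           caliper_sd = 0.25, variance_mode = "plain",
                           min_treated = 10L, min_controls = 10L) {
  label <- paste0("question ", question,
                  if (!is.null(tenure)) paste0(", ", tenure),
                  if (!is.null(tenure_treated))
                    paste0(", ", tenure_treated, " vs ", tenure_control,
                           " (", protection_stratum, ")"))
  if (question == "spillover") {
    abort_if(is.null(spillover_pool), "spillover comparisons need a spillover_pool")
  }
  arms <- comparison_arms(data, spillover_pool, question, biome,
                          tenure = tenure, tenure_treated = tenure_treated,
                          tenure_control = tenure_control,
                          protection_stratum = protection_stratum)
  if (nrow(arms$treated) < min_treated) {
    return(na_att_estimate(label, biome, "NA: very small treated pool",
                           n_t = nrow(arms$treated), n_cp = nrow(arms$controls)))
  }
  if (nrow(arms$controls) < min_controls) {
    return(na_att_estimate(label, biome, "NA: very small control pool",
                           n_t = nrow(arms$treated), n_cp = nrow(arms$controls)))
  }

  pooled <- dplyr::bind_rows(
    dplyr::mutate(arms$treated, arm_treated = 1L),
    dplyr::mutate(arms$controls, arm_treated = 0L)
  )
  fit <- tryCatch(fit_propensity(pooled, "arm_treated", covariates),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(na_att_estimate(label, biome,
                           paste0("NA: propensity model failed (",
                                  conditionMessage(fit), ")"),
                           n_t = nrow(arms$treated), n_cp = nrow(arms$controls)))
  }
  trimmed <- tryCatch(trim_common_support(pooled, fit, caliper_sd = caliper_sd),
                      error = function(e) e)
  if (inherits(trimmed, "error")) {
    return(na_att_estimate(label, biome, "NA: no common support",
                           n_t = 0L, n_cp = nrow(arms$controls)))
  }
  on <- trimmed$sample
  sel <- select_estimator(dplyr::filter(on, .data$arm_treated == 1L),
                          dplyr::filter(on, .data$arm_treated == 0L),
                          covariates, metrics = metrics,
                          same_biome = FALSE, different_property = TRUE)
  if (is.na(sel$metric)) {
    return(na_att_estimate(label, biome, sel$reason,
                           n_t = trimmed$n_t, n_cp = nrow(arms$controls)))
  }
  if (all(sel$balance$flag == "imbalanced")) {
    return(na_att_estimate(label, biome, "NA: very unbalanced covariate distributions",
                           n_t = trimmed$n_t, n_cp = nrow(arms$controls)))
  }
  build_att_estimate(sel$matched, label, biome, variance_mode = variance_mode,
                     balance = sel$balance)
}
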