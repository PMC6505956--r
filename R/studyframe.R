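#' Classify a pixel as forest
#'
#' A pixel counts as forest when its percent tree cover strictly exceeds the
#' cutoff (10% under the national forest definition used as default; 25% is
#' the usual sensitivity cutoff).
#'
#' @param tree_cover_pct Percent tree cover in 2000, in `[0, 100]`.
#' @param cutoff Percent cutoff; forest requires cover strictly greater.
#' @return Logical vector.
#' @export
#' @examples
#' define_forest(c(10, 10.1, 26), cutoff = 10)
define_forest <- function(tree_cover_pct, cutoff = 10) {
  abort_if(any(tree_cover_pct < 0 | tree_cover_pct > 100, na.rm = TRUE),
           "tree_cover_pct must lie in [0, 100]")
  tree_cover_pct > cutoff
}

#' Code the binary forest-loss outcome
#'
#' A pixel forested in 2000 and cleared by 2014 scores 1; forested and intact
#' scores 0; pixels not forested in 2000 are excluded (`NA`).
#'
#' @param forested_2000 Logical: forest in 2000.
#' @param cleared_2000_2014 Logical: cover loss during the study window.
#' @return Integer vector with values 1, 0, or `NA` (excluded).
#' @export
#' @examples
#' code_outcome(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE))
code_outcome <- function(forested_2000, cleared_2000_2014) {
  ifelse(forested_2000, as.integer(cleared_2000_2014), NA_integer_)
}

#' Draw a spaced random sample of forested pixels
#'
#' Uniformly samples a fraction of the forested pixels, then enforces a
#' minimum spacing by greedy thinning in seeded random order: pixels within
#' `min_spacing_m` of an already retained pixel (Chebyshev distance on the
#' 30 m grid, so 30 m means the 8-neighbourhood) are dropped. This breaks
#' short-range spatial dependence between observations.
#'
#' @param data Pixel tibble with `row`, `col` and `forest_cover_pct` columns
#'   (or a logical `forested` column).
#' @param fraction Sampling fraction in `(0, 1]`.
#' @param min_spacing_m Minimum spacing in metres (0 disables thinning).
#' @param cutoff Forest-definition cutoff passed to [define_forest()] when a
#'   `forested` column is absent.
#' @param pixel_size_m Grid resolution (metres).
#' @param seed Integer seed; sampling and thinning are deterministic given it.
#' @return A list: `sample` (tibble of retained pixels) and `log` (tibble
#'   with per-step removal counts: not forested, not sampled, spacing).
#' @export
draw_sample <- function(data, fraction = 0.01, min_spacing_m = 30,
                        cutoff = 10, pixel_size_m = 30, seed = 1L) {
  abort_if(fraction <= 0 || fraction > 1, "fraction must lie in (0, 1]")
  require_columns(data, c("pixel_id", "row", "col"))
  if (!"forested" %in% names(data)) {
    require_columns(data, "forest_cover_pct")
    data <- dplyr::mutate(data, forested = define_forest(.data$forest_cover_pct, cutoff))
  }
  n_in <- nrow(data)
  forest <- dplyr::filter(data, .data$forested)
  abort_if(nrow(forest) == 0, "no forested pixels to sample from")

  set.seed(seed)
  keep <- stats::runif(nrow(forest)) < fraction
  if (fraction == 1) keep <- rep(TRUE, nrow(forest))
  sampled <- forest[keep, , drop = FALSE]
  n_sampled <- nrow(sampled)

  # greedy spacing in random order on a Chebyshev grid
  spacing_px <- if (min_spacing_m <= 0) 0L else ceiling(min_spacing_m / pixel_size_m)
  if (spacing_px > 0 && n_sampled > 1) {
    ord <- sample.int(n_sampled)
    cell <- spacing_px + 1L  # coarse hash cells so only neighbours are checked
    taken_r <- integer(0); taken_c <- integer(0)
    occupied <- new.env(hash = TRUE, parent = emptyenv())
    sel <- logical(n_sampled)
    for (i in ord) {
      r <- sampled$row[i]; cc <- sampled$col[i]
      br <- r %/% cell; bc <- cc %/% cell
      ok <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        key <- paste(br + dr, bc + dc, sep = ",")
        idx <- occupied[[key]]
        if (!is.null(idx) &&
            any(pmax(abs(taken_r[idx] - r), abs(taken_c[idx] - cc)) <= spacing_px)) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        taken_r <- c(taken_r, r); taken_c <- c(taken_c, cc)
        j <- length(taken_r)
        key <- paste(br, bc, sep = ",")
        occupied[[key]] <- c(occupied[[key]], j)
        sel[i] <- TRUE
      }
    }
    sampled <- sampled[sel, , drop = FALSE]
  }
  sampled <- dplyr::arrange(sampled, .data$pixel_id)

  log <- tibble::tibble(
    rule = c("not_forested", "not_sampled", "spacing"),
    n_removed = c(n_in - nrow(forest), nrow(forest) - n_sampled,
                  n_sampled - nrow(sampled))
  )
  list(sample = sampled, log = log)
}

#' Apply the study exclusion rules
#'
#' Filters a sampled pixel table with the study's exclusion rules, in the
#' declared order, keeping a reconciling log. The rule
#' `"spillover_pool"` does not discard pixels: pixels in the unprotected
#' parts of protected properties are routed to a separate pool, used later as
#' the treated group of the spillover analysis.
#'
#' Known rules: `urban`, `water`, `mangrove`, `post2000_pa`, `comunidad`,
#' `named_property`, `spillover_pool`.
#'
#' @param data Pixel tibble.
#' @param rules Character vector of rule names, applied in order.
#' @param excluded_properties Property ids (or names, if the table has a
#'   `property_name` column) removed by the `named_property` rule.
#' @return A list: `sample` (main estimation sample), `spillover_pool`
#'   (tibble, possibly empty), and `log` (tibble: rule, n_removed).
#' @export
apply_exclusions <- function(data,
                             rules = c("urban", "water", "mangrove",
                                       "comunidad", "named_property",
                                       "spillover_pool"),
                             excluded_properties = NULL) {
  known <- c("urban", "water", "mangrove", "post2000_pa", "comunidad",
             "named_property", "spillover_pool")
  bad <- setdiff(rules, known)
  abort_if(length(bad) > 0,
           paste0("unknown exclusion rule(s): ", paste(bad, collapse = ", ")))

  spillover_pool <- data[0, , drop = FALSE]
  counts <- integer(length(rules))
  for (k in seq_along(rules)) {
    rule <- rules[k]
    drop <- switch(rule,
      urban = if ("is_urban" %in% names(data)) data$is_urban else rep(FALSE, nrow(data)),
      water = if ("is_water" %in% names(data)) data$is_water else rep(FALSE, nrow(data)),
      mangrove = data$biome == "mangrove",
      post2000_pa = if ("pa_year" %in% names(data)) {
        !is.na(data$pa_year) & data$pa_year > 2000
      } else rep(FALSE, nrow(data)),
      comunidad = data$tenure == "comunidad",
      named_property = {
        key <- if ("property_name" %in% names(data)) data$property_name else data$property_id
        key %in% excluded_properties
      },
      spillover_pool = data$protection_class == "unprotected_part_of_protected_property"
    )
    drop[is.na(drop)] <- FALSE
    counts[k] <- sum(drop)
    if (rule == "spillover_pool") {
      spillover_pool <- data[drop, , drop = FALSE]
    }
    data <- data[!drop, , drop = FALSE]
  }
  list(
    sample = data,
    spillover_pool = spillover_pool,
    log = tibble::tibble(rule = rules, n_removed = counts)
  )
}

#' Build the estimation sample from a raw pixel table
#'
#' Convenience wrapper chaining the forest definition, outcome coding,
#' spaced random sampling and exclusion rules; the usual entry into the
#' matching pipeline.
#'
#' @inheritParams draw_sample
#' @inheritParams apply_exclusions
#' @return A list: `sample`, `spillover_pool`, `log` (combined sampling and
#'   exclusion log).
#' @export
build_frame <- function(data, fraction = 0.01, min_spacing_m = 30, cutoff = 10,
                        rules = c("urban", "water", "mangrove", "comunidad",
                                  "named_property", "spillover_pool"),
                        excluded_properties = NULL, seed = 1L) {
  drawn <- draw_sample(data, fraction = fraction, min_spacing_m = min_spacing_m,
                       cutoff = cutoff, seed = seed)
  excl <- apply_exclusions(drawn$sample, rules = rules,
                           excluded_properties = excluded_properties)
  list(
    sample = excl$sample,
    spillover_pool = excl$spillover_pool,
    log = dplyr::bind_rows(drawn$log, excl$log)
  )
}
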