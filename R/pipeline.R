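#' Read a pixel table
#'
#' Typed CSV reader for the pixel-record schema; unknown columns are kept,
#' missing required columns raise a schema error with the file name.
#'
#' @param path CSV file path.
#' @return A tibble of pixel records.
#' @export
read_pixel_table <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  abort_if(nrow(out) == 0, paste0("schema error: ", path, " has no rows"))
  require_columns(out, c("pixel_id", "row", "col", "biome", "tenure",
                         "property_id", "protection_class", "y_loss"),
                  paste0("pixel table (", basename(path), ")"))
  out
}

#' Write a pixel table (or any artifact tibble) as CSV
#'
#' @param data Tibble.
#' @param path Output CSV path; directories are created as needed.
#' @return `path`, invisibly.
#' @export
write_pixel_table <- function(data, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' Loads a YAML pipeline configuration and fills defaults. A configuration
#' has (all optional): `pixel_table` (CSV path; if absent a synthetic
#' landscape is generated from `landscape`), `landscape` (arguments for
#' [landscape_config()]), `frame` (`fraction`, `min_spacing_m`, `cutoff`,
#' `excluded_properties`), `comparisons` (list of [run_comparison()]
#' argument sets), `covariates`, `matching` (`metrics`, `caliper_sd`,
#' `variance_mode`), `plm` (`enabled`, `bandwidth`, `B`), `extrapolation`
#' (`mode`, `pixel_area_ha`, `scale`), and `seed`.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  abort_if(!is.list(cfg), "config must be a YAML mapping or a list")
  defaults <- list(
    pixel_table = NULL,
    landscape = list(),
    frame = list(fraction = 0.01, min_spacing_m = 30, cutoff = 10,
                 excluded_properties = NULL),
    covariates = NULL,
    comparisons = list(list(question = "A", biome = "dry"),
                       list(question = "A", biome = "moist")),
    matching = list(metrics = c("mahalanobis_trimmed", "ps_augmented"),
                    caliper_sd = 0.25, variance_mode = "plain"),
    plm = list(enabled = FALSE, bandwidth = NULL, B = 50),
    extrapolation = list(mode = "standard", pixel_area_ha = 0.09, scale = 100),
    seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && nm != "comparisons") {
      miss <- setdiff(names(defaults[[nm]]), names(cfg[[nm]]))
      cfg[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  abort_if(!(cfg$frame$cutoff > 0 && cfg$frame$cutoff < 100),
           "forest cutoff must be a percent in (0, 100)")
  structure(cfg, class = "run_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- paste0("[", stage, "] ", msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full evaluation pipeline
#'
#' Executes sampling frame construction, propensity estimation, trimming,
#' balance-driven matching, ATT estimation, optional effect-heterogeneity
#' PLMs, and avoided-deforestation extrapolation for every configured
#' comparison, writing every intermediate table to `out_dir` along with a
#' manifest (config echo, seeds, stage counts) that makes the run
#' reproducible. Inputs come from `config$pixel_table` (CSV) or, when
#' absent, from a synthetic landscape generated with `config$landscape`.
#'
#' @param config A [read_run_config()] result, YAML path, or list.
#' @param out_dir Output directory for artifacts.
#' @return Invisibly, a list: `estimates` (list of `att_estimate`),
#'   `summary` (tibble of [glance()] rows), `impact` (extrapolation tibble),
#'   `frame` (the estimation sample), `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)

  # stage: input
  if (!is.null(config$pixel_table)) {
    pixels <- read_pixel_table(config$pixel_table)
    pipeline_log(logf, "input", paste0("read ", nrow(pixels), " pixels from ",
                                       config$pixel_table))
  } else {
    ls_args <- config$landscape
    ls_args$seed <- ls_args$seed %||% config$seed
    if (!is.null(ls_args$tenure_shares)) {
      ls_args$tenure_shares <- unlist(ls_args$tenure_shares)
    }
    land <- generate_landscape(do.call(landscape_config, ls_args))
    pixels <- land$pixels
    write_pixel_table(land$properties, file.path(out_dir, "properties.csv"))
    pipeline_log(logf, "simulate", paste0("generated ", nrow(pixels), " pixels"))
  }
  write_pixel_table(pixels, file.path(out_dir, "pixels.csv"))

  # stage: frame
  frame <- build_frame(pixels,
                       fraction = config$frame$fraction,
                       min_spacing_m = config$frame$min_spacing_m,
                       cutoff = config$frame$cutoff,
                       excluded_properties = config$frame$excluded_properties,
                       seed = config$seed)
  write_pixel_table(frame$sample, file.path(out_dir, "sample.csv"))
  write_pixel_table(frame$spillover_pool, file.path(out_dir, "spillover_pool.csv"))
  write_pixel_table(frame$log, file.path(out_dir, "exclusion_log.csv"))
  pipeline_log(logf, "frame", paste0(nrow(frame$sample), " in main sample, ",
                                     nrow(frame$spillover_pool), " in spillover pool"))

  covariates <- config$covariates %||%
    intersect(names(default_covariate_fields()), names(frame$sample))

  # stage: comparisons
  estimates <- list()
  impact_rows <- list()
  plm_fits <- list()
  for (i in seq_along(config$comparisons)) {
    cmp <- config$comparisons[[i]]
    est <- run_comparison(
      frame$sample,
      question = cmp$question, biome = cmp$biome,
      covariates = covariates,
      tenure = cmp$tenure, tenure_treated = cmp$tenure_treated,
      tenure_control = cmp$tenure_control,
      protection_stratum = cmp$protection_stratum %||% "protected",
      spillover_pool = frame$spillover_pool,
      metrics = config$matching$metrics,
      caliper_sd = config$matching$caliper_sd,
      variance_mode = config$matching$variance_mode
    )
    key <- sprintf("comparison_%02d", i)
    estimates[[key]] <- est
    pipeline_log(logf, "match", paste0(
      key, " (", est$label, ", ", est$biome, "): ",
      if (est$feasible) {
        paste0("ATT ", signif(est$bias_adjusted_att, 3), " via ", est$metric,
               " [n_t=", est$n_t, ", n_mc=", est$n_mc, ", n_cp=", est$n_cp, "]")
      } else est$reason
    ))
    if (est$feasible) {
      write_pixel_table(est$matched$pairs,
                        file.path(out_dir, paste0(key, "_pairs.csv")))
      write_pixel_table(est$balance,
                        file.path(out_dir, paste0(key, "_balance.csv")))
      if (isTRUE(config$plm$enabled)) {
        pe <- pair_effects(est$matched)
        plm_cov <- setdiff(covariates, "biomass_tc_ha")
        fit <- tryCatch({
          f <- fit_plm(pe, plm_cov, z = "biomass_tc_ha",
                       bandwidth = config$plm$bandwidth)
          wild_bootstrap_bands(f, B = config$plm$B, seed = config$seed + i)
        }, error = function(e) NULL)
        if (!is.null(fit)) {
          plm_fits[[key]] <- fit
          write_pixel_table(fit$bands,
                            file.path(out_dir, paste0(key, "_plm_curve.csv")))
          pipeline_log(logf, "plm", paste0(key, ": bandwidth ",
                                           signif(fit$bandwidth, 3)))
        } else {
          pipeline_log(logf, "plm", paste0(key, ": skipped (degenerate fit)"))
        }
      }
    }
    impact_rows[[key]] <- extrapolate_impact(
      est, pixel_area_ha = config$extrapolation$pixel_area_ha,
      scale = config$extrapolation$scale, mode = config$extrapolation$mode
    )
  }

  summary_tbl <- dplyr::bind_rows(purrr::map(estimates, glance))
  impact_tbl <- dplyr::bind_rows(impact_rows)
  write_pixel_table(summary_tbl, file.path(out_dir, "att_summary.csv"))
  write_pixel_table(impact_tbl, file.path(out_dir, "impact.csv"))
  write_pixel_table(descriptive_stats(frame$sample),
                    file.path(out_dir, "descriptives.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("forestatt")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      pixels = nrow(pixels),
      sample = nrow(frame$sample),
      spillover_pool = nrow(frame$spillover_pool),
      excluded = sum(frame$log$n_removed) - nrow(frame$spillover_pool)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  pipeline_log(logf, "done", paste0("artifacts in ", out_dir))

  invisible(list(estimates = estimates, summary = summary_tbl,
                 impact = impact_tbl, plm = plm_fits, frame = frame,
                 manifest = manifest))
}
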