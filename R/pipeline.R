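#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. All
#' randomness flows from the single `seed`: each stage k derives its own
#' stream as `(seed mod 1e6) * 1000 + k`, so stages can be rerun in
#' isolation reproducibly. The configuration round-trips losslessly through
#' JSON via [config_to_json()] / [config_from_json()].
#'
#' @param grid_size Grid rows = cols (default 50).
#' @param x_origin,y_origin,cell_size Grid geometry (defaults give a 10-degree
#'   square near the equator at `grid_size` 50).
#' @param n_clusters,n_waves Survey size (defaults 300 clusters, 3 waves).
#' @param n_zones Admin zones (default 9).
#' @param population_total National population (default 1e6). Required when
#'   the coverage stage is enabled.
#' @param candidates Candidate covariate names for selection.
#' @param holdout_fraction Holdout fraction (default 0.10).
#' @param level Credible level for prediction surfaces (default 0.95).
#' @param un_p Uniform national under-five proportion comparator (default
#'   0.175).
#' @param national_coverage Intervention coverage applied uniformly per zone
#'   (default 0.397, a basic-vaccination-scale figure).
#' @param n_starts Optimizer starts per model fit (default 3 in the pipeline).
#' @param compare_menu Fit the full leave-one-out model menu (default TRUE;
#'   FALSE fits only the selected model).
#' @param stages Stages to run (default all).
#' @param seed Root seed.
#' @param out_dir Optional output directory; when set, stage outputs are
#'   written (clusters CSV, rasters and surfaces as ASCII grids, report JSON).
#' @param model Generating `u5_model` (default [default_u5_model()]).
#' @return A `u5_config` list.
#' @export
pipeline_config <- function(grid_size = 50, x_origin = 3, y_origin = 4,
                            cell_size = 0.2, n_clusters = 300, n_waves = 3,
                            n_zones = 9, population_total = 1e6,
                            candidates = c("accessibility", "evi",
                                           "landcover", "nightlights"),
                            holdout_fraction = 0.10, level = 0.95,
                            un_p = 0.175, national_coverage = 0.397,
                            n_starts = 3, compare_menu = TRUE,
                            stages = c("simulate", "select", "fit",
                                       "predict", "validate", "coverage"),
                            seed = 1, out_dir = NULL,
                            model = default_u5_model()) {
  cfg <- list(grid_size = grid_size, x_origin = x_origin,
              y_origin = y_origin, cell_size = cell_size,
              n_clusters = n_clusters, n_waves = n_waves, n_zones = n_zones,
              population_total = population_total, candidates = candidates,
              holdout_fraction = holdout_fraction, level = level,
              un_p = un_p, national_coverage = national_coverage,
              n_starts = n_starts, compare_menu = compare_menu,
              stages = stages, seed = seed, out_dir = out_dir,
              ## beta as a named list so JSON round-trips keep the names
              model = c(list(beta = as.list(model$beta)),
                        unclass(model)[c("sigma2", "kappa", "nugget", "rho",
                                         "nu")]))
  class(cfg) <- "u5_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "u5_config"))
  if ("coverage" %in% cfg$stages &&
      (is.null(cfg$population_total) || is.null(cfg$un_p))) {
    stop("coverage stage enabled but population_total / un_p missing")
  }
  if (is.null(cfg$seed)) stop("seed must be explicit")
  stopifnot(cfg$n_clusters >= 10, cfg$n_waves >= 1, cfg$grid_size >= 2)
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `u5_config`.
#' @export
config_to_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' @rdname pipeline_config
#' @param json JSON string or file path.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$model <- do.call(stgp_model, c(list(beta = unlist(x$model$beta)),
                                   x$model[c("sigma2", "kappa", "nugget",
                                             "rho", "nu")]))
  do.call(pipeline_config, x[setdiff(names(x), character())])
}

stage_seed <- function(root, k) (as.integer(root) %% 1000000L) * 1000L + k

#' Run the end-to-end mapping pipeline
#'
#' Orchestrates the full analysis on synthetic data: simulate covariates,
#' zones, population and a cluster survey; extract covariates at the recorded
#' (displaced) locations; exhaustive best-subset BIC selection; fit the
#' space-time geostatistical model (optionally the whole leave-one-out model
#' menu, compared by DIC); predict the proportion surface for the last wave
#' with credible bounds; validate (holdout metrics, LOO CPO, residual
#' semivariogram with permutation envelopes); and convert to under-five
#' counts for the three denominator methods (MBG, zonal census-style,
#' uniform national proportion), with zonal gap comparisons. Each stage logs
#' its seed and runtime; reruns with the same config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage log messages (default FALSE).
#' @return A `u5_report` list: `config_json`, `clusters`, `truth_summary`,
#'   `selection`, `comparison`, `fit_summary` (tidy table), `glance`,
#'   `surface`, `validation` (metrics, `cpo` summary, `semivariogram`),
#'   `zonal` (per-method tibbles), `gaps` (method differences),
#'   `unprotected`, and a `log` tibble of stage seeds/runtimes.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_config(config)
  t_all <- Sys.time()
  log <- list()
  note <- function(stage, seed, t0) {
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (!quiet) message(sprintf("[%s] seed=%s %.2fs", stage,
                                ifelse(is.na(seed), "-", seed), dt))
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, seed = seed, seconds = round(dt, 3))
  }
  s <- function(k) stage_seed(config$seed, k)
  model <- if (inherits(config$model, "u5_model")) config$model else
    do.call(stgp_model, c(list(beta = unlist(config$model$beta)),
                          config$model[c("sigma2", "kappa", "nugget", "rho",
                                         "nu")]))

  ## -- simulate ------------------------------------------------------------
  t0 <- Sys.time()
  grid <- raster_grid(config$x_origin, config$y_origin, config$cell_size,
                      config$grid_size, config$grid_size)
  stack <- gen_covariate_stack(grid, seed = s(1))
  zones <- gen_zone_raster(grid, n_zones = config$n_zones, seed = s(2))
  pop <- gen_population_raster(grid, seed = s(3),
                               total = config$population_total,
                               stack = stack)
  survey <- simulate_survey(stack, model, n_clusters = config$n_clusters,
                            n_waves = config$n_waves, seed = s(4),
                            zones = zones)
  clusters <- extract_covariates(survey$clusters, stack)
  note("simulate", s(4), t0)

  ## -- select --------------------------------------------------------------
  t0 <- Sys.time()
  selection <- best_subset_bic(clusters, "p_under5", config$candidates)
  selected <- selection$subset[[1]]
  note("select", NA_integer_, t0)

  ## -- fit -----------------------------------------------------------------
  t0 <- Sys.time()
  split <- holdout_split(clusters, fraction = config$holdout_fraction,
                         seed = s(5))
  ## the comparison menu spans the full candidate set (full model plus each
  ## leave-one-out subset); the DIC comparison makes the final call, with
  ## the non-spatial BIC ranking reported alongside
  menu <- if (config$compare_menu) {
    candidate_model_menu(config$candidates)
  } else {
    stats::setNames(list(if (length(selected) >= 1) selected else
      config$candidates), "model_1")
  }
  fits <- lapply(menu, function(cv) {
    stgp_fit(split$train, covariates = cv, n_starts = config$n_starts)
  })
  comparison <- if (length(fits) >= 2) compare_models(fits) else
    tibble::tibble(model = names(fits), dic = fits[[1]]$dic,
                   p_d = fits[[1]]$p_d, loglik = fits[[1]]$loglik,
                   delta_dic = 0, rank = 1L,
                   covariates = paste(fits[[1]]$covariates, collapse = "+"))
  best_fit <- fits[[comparison$model[1]]]
  note("fit", NA_integer_, t0)

  ## -- validate ------------------------------------------------------------
  t0 <- Sys.time()
  metrics <- validate_holdout(best_fit, split$test)
  cpo <- loo_cpo(best_fit)
  semiv <- residual_semivariogram(cpo$loo_z,
                                  best_fit$points[, c("lon", "lat")],
                                  seed = s(6))
  note("validate", s(6), t0)

  ## -- predict -------------------------------------------------------------
  t0 <- Sys.time()
  surface <- predict(best_fit, stack, wave = config$n_waves - 1L,
                     level = config$level)
  note("predict", NA_integer_, t0)

  ## -- coverage ------------------------------------------------------------
  zonal <- gaps <- unprot <- NULL
  if ("coverage" %in% config$stages) {
    t0 <- Sys.time()
    counts_mbg <- under5_surface(surface, pop)
    zonal_mbg <- zonal_aggregate(counts_mbg, zones)
    zonal_un <- zonal_aggregate(uniform_adjustment(pop, config$un_p), zones)
    ## census-style comparator: direct per-zone survey means
    zone_props <- dplyr::summarise(
      dplyr::group_by(clusters, .data$zone_id),
      proportion = mean(.data$p_under5), .groups = "drop")
    all_z <- sort(unique(zones$values[!is.na(zones$values)]))
    missing_z <- setdiff(all_z, zone_props$zone_id)
    if (length(missing_z)) {
      zone_props <- dplyr::bind_rows(
        zone_props, tibble::tibble(zone_id = missing_z,
                                   proportion = mean(clusters$p_under5)))
    }
    zonal_census <- zonal_aggregate(
      census_adjustment(pop, zone_props, zones), zones)
    zonal <- list(mbg = zonal_mbg, census = zonal_census,
                  un_uniform = zonal_un)
    gaps <- compare_methods(zonal)
    covg <- tibble::tibble(zone_id = zonal_mbg$zone_id,
                           coverage = config$national_coverage)
    unprot <- dplyr::bind_rows(
      unprotected_counts(zonal_mbg, covg, "mbg"),
      unprotected_counts(zonal_census, covg, "census"),
      unprotected_counts(zonal_un, covg, "un_uniform"))
    note("coverage", NA_integer_, t0)
  }

  report <- structure(
    list(config_json = as.character(config_to_json(config)),
         clusters = clusters,
         truth_summary = list(n_clipped = survey$truth$n_clipped,
                              seed = survey$truth$seed),
         selection = selection, comparison = comparison,
         fit_summary = tidy(best_fit), glance = glance(best_fit),
         surface = surface,
         validation = list(metrics = metrics,
                           cpo_summary = summary(cpo$cpo),
                           n_flagged = sum(cpo$flagged),
                           semivariogram = tibble::as_tibble(semiv)),
         zonal = zonal, gaps = gaps, unprotected = unprot,
         log = dplyr::bind_rows(log)),
    class = "u5_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_clusters(clusters, file.path(config$out_dir, "clusters.csv"))
    write_raster_ascii(pop, file.path(config$out_dir, "population.asc"))
    write_raster_ascii(zones, file.path(config$out_dir, "zones.asc"))
    write_surface(surface, config$out_dir)
    writeLines(report_to_json(report),
               file.path(config$out_dir, "report.json"))
  }
  if (!quiet) message(sprintf(
    "pipeline done in %.1fs",
    as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
  report
}

#' Serialize a pipeline report to JSON
#'
#' Full-precision (17 significant digits) serialization of the tabular parts
#' of a report; matrices (surfaces) are summarized by national means. Two
#' runs of the same configuration serialize identically.
#'
#' @param report A `u5_report`.
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  surf <- report$surface
  x <- list(
    config = jsonlite::fromJSON(report$config_json),
    truth_summary = report$truth_summary,
    selection = dplyr::select(report$selection, -"subset", -"coefficients"),
    comparison = report$comparison,
    fit_summary = report$fit_summary,
    glance = report$glance,
    surface_summary = list(
      wave = surf$time, level = surf$level, n_clipped = surf$n_clipped,
      mean_of_mean = mean(surf$mean, na.rm = TRUE),
      mean_width = mean(surf$upper - surf$lower, na.rm = TRUE)),
    validation = list(metrics = report$validation$metrics,
                      n_flagged = report$validation$n_flagged,
                      semivariogram = report$validation$semivariogram),
    zonal = report$zonal, gaps = report$gaps,
    unprotected = report$unprotected)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 17,
                                null = "null", na = "null", pretty = TRUE))
}

#' @export
print.u5_report <- function(x, ...) {
  cat("<u5_report>\n")
  sel <- x$selection$subset[[1]]
  cat("  selected covariates:",
      if (length(sel)) paste(sel, collapse = ", ") else "(intercept only)",
      "\n")
  cat(sprintf("  best model: %s (DIC %.2f)\n", x$comparison$model[1],
              x$comparison$dic[1]))
  m <- x$validation$metrics
  cat(sprintf("  holdout: mpe %.5f mae %.5f rmse %.5f r %.3f (n=%d)\n",
              m$mpe, m$mae, m$rmse, m$pearson_r, m$n))
  invisible(x)
}
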