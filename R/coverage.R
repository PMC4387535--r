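#' Under-five count surface from a proportion surface and a population raster
#'
#' Multiplies the predicted proportion surface (mean and credible bounds,
#' cellwise) with a gridded population raster to obtain under-five counts per
#' cell. Nodata in either input propagates.
#'
#' @param prop A `u5_surface` (proportions with bounds).
#' @param pop A `u5_raster` of persons per cell on the same grid.
#' @return An object of class `u5_counts`: `grid` plus matrices `mean`,
#'   `lower`, `upper` (persons per cell).
#' @export
under5_surface <- function(prop, pop) {
  stopifnot(inherits(prop, "u5_surface"), inherits(pop, "u5_raster"))
  if (!grids_identical(prop$grid, pop$grid)) {
    stop("proportion surface and population raster are on different grids")
  }
  structure(list(grid = prop$grid,
                 mean = prop$mean * pop$values,
                 lower = prop$lower * pop$values,
                 upper = prop$upper * pop$values),
            class = "u5_counts")
}

#' @export
print.u5_counts <- function(x, ...) {
  cat(sprintf("<u5_counts> %d x %d, national total %.1f persons\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Uniform national-proportion adjustment
#'
#' The simplest denominator: every cell's population multiplied by one
#' national under-five proportion (default 0.175, the UN medium-scenario
#' national estimate), ignoring subnational variation.
#'
#' @param pop A `u5_raster` of persons per cell.
#' @param p National under-five proportion in \[0, 1\].
#' @return A `u5_raster` of under-five persons per cell.
#' @export
uniform_adjustment <- function(pop, p = 0.175) {
  stopifnot(inherits(pop, "u5_raster"), p >= 0, p <= 1)
  raster_layer(pop$grid, pop$values * p)
}

#' Census-style zonal-proportion adjustment
#'
#' Multiplies each cell's population by the under-five proportion of its
#' admin zone (as census projections would supply per state).
#'
#' @param pop A `u5_raster`.
#' @param zone_props Data frame with `zone_id` and `proportion` columns
#'   covering every zone present in `zones`.
#' @param zones A `u5_raster` of integer zone labels on the same grid.
#' @return A `u5_raster` of under-five persons per cell.
#' @export
census_adjustment <- function(pop, zone_props, zones) {
  stopifnot(inherits(pop, "u5_raster"), inherits(zones, "u5_raster"),
            all(c("zone_id", "proportion") %in% names(zone_props)))
  if (!grids_identical(pop$grid, zones$grid)) stop("grid mismatch")
  zv <- zones$values
  present <- sort(unique(zv[!is.na(zv) & !is.na(pop$values)]))
  missing_z <- setdiff(present, zone_props$zone_id)
  if (length(missing_z)) {
    stop("no proportion supplied for zone(s): ",
         paste(missing_z, collapse = ", "))
  }
  pr <- zone_props$proportion[match(zv, zone_props$zone_id)]
  raster_layer(pop$grid, pop$values * matrix(pr, nrow(zv), ncol(zv)))
}

#' Aggregate a count raster to admin zones
#'
#' Sums cell values within each zone label. For a `u5_counts` triple the
#' mean, lower and upper layers are summed independently — the bound sums are
#' conservative envelopes, not joint posterior quantiles, since cell-level
#' posterior correlation is not retained in the surfaces. Cells carrying
#' counts but no zone label are collected in an `NA`-zone "unassigned" row
#' (with a warning), so that zone totals plus unassigned always conserve the
#' national total exactly.
#'
#' @param x A `u5_raster` or `u5_counts`.
#' @param zones A `u5_raster` of integer zone labels on the same grid.
#' @return A tibble with `zone_id` (NA = unassigned) and `mean` (plus
#'   `lower`, `upper` for a `u5_counts`), one row per zone.
#' @export
zonal_aggregate <- function(x, zones) {
  stopifnot(inherits(zones, "u5_raster"))
  layers <- if (inherits(x, "u5_counts")) {
    x[c("mean", "lower", "upper")]
  } else if (inherits(x, "u5_raster")) {
    list(mean = x$values)
  } else {
    stop("x must be a u5_raster or u5_counts")
  }
  if (!grids_identical(x$grid, zones$grid)) stop("grid mismatch")
  zv <- c(zones$values)
  has_data <- !is.na(c(layers$mean))
  if (any(is.na(zv) & has_data)) {
    warning(sprintf("%d populated cell(s) without a zone label: %s",
                    sum(is.na(zv) & has_data),
                    "collected as unassigned (zone_id NA)"))
  }
  zfac <- factor(zv, exclude = NULL)
  out <- tibble::tibble(zone_id = as.integer(as.character(levels(zfac))))
  for (nm in names(layers)) {
    v <- c(layers[[nm]])
    v[is.na(v)] <- 0
    out[[nm]] <- as.numeric(rowsum(v, zfac))
  }
  dplyr::arrange(out, is.na(.data$zone_id), .data$zone_id)
}

#' Unprotected under-five counts per zone
#'
#' Applies intervention-coverage proportions (e.g. the fraction of children
#' having received basic vaccination, or sleeping under an ITN) to zonal
#' under-five totals: `unprotected = under5 * (1 - coverage)`, elementwise
#' for mean/lower/upper.
#'
#' @param zonal Tibble from [zonal_aggregate()] (`zone_id`, `mean`, and
#'   optionally `lower`, `upper`).
#' @param coverage Data frame with `zone_id` and `coverage` in \[0, 1\] for
#'   every zone in `zonal` (a single-row data frame with `zone_id = NA` is
#'   matched to the unassigned bucket).
#' @param method Label recorded in the output (e.g. `"mbg"`).
#' @return A tibble: `zone_id`, `method`, `under5`, `coverage_prop`,
#'   `unprotected` (and `*_lower`, `*_upper` when bounds are present).
#' @export
unprotected_counts <- function(zonal, coverage, method = "mbg") {
  stopifnot(all(c("zone_id", "coverage") %in% names(coverage)),
            all(coverage$coverage >= 0), all(coverage$coverage <= 1))
  i <- match(zonal$zone_id, coverage$zone_id)
  if (anyNA(i[!is.na(zonal$zone_id)])) {
    stop("coverage proportions missing for some zones")
  }
  cv <- coverage$coverage[i]
  out <- tibble::tibble(zone_id = zonal$zone_id, method = method,
                        under5 = zonal$mean, coverage_prop = cv,
                        unprotected = zonal$mean * (1 - cv))
  if (all(c("lower", "upper") %in% names(zonal))) {
    out$under5_lower <- zonal$lower
    out$under5_upper <- zonal$upper
    out$unprotected_lower <- zonal$lower * (1 - cv)
    out$unprotected_upper <- zonal$upper * (1 - cv)
  }
  out
}

#' Compare denominator methods zone by zone
#'
#' Absolute and percentage differences of each method's zonal estimate
#' against the reference method (default `"mbg"`), with zones ranked by the
#' largest absolute gap.
#'
#' @param estimates Named list of zonal tibbles (each with `zone_id` and a
#'   value column), one per method, identical zone sets.
#' @param value Column to compare (default `"mean"`).
#' @param reference Name of the reference method (default `"mbg"`).
#' @return A tibble: `zone_id`, `method`, `value`, `reference_value`,
#'   `abs_diff` (method minus reference), `pct_diff` (in percent of the
#'   reference), `rank` (1 = largest |abs_diff|, within method).
#' @export
compare_methods <- function(estimates, value = "mean", reference = "mbg") {
  stopifnot(reference %in% names(estimates))
  ref <- estimates[[reference]]
  zid <- ref$zone_id
  for (e in estimates) {
    if (!identical(sort(e$zone_id, na.last = TRUE),
                   sort(zid, na.last = TRUE))) {
      stop("methods cover different zone sets")
    }
  }
  others <- setdiff(names(estimates), reference)
  purrr::map_dfr(others, function(nm) {
    e <- estimates[[nm]]
    i <- match(zid, e$zone_id, incomparables = NULL)
    v <- e[[value]][i]
    r <- ref[[value]]
    d <- tibble::tibble(zone_id = zid, method = nm, value = v,
                        reference_value = r,
                        abs_diff = v - r,
                        pct_diff = ifelse(r == 0, NA_real_,
                                          100 * (v - r) / r))
    d$rank <- rank(-abs(d$abs_diff), ties.method = "first")
    dplyr::arrange(d, .data$rank)
  })
}
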