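cluster_columns <- c("cluster_id", "lon", "lat", "time", "n_households",
                     "n_people", "n_under5", "p_under5", "urban", "zone_id")

#' Read and validate a cluster CSV
#'
#' Reads a cluster-survey CSV with the canonical columns (`cluster_id`,
#' `lon`, `lat`, `time`, `n_households`, `n_people`, `n_under5`, `p_under5`,
#' `urban`, `zone_id`) and validates every record: `p_under5` in \[0, 1\],
#' `n_under5 <= n_people`, and `p_under5` consistent with
#' `n_under5 / n_people` up to count rounding (|difference| no more than
#' half a person, i.e. `0.5 / n_people`, plus numerical slack — `p_under5`
#' carries the continuous proportion while counts are integers). Violations
#' are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A validated tibble of cluster records.
#' @seealso [write_clusters()]
#' @export
read_clusters <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(cluster_columns, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[cluster_columns]
  df$urban <- as.logical(df$urban)
  problems <- character()
  bad <- which(df$p_under5 < 0 | df$p_under5 > 1)
  if (length(bad)) {
    problems <- c(problems, paste0("p_under5 outside [0, 1] in row(s): ",
                                   paste(bad, collapse = ", ")))
  }
  bad <- which(df$n_under5 > df$n_people)
  if (length(bad)) {
    problems <- c(problems, paste0("n_under5 > n_people in row(s): ",
                                   paste(bad, collapse = ", ")))
  }
  ok <- df$n_people > 0
  tol <- 0.5 / df$n_people + 1e-9
  bad <- which(ok & abs(df$p_under5 - df$n_under5 / df$n_people) > tol)
  if (length(bad)) {
    problems <- c(problems,
                  paste0("p_under5 inconsistent with counts in row(s): ",
                         paste(bad, collapse = ", ")))
  }
  if (length(problems)) stop(paste(problems, collapse = "; "))
  df
}

#' Write cluster records as CSV
#'
#' @param clusters Cluster tibble with the canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(all(cluster_columns %in% names(clusters)))
  readr::write_csv(clusters[cluster_columns], path)
  invisible(path)
}

#' Raster text I/O (ESRI ASCII grid)
#'
#' Single-band rasters are stored as plain-text ESRI ASCII grids
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header followed
#' by rows of values, northernmost row first). Nodata cells are written as
#' -9999 and read back as `NA`. Values are written with 9 significant digits
#' (beyond single precision).
#'
#' @param x A `u5_raster`.
#' @param path File path (conventionally `.asc`).
#' @param nodata Nodata sentinel (default -9999).
#' @return `write_raster_ascii`: `path` invisibly. `read_raster_ascii`: a
#'   `u5_raster`.
#' @export
write_raster_ascii <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "u5_raster"))
  g <- x$grid
  v <- x$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$n_cols), paste("nrows", g$n_rows),
    paste("xllcorner", format(g$x_origin, digits = 15)),
    paste("yllcorner", format(g$y_origin, digits = 15)),
    paste("cellsize", format(g$cell_size, digits = 15)),
    paste("NODATA_value", nodata)), con)
  ## ASCII grids run north to south; internal row 1 is the south row
  for (r in seq(g$n_rows, 1)) {
    writeLines(paste(formatC(v[r, ], format = "g", digits = 9),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_raster_ascii
#' @param reference_grid Optional `u5_grid`; the file's geometry must match
#'   it exactly or an error is raised.
#' @export
read_raster_ascii <- function(path, reference_grid = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0
  repeat {
    i <- i + 1
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.numeric(parts[1])))) { i <- i - 1; break }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  grid <- raster_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                      hdr$nrows, hdr$ncols)
  if (!is.null(reference_grid) && !grids_identical(grid, reference_grid)) {
    stop("raster geometry in ", path, " does not match the reference grid")
  }
  vals <- scan(text = lines[(i + 1):length(lines)], quiet = TRUE)
  if (length(vals) != n_cells(grid)) {
    stop("expected ", n_cells(grid), " values, found ", length(vals))
  }
  m <- matrix(vals, grid$n_rows, grid$n_cols, byrow = TRUE)
  m <- m[seq(grid$n_rows, 1), , drop = FALSE]   # back to south-first rows
  m[m == nodata] <- NA_real_
  raster_layer(grid, m)
}

#' Write a prediction surface as three ASCII rasters
#'
#' @param surface A `u5_surface`.
#' @param dir Output directory.
#' @param prefix File-name prefix (default "surface").
#' @return Character vector of the three paths, invisibly.
#' @export
write_surface <- function(surface, dir, prefix = "surface") {
  stopifnot(inherits(surface, "u5_surface"))
  paths <- file.path(dir, paste0(prefix, "_", c("mean", "lower", "upper"),
                                 ".asc"))
  write_raster_ascii(raster_layer(surface$grid, surface$mean), paths[1])
  write_raster_ascii(raster_layer(surface$grid, surface$lower), paths[2])
  write_raster_ascii(raster_layer(surface$grid, surface$upper), paths[3])
  invisible(paths)
}
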