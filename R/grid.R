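#' Kilometres per degree of longitude/latitude
#'
#' Fixed conversion constant used throughout the package when a distance in
#' degrees is presented in kilometres (and when displacement caps given in km
#' are applied to coordinates in degrees). Latitude dependence is ignored:
#' the package targets near-equatorial study areas where the distortion is
#' small, and all model distances are computed in degrees anyway -- the
#' conversion is presentation only.
#' @export
KM_PER_DEGREE <- 111.32

#' Define a regular raster grid
#'
#' A lightweight grid geometry shared by all raster layers: an origin (the
#' lower-left corner), a square cell size in decimal degrees, and a row/column
#' count. Cell centres sit at `origin + (index - 0.5) * cell_size`; row 1 is
#' the southernmost row, column 1 the westernmost column.
#'
#' @param x_origin,y_origin Coordinates of the lower-left grid corner, decimal
#'   degrees.
#' @param cell_size Cell edge length in degrees; must be positive.
#' @param n_rows,n_cols Number of rows (south to north) and columns (west to
#'   east); each at least 1.
#' @param crs_note Free-text note on the coordinate system; geographic lon/lat
#'   is assumed by every computation.
#' @return An object of class `u5_grid`.
#' @examples
#' g <- raster_grid(3, 4, 0.1, 50, 50)
#' grid_coords(g)
#' @export
raster_grid <- function(x_origin, y_origin, cell_size, n_rows, n_cols,
                        crs_note = "geographic lon/lat") {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols))
  structure(
    list(x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs_note = crs_note),
    class = "u5_grid"
  )
}

#' @export
print.u5_grid <- function(x, ...) {
  cat(sprintf("<u5_grid> %d x %d cells of %g deg, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin,
              x$crs_note))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

grids_identical <- function(a, b) {
  isTRUE(all.equal(a[c("x_origin", "y_origin", "cell_size")],
                   b[c("x_origin", "y_origin", "cell_size")])) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `u5_grid`.
#' @return A tibble with one row per cell: `row`, `col`, `x`, `y` (cell-centre
#'   longitude/latitude in degrees), in column-major order matching `c(values)`
#'   of a layer matrix.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "u5_grid"))
  row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  tibble::tibble(
    row = row, col = col,
    x = grid$x_origin + (col - 0.5) * grid$cell_size,
    y = grid$y_origin + (row - 0.5) * grid$cell_size
  )
}

#' Locate points on a grid
#'
#' Maps longitude/latitude to the row/column of the containing cell. Points on
#' a cell boundary belong to the cell to the north-east of the boundary.
#'
#' @param grid A `u5_grid`.
#' @param lon,lat Numeric vectors of equal length, degrees.
#' @return A tibble with `row`, `col` (NA for points off the grid).
#' @export
cell_at <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "u5_grid"), length(lon) == length(lat))
  col <- floor((lon - grid$x_origin) / grid$cell_size) + 1
  row <- floor((lat - grid$y_origin) / grid$cell_size) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Construct a single raster layer
#'
#' @param grid A `u5_grid`.
#' @param values Numeric matrix of dimension `n_rows x n_cols` (row 1 = south),
#'   or a single number recycled to the full grid. `NA` marks nodata.
#' @return An object of class `u5_raster`.
#' @export
raster_layer <- function(grid, values) {
  stopifnot(inherits(grid, "u5_grid"))
  if (length(values) == 1) {
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  }
  stopifnot(is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "u5_raster")
}

#' @export
print.u5_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<u5_raster> %d x %d, %d nodata cells, range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @rdname raster_layer
#' @param x A `u5_raster`.
#' @param ... Unused.
#' @method as_tibble u5_raster
#' @export
as_tibble.u5_raster <- function(x, ...) {
  out <- grid_coords(x$grid)   # its `x` column would mask the argument in
  out$value <- c(x$values)     # a data-masked verb, so assign directly
  out
}

#' @method autoplot u5_raster
#' @export
autoplot.u5_raster <- function(object, ...) {
  df <- as_tibble.u5_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude")
}
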