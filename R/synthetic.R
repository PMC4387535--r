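## Run code with a private RNG stream: seeds deterministically, restores any
## pre-existing .Random.seed so callers' streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Smooth stationary random surface on the grid via random cosine features
## (squared-exponential spectrum, lengthscale `ell` in degrees). Cheap for any
## grid size and exactly reproducible; used only to paint covariate layers,
## not for the model's own Matern field.
random_smooth_field <- function(grid, ell, n_features = 96) {
  xy <- grid_coords(grid)
  w <- matrix(stats::rnorm(2 * n_features, sd = 1 / ell), ncol = 2)
  phase <- stats::runif(n_features, 0, 2 * pi)
  proj <- cbind(xy$x, xy$y) %*% t(w)
  v <- sqrt(2 / n_features) * rowSums(cos(sweep(proj, 2, phase, "+")))
  matrix(v, grid$n_rows, grid$n_cols)
}

#' Generate a synthetic covariate stack
#'
#' Paints four spatially smooth covariate layers on a grid, emulating the
#' long-term-mean environmental surfaces used to predict under-five
#' proportions: an accessibility index, enhanced vegetation index (EVI), a
#' land-cover class code and night-time lights. Continuous layers are
#' standardized to mean 0, sd 1 over the valid (masked-in) cells; land cover
#' holds integer codes 0..5 cut from a smooth latent surface; night-time
#' lights is right-skewed so that an urban indicator can be derived as cells
#' above its 90th percentile (see [urban_mask()]). A small fraction of cells
#' is masked out (e.g. water bodies) via a latent threshold.
#'
#' @param grid A [raster_grid()] with at least 2 cells.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param mask_frac Fraction of cells masked out as invalid (default 0.02).
#' @return An object of class `u5_stack`: list with `grid`, named `layers`
#'   (matrices), and logical `mask` (TRUE = valid).
#' @export
gen_covariate_stack <- function(grid, seed, mask_frac = 0.02) {
  stopifnot(inherits(grid, "u5_grid"))
  if (n_cells(grid) < 2) stop("degenerate grid: need at least 2 cells")
  extent <- max(grid$n_rows, grid$n_cols) * grid$cell_size
  with_seed(seed, {
    water <- random_smooth_field(grid, ell = 0.15 * extent)
    mask <- water <= stats::quantile(water, 1 - mask_frac)
    access <- random_smooth_field(grid, ell = 0.25 * extent)
    evi <- random_smooth_field(grid, ell = 0.20 * extent)
    lc_latent <- random_smooth_field(grid, ell = 0.12 * extent)
    ntl_latent <- random_smooth_field(grid, ell = 0.10 * extent)
    ## night-time lights: bright in a few hotspots, dim elsewhere
    ntl <- exp(1.5 * ntl_latent)
    landcover <- matrix(
      as.numeric(cut(c(lc_latent), breaks = stats::quantile(
        c(lc_latent), probs = seq(0, 1, length.out = 7)),
        include.lowest = TRUE, labels = FALSE)) - 1,
      grid$n_rows, grid$n_cols)
    std <- function(m) {
      v <- m[mask]
      m[] <- (m - mean(v)) / stats::sd(v)
      m[!mask] <- NA_real_
      m
    }
    landcover[!mask] <- NA_real_
    structure(
      list(grid = grid,
           layers = list(accessibility = std(access), evi = std(evi),
                         landcover = landcover, nightlights = std(ntl)),
           mask = mask),
      class = "u5_stack")
  })
}

#' @export
print.u5_stack <- function(x, ...) {
  cat(sprintf("<u5_stack> %d x %d, layers: %s; %d masked-out cells\n",
              x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", "), sum(!x$mask)))
  invisible(x)
}

#' @rdname gen_covariate_stack
#' @param x A `u5_stack`.
#' @param ... Unused.
#' @return For `as_tibble`: a tibble with `row`, `col`, `x`, `y`, `mask` and
#'   one column per layer.
#' @method as_tibble u5_stack
#' @export
as_tibble.u5_stack <- function(x, ...) {
  out <- grid_coords(x$grid)
  out$mask <- c(x$mask)
  for (nm in names(x$layers)) out[[nm]] <- c(x$layers[[nm]])
  out
}

#' Urban indicator derived from night-time lights
#'
#' Cells whose night-time-lights value exceeds its 90th percentile over valid
#' cells are flagged urban, mirroring the use of bright lights as a proxy for
#' large settlements.
#'
#' @param stack A `u5_stack` containing a `nightlights` layer.
#' @param quantile Percentile threshold (default 0.9).
#' @return Logical matrix (NA where masked out).
#' @export
urban_mask <- function(stack, quantile = 0.9) {
  ntl <- stack$layers$nightlights
  thr <- stats::quantile(ntl[stack$mask], quantile, names = FALSE)
  out <- ntl > thr
  out[!stack$mask] <- NA
  out
}

#' Draw from the space-time Matern Gaussian field
#'
#' Samples zero-mean Gaussian vectors whose covariance is [st_cov()] evaluated
#' between every pair of points (no nugget), via dense Cholesky factorization
#' with escalating diagonal jitter.
#'
#' @param points Data frame with `lon`, `lat`, `time`; at most a few thousand
#'   rows (dense Cholesky).
#' @param model A `u5_model`.
#' @param seed Integer seed.
#' @param n Number of independent draws (default 1).
#' @return A numeric vector (n = 1) or a `nrow(points) x n` matrix.
#' @export
sim_matern_gp <- function(points, model, seed, n = 1) {
  stopifnot(inherits(model, "u5_model"), nrow(points) >= 1)
  if (model$sigma2 == 0) {
    z <- matrix(0, nrow(points), n)
    return(if (n == 1) drop(z) else z)
  }
  K <- build_cov_matrix(points, model, nugget = FALSE)
  ch <- chol_jitter(K)
  with_seed(seed, {
    z <- matrix(stats::rnorm(nrow(points) * n), nrow(points), n)
    out <- crossprod(ch$R, z)
    if (n == 1) drop(out) else out
  })
}

#' Displace cluster coordinates for anonymisation
#'
#' Emulates the random geomasking applied to survey cluster centroids: each
#' cluster is moved along a uniform random bearing by a distance uniform on
#' \[0, D\], with D = 2 km for urban clusters and 5 km for rural clusters,
#' except that a fraction `rural_far_fraction` of rural clusters (1% by
#' default) is displaced up to 10 km. Kilometres convert to degrees by the
#' fixed [KM_PER_DEGREE] constant.
#'
#' @param lon,lat Coordinate vectors, degrees.
#' @param urban Logical vector, same length.
#' @param rural_far_fraction Fraction of rural clusters given the far cap.
#' @param seed Integer seed.
#' @param urban_max_km,rural_max_km,far_max_km Displacement caps in km;
#'   setting a cap to 0 leaves those clusters at their input location.
#' @return A tibble with `lon`, `lat` (displaced), `dist_km` and `far`
#'   (logical: drew the 10 km cap).
#' @export
displace_location <- function(lon, lat, urban, rural_far_fraction = 0.01,
                              seed = NULL, urban_max_km = 2,
                              rural_max_km = 5, far_max_km = 10) {
  n <- length(lon)
  stopifnot(length(lat) == n, length(urban) == n)
  run <- function() {
    far <- !urban & stats::runif(n) < rural_far_fraction
    cap <- ifelse(urban, urban_max_km, ifelse(far, far_max_km, rural_max_km))
    d <- stats::runif(n, 0, cap)
    theta <- stats::runif(n, 0, 2 * pi)
    tibble::tibble(
      lon = lon + d * sin(theta) / KM_PER_DEGREE,
      lat = lat + d * cos(theta) / KM_PER_DEGREE,
      dist_km = d, far = far)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## Default admin-zone partition: k x k equal blocks labelled 1..k^2
block_zones <- function(grid, k = 3) {
  co <- grid_coords(grid)
  zr <- pmin(k, ceiling(co$row / (grid$n_rows / k)))
  zc <- pmin(k, ceiling(co$col / (grid$n_cols / k)))
  raster_layer(grid, matrix((zr - 1) * k + zc, grid$n_rows, grid$n_cols))
}

#' Generate an admin-zone raster
#'
#' Partitions the grid into `n_zones` contiguous zones by nearest seeded
#' centre (a Voronoi tessellation of cell centres), labelled 1..n_zones.
#'
#' @param grid A `u5_grid`.
#' @param n_zones Number of zones.
#' @param seed Integer seed for the centre placement.
#' @return A `u5_raster` of integer zone labels.
#' @export
gen_zone_raster <- function(grid, n_zones = 9, seed = 1) {
  stopifnot(n_zones >= 1, n_zones <= n_cells(grid))
  co <- grid_coords(grid)
  with_seed(seed, {
    ctr <- co[sample.int(nrow(co), n_zones), ]
    d2 <- outer(co$x, ctr$x, "-")^2 + outer(co$y, ctr$y, "-")^2
    raster_layer(grid, matrix(max.col(-d2), grid$n_rows, grid$n_cols))
  })
}

#' Generate a synthetic gridded population raster
#'
#' A heterogeneous, strictly positive population-count surface: a log-normal
#' transform of a smooth latent field, concentrated where night-time lights
#' are bright when a stack is supplied, scaled to a national total. Cells
#' masked out in the stack get NA.
#'
#' @param grid A `u5_grid`.
#' @param seed Integer seed.
#' @param total National population total to distribute (default 1e6).
#' @param stack Optional `u5_stack`; its `nightlights` layer attracts
#'   population and its mask is inherited.
#' @return A `u5_raster` of persons per cell.
#' @export
gen_population_raster <- function(grid, seed, total = 1e6, stack = NULL) {
  extent <- max(grid$n_rows, grid$n_cols) * grid$cell_size
  with_seed(seed, {
    f <- random_smooth_field(grid, ell = 0.2 * extent)
    if (!is.null(stack)) {
      stopifnot(grids_identical(grid, stack$grid))
      ntl <- stack$layers$nightlights
      ntl[is.na(ntl)] <- 0
      f <- f + 1.2 * ntl
      mask <- stack$mask
    } else {
      mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
    }
    w <- exp(f)
    w[!mask] <- 0
    pop <- w / sum(w) * total
    pop[!mask] <- NA_real_
    raster_layer(grid, pop)
  })
}

#' Simulate a multi-wave cluster survey
#'
#' Generates geolocated survey clusters with the exact statistical structure
#' the mapping model assumes. True cluster locations are drawn over valid
#' cells, stratified into urban and rural strata (urban = bright night-time
#' lights, see [urban_mask()]); each cluster belongs to one survey wave. The
#' observed proportion is
#' `linear predictor (beta . covariates at the TRUE location) + space-time
#' Matern GP draw + Gaussian measurement noise`, clipped to \[0, 1\] with the
#' number of clip events recorded. The *recorded* coordinates are displaced
#' per [displace_location()] — reproducing the geomasking error source that
#' real cluster data carry — while the truth object keeps the original
#' locations. Household counts are uniform integers in `households_range`;
#' total persons are Poisson around `mean_household_size` per household, and
#' `n_under5` is back-filled as `round(p_under5 * n_people)` (so printed
#' counts are consistent with the proportion only up to rounding; `p_under5`
#' keeps the continuous model response).
#'
#' @param stack A `u5_stack` whose layer names cover `names(model$beta)[-1]`.
#' @param model A `u5_model`.
#' @param n_clusters Number of clusters (>= 10).
#' @param n_waves Number of survey waves (>= 1); waves are indexed 0-based and
#'   clusters split evenly across them.
#' @param households_range Integer (min, max) households per cluster.
#' @param seed Integer seed.
#' @param zones Optional `u5_raster` of integer zone labels; defaults to a
#'   3 x 3 block partition of the grid.
#' @param urban_share Fraction of clusters drawn from the urban stratum
#'   (default 0.3, emulating urban oversampling relative to urban land area).
#' @param mean_household_size Mean persons per household (default 5).
#' @param truth_points Optional data frame (`lon`, `lat`, `time`) of extra
#'   sites at which the latent truth is evaluated jointly with the clusters
#'   (for calibration studies).
#' @param rural_far_fraction Passed to [displace_location()].
#' @return A list with `clusters` (tibble with columns `cluster_id`, `lon`,
#'   `lat`, `time`, `n_households`, `n_people`, `n_under5`, `p_under5`,
#'   `urban`, `zone_id`) and `truth` (class `u5_truth`: true locations,
#'   linear predictor, GP values, latent truth at `truth_points`, the model,
#'   the seed, and `n_clipped`).
#' @export
simulate_survey <- function(stack, model, n_clusters, n_waves,
                            households_range = c(20, 50), seed = 1,
                            zones = NULL, urban_share = 0.3,
                            mean_household_size = 5, truth_points = NULL,
                            rural_far_fraction = 0.01) {
  stopifnot(inherits(stack, "u5_stack"), inherits(model, "u5_model"),
            n_clusters >= 10, n_waves >= 1)
  covs <- names(model$beta)[-1]
  missing_layers <- setdiff(covs, names(stack$layers))
  if (length(missing_layers)) {
    stop("stack lacks layers for model coefficients: ",
         paste(missing_layers, collapse = ", "))
  }
  grid <- stack$grid
  valid <- which(c(stack$mask))
  if (n_clusters > length(valid)) {
    stop(sprintf("n_clusters (%d) exceeds valid cells (%d)",
                 n_clusters, length(valid)))
  }
  urb <- c(urban_mask(stack))
  if (is.null(zones)) zones <- block_zones(grid)
  stopifnot(grids_identical(grid, zones$grid))
  co <- grid_coords(grid)

  with_seed(seed, {
    ## stratified cell sampling: urban stratum first, topped up if small
    urban_cells <- valid[urb[valid] %in% TRUE]
    rural_cells <- valid[urb[valid] %in% FALSE]
    n_urb <- min(round(urban_share * n_clusters), length(urban_cells))
    n_rur <- n_clusters - n_urb
    if (n_rur > length(rural_cells)) {
      n_urb <- n_urb + (n_rur - length(rural_cells))
      n_rur <- length(rural_cells)
    }
    cells <- c(sample(urban_cells, n_urb), sample(rural_cells, n_rur))
    is_urban <- c(rep(TRUE, n_urb), rep(FALSE, n_rur))
    ## true location: uniform within the sampled cell
    true_lon <- co$x[cells] + stats::runif(n_clusters, -0.5, 0.5) * grid$cell_size
    true_lat <- co$y[cells] + stats::runif(n_clusters, -0.5, 0.5) * grid$cell_size
    time <- rep(seq_len(n_waves) - 1L, length.out = n_clusters)

    Xc <- vapply(covs, function(nm) stack$layers[[nm]][cells],
                 numeric(n_clusters))
    lp <- model$beta[1] +
      if (length(covs)) drop(Xc %*% model$beta[covs]) else 0

    pts <- tibble::tibble(lon = true_lon, lat = true_lat, time = time)
    all_pts <- if (is.null(truth_points)) pts else
      dplyr::bind_rows(pts, truth_points[, c("lon", "lat", "time")])
    gp_seed <- sample.int(.Machine$integer.max, 1)
    gp_all <- sim_matern_gp(all_pts, model, seed = gp_seed)
    gp <- gp_all[seq_len(n_clusters)]

    noise <- stats::rnorm(n_clusters, 0, sqrt(model$nugget))
    p_raw <- lp + gp + noise
    p <- pmin(1, pmax(0, p_raw))
    n_clipped <- sum(p != p_raw)

    hh <- sample(households_range[1]:households_range[2], n_clusters,
                 replace = TRUE)
    n_people <- pmax(1L, stats::rpois(n_clusters, hh * mean_household_size))
    n_under5 <- pmin(n_people, pmax(0L, as.integer(round(p * n_people))))

    disp <- displace_location(true_lon, true_lat, is_urban,
                              rural_far_fraction = rural_far_fraction)
    clusters <- tibble::tibble(
      cluster_id = sprintf("cl%04d", seq_len(n_clusters)),
      lon = disp$lon, lat = disp$lat, time = time,
      n_households = as.integer(hh), n_people = as.integer(n_people),
      n_under5 = as.integer(n_under5), p_under5 = p,
      urban = is_urban, zone_id = as.integer(zones$values[cells]))
    truth <- structure(
      list(model = model, seed = seed, n_clipped = n_clipped,
           true_lon = true_lon, true_lat = true_lat,
           linear_predictor = lp, gp = gp, latent = lp + gp,
           truth_points = if (is.null(truth_points)) NULL else
             dplyr::mutate(
               tibble::as_tibble(truth_points),
               latent = model$beta[1] + gp_all[-seq_len(n_clusters)] +
                 truth_lp(truth_points, stack, model))),
      class = "u5_truth")
    list(clusters = clusters, truth = truth)
  })
}

## linear predictor at arbitrary points (covariates looked up by cell)
truth_lp <- function(points, stack, model) {
  covs <- names(model$beta)[-1]
  if (!length(covs)) return(rep(0, nrow(points)))
  rc <- cell_at(stack$grid, points$lon, points$lat)
  idx <- (rc$col - 1L) * stack$grid$n_rows + rc$row
  Xc <- matrix(unlist(lapply(covs, function(nm) stack$layers[[nm]][idx])),
               nrow = nrow(points))
  drop(Xc %*% model$beta[covs])
}

#' @export
print.u5_truth <- function(x, ...) {
  cat(sprintf("<u5_truth> %d clusters, %d clipped; seed %d\n",
              length(x$latent), x$n_clipped, x$seed))
  print(x$model)
  invisible(x)
}
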