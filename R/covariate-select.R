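#' Attach covariate values to cluster records
#'
#' Looks up each cluster's covariate values from a stack, either at the cell
#' containing the (recorded, i.e. displaced) coordinates or as a buffer
#' average. Because geomasking can push a recorded location off the valid
#' grid, points falling on a masked-out or off-grid cell take the value of
#' the nearest valid cell. In buffer mode continuous layers are averaged over
#' valid cells whose centres lie within `buffer_km`; the land-cover code takes
#' the modal class in the buffer.
#'
#' @param clusters A data frame with `lon`, `lat` columns.
#' @param stack A `u5_stack`.
#' @param layers Layer names to extract (default: all).
#' @param buffer_km Buffer radius in km (0 = point extraction). Converted to
#'   degrees by [KM_PER_DEGREE].
#' @return The input tibble with one extra column per layer.
#' @export
extract_covariates <- function(clusters, stack, layers = names(stack$layers),
                               buffer_km = 0) {
  stopifnot(all(c("lon", "lat") %in% names(clusters)),
            all(layers %in% names(stack$layers)))
  grid <- stack$grid
  co <- grid_coords(grid)
  valid <- which(c(stack$mask))
  out <- tibble::as_tibble(clusters)
  if (buffer_km <= 0) {
    rc <- cell_at(grid, clusters$lon, clusters$lat)
    idx <- (rc$col - 1L) * grid$n_rows + rc$row
    bad <- is.na(idx) | !(idx %in% valid)
    if (any(bad)) {
      ## snap to nearest valid cell centre
      for (i in which(bad)) {
        d2 <- (co$x[valid] - clusters$lon[i])^2 +
          (co$y[valid] - clusters$lat[i])^2
        idx[i] <- valid[which.min(d2)]
      }
    }
    for (nm in layers) out[[nm]] <- stack$layers[[nm]][idx]
  } else {
    r_deg <- buffer_km / KM_PER_DEGREE
    for (nm in layers) out[[nm]] <- NA_real_
    for (i in seq_len(nrow(clusters))) {
      d2 <- (co$x[valid] - clusters$lon[i])^2 +
        (co$y[valid] - clusters$lat[i])^2
      sel <- valid[d2 <= r_deg^2]
      if (!length(sel)) sel <- valid[which.min(d2)]
      for (nm in layers) {
        v <- stack$layers[[nm]][sel]
        out[[nm]][i] <- if (nm == "landcover") {
          as.numeric(names(which.max(table(v))))
        } else {
          mean(v)
        }
      }
    }
  }
  out
}

#' Ordinary least-squares Gaussian regression with its log-likelihood
#'
#' Fits the non-spatial Gaussian linear model (identity link) of a proportion
#' on a covariate subset, with an implicit intercept, and evaluates the
#' Gaussian log-likelihood at the maximum-likelihood variance
#' \eqn{\hat\sigma^2 = RSS / n}.
#'
#' @param X Data frame or matrix of covariate columns (possibly zero columns
#'   for the intercept-only model). No missing values; full column rank.
#' @param y Numeric response vector.
#' @return A list with `coefficients` (named, starting `intercept`), `loglik`,
#'   `sigma2` (the MLE \eqn{RSS/n}) and `n`.
#' @export
fit_gaussian_glm <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n || p == 0)
  if (p > 0 && anyNA(X)) stop("missing values in design matrix")
  if (n <= p + 2) stop("need n > p + 2 observations")
  design <- cbind(intercept = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(design, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(coefficients = fit$coefficients, loglik = loglik,
       sigma2 = sigma2, n = n)
}

#' Bayesian information criterion
#'
#' `-2 * loglik + k * log(n)`. For the Gaussian regression models scored here
#' `k` counts the intercept, the slopes and the error variance.
#'
#' @param loglik Log-likelihood at the MLE.
#' @param k Number of estimated parameters (intercept + slopes + variance).
#' @param n Number of observations; > 0.
#' @return The BIC value (smaller is better).
#' @export
bic_score <- function(loglik, k, n) {
  stopifnot(n > 0)
  -2 * loglik + k * log(n)
}

#' Exhaustive best-subset selection under BIC
#'
#' Scores every subset of the candidate covariates (2^p Gaussian regressions,
#' p <= 20) by BIC and returns the full ranking. This exhaustive enumeration
#' finds the same optimum a branch-and-bound search would, and is trivially
#' verifiable. Ties in BIC are broken in favour of fewer covariates, then
#' lexicographic subset labels.
#'
#' @param data Data frame holding the response and candidate columns; no
#'   missing values among them.
#' @param response Name of the response column (a proportion).
#' @param candidates Character vector of candidate covariate column names
#'   (unique; at most 20).
#' @return A tibble, one row per subset, ranked: `rank`, `subset` (list
#'   column of names), `label`, `n_covariates`, `coefficients` (list column),
#'   `loglik`, `bic`. Row 1 (`rank == 1`) is the selected model.
#' @examples
#' d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
#' best_subset_bic(d, "y", c("a", "b"))
#' @export
best_subset_bic <- function(data, response, candidates) {
  stopifnot(response %in% names(data), all(candidates %in% names(data)))
  if (anyDuplicated(candidates)) stop("duplicate candidate names")
  p <- length(candidates)
  if (p > 20) {
    stop("more than 20 candidates: pre-screen before exhaustive enumeration")
  }
  y <- data[[response]]
  if (anyNA(y) || anyNA(data[candidates])) {
    stop("missing values in response or candidates")
  }
  X_all <- as.matrix(data[candidates])
  subsets <- purrr::map(0:(2^p - 1), function(code) {
    candidates[bitwAnd(code, bitwShiftL(1, seq_len(p) - 1)) > 0]
  })
  res <- purrr::map_dfr(subsets, function(s) {
    f <- fit_gaussian_glm(X_all[, s, drop = FALSE], y)
    tibble::tibble(
      subset = list(s),
      label = if (length(s)) paste(sort(s), collapse = "+") else "(intercept)",
      n_covariates = length(s),
      coefficients = list(f$coefficients),
      loglik = f$loglik,
      bic = bic_score(f$loglik, k = length(s) + 2, n = f$n))
  })
  res <- dplyr::arrange(res, .data$bic, .data$n_covariates, .data$label)
  dplyr::relocate(dplyr::mutate(res, rank = dplyr::row_number()), "rank")
}

#' Candidate model menu from a selected covariate set
#'
#' Given the selected covariates, builds the conventional comparison menu:
#' the full set plus every leave-one-out subset (five models when four
#' covariates are selected).
#'
#' @param covariates Character vector of selected covariate names (>= 2).
#' @return A named list of character vectors (`model_1` = full set,
#'   `model_2`... = each with one covariate dropped).
#' @export
candidate_model_menu <- function(covariates) {
  stopifnot(length(covariates) >= 2)
  menu <- c(list(covariates),
            lapply(seq_along(covariates), function(i) covariates[-i]))
  names(menu) <- paste0("model_", seq_along(menu))
  menu
}
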