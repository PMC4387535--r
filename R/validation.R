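#' Random holdout split of cluster data
#'
#' Simple random (optionally urban-stratified) split into training and test
#' sets, seed-reproducible. The test size is `round(n * fraction)` — a 10%
#' split of 1624 clusters yields 162 test clusters.
#'
#' @param clusters Data frame of cluster records.
#' @param fraction Test fraction in (0, 0.5].
#' @param seed Integer seed.
#' @param stratify_urban Draw the split within urban/rural strata (requires
#'   an `urban` column; default FALSE).
#' @return A list with `train` and `test` tibbles and `holdout_ids` (row
#'   indices of the test set in the input).
#' @export
holdout_split <- function(clusters, fraction = 0.10, seed = 1,
                          stratify_urban = FALSE) {
  stopifnot(fraction > 0, fraction <= 0.5)
  n <- nrow(clusters)
  with_seed(seed, {
    if (stratify_urban) {
      stopifnot("urban" %in% names(clusters))
      idx <- unlist(lapply(split(seq_len(n), clusters$urban), function(g) {
        sample(g, round(length(g) * fraction))
      }), use.names = FALSE)
      idx <- sort(idx)
    } else {
      idx <- sort(sample.int(n, round(n * fraction)))
    }
    list(train = tibble::as_tibble(clusters)[-idx, ],
         test = tibble::as_tibble(clusters)[idx, ],
         holdout_ids = idx)
  })
}

#' Holdout prediction-error metrics
#'
#' Mean prediction error (MPE, signed: predicted minus observed), mean
#' absolute error (MAE), root mean squared error (RMSE) and the Pearson
#' product-moment correlation between observed and predicted values.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return A one-row tibble: `mpe`, `mae`, `rmse`, `pearson_r`, `n`.
#'   `pearson_r` is NA (with a warning) when either vector has zero variance.
#' @examples
#' holdout_metrics(c(0.1, 0.2, 0.3), c(0.12, 0.18, 0.33))
#' @export
holdout_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  e <- predicted - observed
  r <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance: Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(observed, predicted)
  }
  tibble::tibble(mpe = mean(e), mae = mean(abs(e)),
                 rmse = sqrt(mean(e^2)), pearson_r = r,
                 n = length(observed))
}

#' Leave-one-out conditional predictive ordinates
#'
#' For each observation, the Gaussian predictive density of \eqn{y_i} under
#' the fitted model conditioned on all other observations, computed in closed
#' form from the fitted covariance matrix without refitting: with
#' \eqn{Q = K^{-1}} and residuals \eqn{r = y - X\hat\beta},
#' \deqn{\sigma^2_{-i} = 1 / Q_{ii}, \qquad
#'       \mu_{-i} = y_i - (Q r)_i / Q_{ii},}
#' and \eqn{CPO_i = N(y_i; \mu_{-i}, \sigma^2_{-i})}. The fixed effects are
#' held at their full-data GLS estimate (an empirical-Bayes convention: no
#' per-deletion re-estimation of \eqn{\beta} or of variance components, hence
#' no n/(n-1)-style variance adjustment). Under a purely iid model
#' (\eqn{\sigma^2 = 0}) this reduces to the normal density of each residual
#' with variance equal to the nugget.
#'
#' @param fit A `u5_fit`.
#' @param flag_quantile Observations with CPO below this quantile of the CPO
#'   distribution are flagged (qualitative screening; default 0.025).
#' @return A tibble with `cpo`, `loo_mean`, `loo_sd`, `loo_z` (standardized
#'   LOO residual `(y - loo_mean) / loo_sd`) and `flagged`.
#' @export
loo_cpo <- function(fit, flag_quantile = 0.025) {
  stopifnot(inherits(fit, "u5_fit"))
  Q <- chol2inv(fit$chol_R)
  qd <- diag(Q)
  if (any(qd <= 0)) stop("singular conditional sub-matrix in LOO computation")
  r <- fit$y - drop(fit$X %*% fit$model$beta)
  loo_var <- 1 / qd
  loo_mean <- fit$y - drop(Q %*% r) / qd
  cpo <- stats::dnorm(fit$y, loo_mean, sqrt(loo_var))
  tibble::tibble(
    cpo = cpo, loo_mean = loo_mean, loo_sd = sqrt(loo_var),
    loo_z = (fit$y - loo_mean) / sqrt(loo_var),
    flagged = cpo < stats::quantile(cpo, flag_quantile))
}

#' Empirical semivariogram with permutation envelopes
#'
#' Bins all point pairs (up to `max_dist`) by separation distance and
#' computes the empirical semivariance \eqn{\gamma(b) = mean_{(i,j) \in b}
#' (r_i - r_j)^2 / 2}. Envelopes are the pointwise per-bin minimum and
#' maximum of \eqn{\gamma} recomputed under `n_perm` random permutations of
#' the residuals over the fixed locations — the range expected by chance in
#' the absence of spatial autocorrelation. An observed \eqn{\gamma} falling
#' below the lower envelope at short distances indicates residual spatial
#' autocorrelation.
#'
#' @param residuals Numeric vector (length >= 30), typically standardized
#'   leave-one-out residuals (`loo_z` from [loo_cpo()]).
#' @param locations Data frame with `lon`, `lat` for each residual.
#' @param n_bins Number of distance bins (default 12).
#' @param max_dist Maximum pair separation, degrees (default: half the
#'   maximum observed separation).
#' @param n_perm Number of permutations (default 99).
#' @param seed Integer seed for the permutations.
#' @return An object of class `u5_semivariogram`: a tibble with one row per
#'   bin (`bin`, `dist` mean pair distance, `gamma`, `lower`, `upper`,
#'   `n_pairs`, `empty`), with `n_perm` and `max_dist` attributes.
#' @export
residual_semivariogram <- function(residuals, locations, n_bins = 12,
                                   max_dist = NULL, n_perm = 99, seed = 1) {
  n <- length(residuals)
  stopifnot(n >= 30, nrow(locations) == n)
  d <- dist_degrees(cbind(locations$lon, locations$lat))
  lt <- which(lower.tri(d))
  dv <- d[lt]
  if (is.null(max_dist)) max_dist <- max(dv) / 2
  keep <- dv <= max_dist
  ii <- row(d)[lt][keep]
  jj <- col(d)[lt][keep]
  dv <- dv[keep]
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- pmin(n_bins, findInterval(dv, breaks, rightmost.closed = TRUE))
  counts <- tabulate(bin, n_bins)
  gamma_of <- function(r) {
    s <- 0.5 * (r[ii] - r[jj])^2
    out <- rep(NA_real_, n_bins)
    agg <- rowsum(s, bin)
    out[as.integer(rownames(agg))] <- agg[, 1] / counts[as.integer(rownames(agg))]
    out
  }
  g <- gamma_of(residuals)
  env <- with_seed(seed, {
    matrix(vapply(seq_len(n_perm), function(k) gamma_of(sample(residuals)),
                  numeric(n_bins)), nrow = n_bins)
  })
  mean_dist <- rep(NA_real_, n_bins)
  agg_d <- rowsum(dv, bin)
  mean_dist[as.integer(rownames(agg_d))] <-
    agg_d[, 1] / counts[as.integer(rownames(agg_d))]
  if (any(counts == 0)) {
    warning(sprintf("%d empty distance bin(s)", sum(counts == 0)))
  }
  out <- tibble::tibble(
    bin = seq_len(n_bins), dist = mean_dist, gamma = g,
    lower = apply(env, 1, function(x) suppressWarnings(min(x, na.rm = TRUE))),
    upper = apply(env, 1, function(x) suppressWarnings(max(x, na.rm = TRUE))),
    n_pairs = counts, empty = counts == 0)
  out$lower[out$empty] <- NA_real_
  out$upper[out$empty] <- NA_real_
  structure(out, n_perm = n_perm, max_dist = max_dist,
            class = c("u5_semivariogram", class(out)))
}

#' Plot a semivariogram with its permutation envelopes
#'
#' @param object A `u5_semivariogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot u5_semivariogram
#' @export
autoplot.u5_semivariogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[!df$empty, ], ggplot2::aes(x = .data$dist)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$gamma)) +
    ggplot2::labs(x = "distance (degrees)", y = "semivariance",
                  title = "Residual semivariogram with permutation envelopes")
}

#' Holdout validation of a fitted model
#'
#' Convenience wrapper: predicts at held-out clusters with [predict_points()]
#' and computes [holdout_metrics()].
#'
#' @param fit A `u5_fit` (trained on the training subset).
#' @param test Held-out cluster tibble with coordinates, wave, response and
#'   covariate columns.
#' @param response Response column name.
#' @return A one-row tibble of metrics plus the predictions as an attribute
#'   `"predictions"`.
#' @export
validate_holdout <- function(fit, test, response = "p_under5") {
  pr <- predict_points(fit, test)
  m <- holdout_metrics(test[[response]], pr$mean)
  attr(m, "predictions") <- pr
  m
}
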