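#' Space-time Gaussian process model for under-five proportions
#'
#' Parameter container for the separable space-time model used throughout the
#' package. The latent proportion at location \eqn{s} and survey wave \eqn{t}
#' is \eqn{x(s)'\beta + Z(s, t)}, where \eqn{Z} is a zero-mean Gaussian
#' process with separable covariance
#' \deqn{Cov(Z(s,t), Z(s',t')) = M(\|s - s'\|)\,\rho^{|t - t'|},}
#' \eqn{M} the Matern(\eqn{\nu = 1}) function with marginal variance
#' \eqn{\sigma^2} and spatial scaling \eqn{\kappa} (1/degrees), and
#' \eqn{\rho} a first-order autoregressive coefficient across survey waves.
#' Observations add Gaussian measurement error with variance `nugget`
#' (identity link: the model operates directly on the proportion scale).
#'
#' @param beta Named numeric vector of fixed effects. The first element must
#'   be named `"intercept"`; remaining names refer to covariate layers.
#' @param sigma2 Marginal variance of the spatial field (proportion^2); >= 0.
#' @param kappa Matern spatial scaling parameter, 1/degrees; > 0. The nominal
#'   range (correlation approximately 0.1) is `sqrt(8 * nu) / kappa`.
#' @param nugget Measurement-error variance (proportion^2); >= 0.
#' @param rho AR(1) coefficient across survey waves; strictly inside (-1, 1).
#' @param nu Matern smoothness; fixed at 1 (the two-dimensional SPDE default
#'   alpha = 2). Other values are rejected.
#' @return An object of class `u5_model`.
#' @examples
#' m <- stgp_model(beta = c(intercept = 0.18), sigma2 = 7e-4,
#'                 kappa = sqrt(8) / 4.5, nugget = 2.2e-3, rho = -0.47)
#' range_from_kappa(m$kappa)
#' @seealso [default_u5_model()] for study-scale defaults, [matern_cov()],
#'   [st_cov()].
#' @export
stgp_model <- function(beta, sigma2, kappa, nugget, rho, nu = 1) {
  stopifnot(is.numeric(beta), length(beta) >= 1)
  if (is.null(names(beta)) || names(beta)[1] != "intercept") {
    stop("`beta` must be named and start with an \"intercept\" element")
  }
  stopifnot(sigma2 >= 0, kappa > 0, nugget >= 0, abs(rho) < 1)
  if (nu != 1) stop("only nu = 1 is supported")
  structure(
    list(beta = beta, sigma2 = as.numeric(sigma2), kappa = as.numeric(kappa),
         nugget = as.numeric(nugget), rho = as.numeric(rho), nu = 1),
    class = "u5_model"
  )
}

#' @export
print.u5_model <- function(x, ...) {
  cat("<u5_model> separable Matern(nu=1) x AR(1) Gaussian process\n")
  cat(sprintf("  sigma2 = %.6g, kappa = %.4g (range %.3g deg), nugget = %.6g, rho = %.3g\n",
              x$sigma2, x$kappa, range_from_kappa(x$kappa), x$nugget, x$rho))
  cat("  beta:", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Study-scale default model
#'
#' A parameterization at the magnitudes typical of national household-survey
#' under-five proportion data (Nigeria-scale): overall proportion near 0.18,
#' small spatially structured variance, a dominant measurement-error nugget,
#' a nominal spatial range of about 4.5 degrees, and weak negative wave-to-wave
#' correlation. Covariate effects are per standard deviation of the
#' standardized layers (land cover acts through its raw class code).
#'
#' @return A `u5_model`.
#' @export
default_u5_model <- function() {
  stgp_model(
    beta = c(intercept = 0.1815, accessibility = 0.0044, evi = -0.0045,
             landcover = -0.0035, nightlights = 0.0016),
    sigma2 = 7e-4,
    kappa = exp(-0.47),
    nugget = 2.2e-3,
    rho = -0.47
  )
}

#' Matern covariance function (smoothness 1)
#'
#' \eqn{C(h) = \sigma^2 (\kappa h) K_1(\kappa h)} for \eqn{h > 0} and
#' \eqn{\sigma^2} at \eqn{h = 0}, with \eqn{K_1} the modified Bessel function
#' of the second kind. This is the Matern family at \eqn{\nu = 1}, where the
#' general form \eqn{\sigma^2 2^{1-\nu}/\Gamma(\nu) (\kappa h)^\nu
#' K_\nu(\kappa h)} simplifies.
#'
#' @param h Non-negative distance(s), degrees. Vectorized.
#' @param sigma2 Marginal variance.
#' @param kappa Spatial scaling, 1/degrees.
#' @param nu Smoothness; only 1 supported.
#' @return Covariance value(s), same length as `h`.
#' @examples
#' matern_cov(0, 1, 1)            # exactly sigma2
#' matern_cov(1, 1, 1)            # K_1(1) ~ 0.6019
#' @export
matern_cov <- function(h, sigma2, kappa, nu = 1) {
  if (nu != 1) stop("only nu = 1 is supported")
  stopifnot(all(h >= 0), kappa > 0)
  x <- kappa * h
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- sigma2 * x[pos] * besselK(x[pos], 1)
  out[!pos] <- sigma2
  out
}

#' Nominal spatial range implied by the Matern scaling parameter
#'
#' The conventional range at which Matern correlation drops to about 0.1:
#' `sqrt(8 * nu) / kappa`, in degrees. Conversion to kilometres (via
#' [KM_PER_DEGREE]) is a separate presentation step.
#'
#' @inheritParams matern_cov
#' @return Range in degrees.
#' @export
range_from_kappa <- function(kappa, nu = 1) {
  stopifnot(all(kappa > 0))
  sqrt(8 * nu) / kappa
}

#' Separable space-time covariance
#'
#' `matern_cov(h) * rho^|tlag|`: the Matern spatial covariance damped by the
#' AR(1) wave correlation at integer temporal lag `tlag`.
#'
#' @param h Spatial lag(s), degrees, >= 0.
#' @param tlag Integer temporal lag(s) in survey waves (sign irrelevant).
#' @param model A `u5_model`.
#' @return Covariance value(s).
#' @export
st_cov <- function(h, tlag, model) {
  stopifnot(inherits(model, "u5_model"), all(tlag == round(tlag)))
  matern_cov(h, model$sigma2, model$kappa) * model$rho^abs(tlag)
}

## Pairwise Euclidean distance in degrees between two point sets given as
## matrices with columns (lon, lat). Returns an n x m matrix.
dist_degrees <- function(a, b = a) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Dense space-time covariance matrix of a set of observations
#'
#' `K[i, j] = st_cov(d_ij, t_i - t_j) + nugget * 1{i = j}` with `d_ij` the
#' Euclidean distance in degrees. Intended for dense-likelihood work at up to
#' a few thousand points.
#'
#' @param points A data frame with columns `lon`, `lat`, `time` (integer
#'   survey wave).
#' @param model A `u5_model`.
#' @param nugget Logical; include the nugget on the diagonal (default TRUE).
#' @return A symmetric positive-definite numeric matrix.
#' @export
build_cov_matrix <- function(points, model, nugget = TRUE) {
  stopifnot(inherits(model, "u5_model"),
            all(c("lon", "lat", "time") %in% names(points)))
  xy <- cbind(points$lon, points$lat)
  d <- dist_degrees(xy)
  tl <- abs(outer(points$time, points$time, "-"))
  K <- matrix(matern_cov(c(d), model$sigma2, model$kappa),
              nrow(d), ncol(d)) * model$rho^tl
  if (nugget) diag(K) <- diag(K) + model$nugget
  ## enforce exact symmetry against floating-point asymmetry in outer()
  (K + t(K)) / 2
}

## Cholesky with escalating jitter: starts at `base_rel` times the mean
## diagonal, escalates x10 up to `max_rel`, then fails with diagnostics.
chol_jitter <- function(K, base_rel = 1e-10, max_rel = 1e-6) {
  scale <- mean(diag(K))
  if (scale <= 0) scale <- 1
  jit <- 0
  rel <- base_rel
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(R = L, jitter = jit))
    if (rel > max_rel) {
      ev <- range(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
      stop(sprintf(paste0("covariance matrix not positive definite after ",
                          "jitter %.3g (eigenvalue range [%.3g, %.3g])"),
                   jit, ev[1], ev[2]))
    }
    jit <- rel * scale
    rel <- rel * 10
  }
}

#' Gaussian-process log marginal likelihood
#'
#' Evaluates \eqn{\log N(y; X\beta, K)} with `K` from [build_cov_matrix()],
#' via Cholesky factorization (no explicit inverse).
#'
#' @param model A `u5_model`; its `beta` must match `ncol(X)` and is applied
#'   in column order of `X`.
#' @param X Design matrix (first column the intercept).
#' @param y Response vector of observed proportions.
#' @param points Data frame with `lon`, `lat`, `time` for the rows of `X`.
#' @return The log marginal likelihood (a scalar).
#' @export
log_marginal_likelihood <- function(model, X, y, points) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), nrow(points) == nrow(X),
            length(model$beta) == ncol(X))
  K <- build_cov_matrix(points, model)
  r <- y - drop(X %*% model$beta)
  gauss_loglik_chol(K, r)
}

## log N(r; 0, K) via Cholesky with jitter fallback
gauss_loglik_chol <- function(K, r) {
  ch <- chol_jitter(K)
  z <- backsolve(ch$R, r, transpose = TRUE)
  -0.5 * length(r) * log(2 * pi) - sum(log(diag(ch$R))) - 0.5 * sum(z * z)
}
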