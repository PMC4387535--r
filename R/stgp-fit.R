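## ---- internal machinery for maximum marginal-likelihood fitting ----------
##
## Parameters are optimized on unconstrained scales:
##   theta = (log sigma2, log kappa, atanh rho, log nugget)
## with the fixed effects beta profiled out in closed form (generalized least
## squares) at every evaluation. Gradients of the profile negative
## log-likelihood are analytic (envelope theorem), using
##   d/dlogkappa [ (kd) K1(kd) ] = -(kd)^2 K0(kd).

## Precompute geometry shared by all likelihood evaluations.
fit_workspace <- function(points, X, y) {
  n <- nrow(points)
  d <- dist_degrees(cbind(points$lon, points$lat))
  tl <- abs(outer(points$time, points$time, "-"))
  lt <- which(lower.tri(d))
  list(n = n, X = as.matrix(X), y = y,
       d_lt = d[lt], tl_lt = tl[lt], lt = lt, d = d, tl = tl)
}

## Build K from theta using the triangle vectors; returns full matrix.
theta_cov <- function(ws, th) {
  sigma2 <- exp(th[1]); kappa <- exp(th[2])
  rho <- tanh(th[3]); nugget <- exp(th[4])
  x <- kappa * ws$d_lt
  m <- numeric(length(x))
  pos <- x > 0
  m[pos] <- x[pos] * besselK(x[pos], 1)
  m[!pos] <- 1
  k_lt <- sigma2 * m * rho^ws$tl_lt
  K <- matrix(0, ws$n, ws$n)
  K[ws$lt] <- k_lt
  K <- K + t(K)
  diag(K) <- sigma2 + nugget
  list(K = K, m_lt = m, sigma2 = sigma2, kappa = kappa, rho = rho,
       nugget = nugget)
}

## Profile negative log-likelihood and its gradient; returns both plus the
## GLS pieces so callers can reuse them.
profile_nll <- function(ws, th, want_grad = TRUE) {
  cv <- theta_cov(ws, th)
  ch <- tryCatch(chol_jitter(cv$K), error = function(e) NULL)
  if (is.null(ch)) return(list(nll = 1e10, grad = rep(0, 4)))
  R <- ch$R
  u <- backsolve(R, ws$y, transpose = TRUE)
  V <- backsolve(R, ws$X, transpose = TRUE)
  A <- crossprod(V)
  b <- drop(crossprod(V, u))
  beta <- solve(A, b)
  quad <- sum(u * u) - sum(b * beta)
  nll <- 0.5 * (ws$n * log(2 * pi) + quad) + sum(log(diag(R)))
  out <- list(nll = nll, beta = beta, R = R, A = A, cv = cv)
  if (!want_grad) return(out)

  ## alpha = K^{-1} (y - X beta); Kinv for the trace terms
  alpha <- backsolve(R, u - drop(V %*% beta))
  Kinv <- chol2inv(R)
  ao <- tcrossprod(alpha)
  a_lt <- ao[ws$lt]; ki_lt <- Kinv[ws$lt]
  a_dg <- diag(ao); ki_dg <- diag(Kinv)

  sigma2 <- cv$sigma2; rho <- cv$rho; nugget <- cv$nugget
  k_lt <- sigma2 * cv$m_lt * rho^ws$tl_lt

  ## gradient entry from triangle (dk_lt) and diagonal (dk_dg) derivatives
  gent <- function(dk_lt, dk_dg) {
    -0.5 * (2 * sum(dk_lt * a_lt) + sum(dk_dg * a_dg)) +
      0.5 * (2 * sum(dk_lt * ki_lt) + sum(dk_dg * ki_dg))
  }
  x <- cv$kappa * ws$d_lt
  dm_lk <- numeric(length(x))
  pos <- x > 0
  dm_lk[pos] <- -(x[pos]^2) * besselK(x[pos], 0)
  drho_lt <- sigma2 * cv$m_lt * ws$tl_lt * rho^pmax(ws$tl_lt - 1, 0)
  g <- c(
    gent(k_lt, rep(sigma2, ws$n)),                       # log sigma2
    gent(sigma2 * dm_lk * rho^ws$tl_lt, rep(0, ws$n)),   # log kappa
    gent(drho_lt, rep(0, ws$n)) * (1 - rho^2),           # atanh rho
    gent(rep(0, length(k_lt)), rep(nugget, ws$n))        # log nugget
  )
  out$grad <- g
  out$alpha <- alpha
  out$Kinv <- Kinv
  out
}

## Dispersed optimizer starting points (documented, deterministic).
fit_starts <- function(v, dmax, n_starts) {
  grid <- list(
    c(0.5, 1 / 4, 0.0, 0.5),
    c(0.2, 1 / 10, 0.3, 0.8),
    c(0.8, 1 / 2, -0.3, 0.2),
    c(0.05, 1 / 20, 0.0, 0.95),
    c(1.0, 1 / 8, 0.6, 0.1))
  lapply(grid[seq_len(min(n_starts, length(grid)))], function(s) {
    c(log(s[1] * v), log(sqrt(8) / (s[2] * dmax)), atanh(s[3]),
      log(s[4] * v))
  })
}

#' Fit the space-time geostatistical model
#'
#' Maximum marginal-likelihood estimation of the separable Matern(nu = 1)
#' x AR(1) Gaussian process with nugget and linear fixed effects, on the
#' identity (proportion) scale. The fixed effects are profiled out by
#' generalized least squares at every covariance-parameter evaluation;
#' the four covariance parameters are optimized by bounded quasi-Newton
#' (L-BFGS-B with analytic gradients) on log / atanh scales from several
#' dispersed starting points. Uncertainty is Laplace-style: the inverse of a
#' numerically differentiated Hessian on the transformed scale, with Gaussian
#' 5% / 50% / 95% quantiles back-transformed to natural scales; fixed-effect
#' covariance is the exact GLS expression given the covariance parameters.
#' DIC is reported as \eqn{D(\hat\theta) + 2 p_D}, with the effective number
#' of parameters \eqn{p_D} computed from the trace of the Gaussian smoother
#' (hat) matrix.
#'
#' @param data Data frame with `lon`, `lat`, `time` (integer wave),
#'   the response column, and one column per selected covariate (see
#'   [extract_covariates()]). At least 50 rows.
#' @param covariates Character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param response Response column name (default `"p_under5"`).
#' @param n_starts Number of dispersed optimizer starts (1-5, default 5).
#' @param max_iter L-BFGS-B iteration cap per start.
#' @param min_clusters Minimum rows required (default 50).
#' @param laplace Compute the Laplace (inverse-Hessian) uncertainty for the
#'   covariance parameters (default TRUE). When FALSE, their `sd` and
#'   quantile columns are NA; fixed-effect uncertainty (exact GLS) is always
#'   available.
#' @param range_floor_q Quantile of the pairwise-distance distribution used
#'   as the lower bound for the nominal range (default 0.01). Ranges below
#'   the distances the sampling design resolves are statistically
#'   indistinguishable from the nugget; the floor keeps the two variance
#'   components identifiable.
#' @return An object of class `u5_fit`: the fitted `u5_model`, a
#'   `summaries` tibble (per-parameter mean, sd, 5% / 50% / 95% quantiles),
#'   `loglik`, `dic`, `p_d`, convergence info, and the training data pieces
#'   needed for prediction.
#' @seealso [predict.u5_fit()], [predict_points()], [compare_models()],
#'   [generics::tidy()], [generics::glance()].
#' @export
stgp_fit <- function(data, covariates = character(), response = "p_under5",
                     n_starts = 5, max_iter = 100, min_clusters = 50,
                     laplace = TRUE, range_floor_q = 0.01) {
  stopifnot(all(c("lon", "lat", "time", response) %in% names(data)),
            all(covariates %in% names(data)))
  if (nrow(data) < min_clusters) {
    stop(sprintf("need at least %d clusters, got %d", min_clusters,
                 nrow(data)))
  }
  data <- tibble::as_tibble(data)
  y <- data[[response]]
  X <- cbind(intercept = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  points <- data[, c("lon", "lat", "time")]
  ws <- fit_workspace(points, X, y)

  ols <- stats::lm.fit(ws$X, y)
  v <- max(sum(ols$residuals^2) / ws$n, 1e-12)
  dmax <- max(ws$d_lt)
  ## identifiability guard: a nominal range below the distances the design
  ## actually resolves is indistinguishable from the nugget, so the range is
  ## floored at the `range_floor_q` quantile of pairwise distances
  range_floor <- max(dmax / 200,
                     stats::quantile(ws$d_lt, range_floor_q, names = FALSE))
  lb <- c(log(v) - 16, log(sqrt(8) / (20 * dmax)), atanh(-0.98),
          log(v) - 16)
  ub <- c(log(v) + 3, log(sqrt(8) / range_floor), atanh(0.98), log(v) + 3)

  cache <- new.env(parent = emptyenv())
  fn <- function(th) {
    key <- paste(format(th, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$val <- profile_nll(ws, th, want_grad = TRUE)
      cache$key <- key
    }
    cache$val$nll
  }
  gr <- function(th) {
    fn(th)
    cache$val$grad
  }

  best <- NULL
  n_iter <- 0
  for (st in fit_starts(v, dmax, n_starts)) {
    st <- pmin(pmax(st, lb), ub)
    opt <- tryCatch(
      stats::optim(st, fn, gr, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = max_iter, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(opt)) next
    n_iter <- n_iter + opt$counts[1]
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimizer failed from every start")

  th <- best$par
  pf <- profile_nll(ws, th, want_grad = TRUE)
  loglik <- -pf$nll
  beta <- stats::setNames(drop(pf$beta), colnames(ws$X))
  cov_beta <- solve(pf$A)
  model <- stgp_model(beta = beta, sigma2 = pf$cv$sigma2,
                      kappa = pf$cv$kappa, nugget = pf$cv$nugget,
                      rho = pf$cv$rho)

  ## Laplace covariance of theta from the numeric Hessian of the profile nll
  if (laplace) {
    H <- pracma::hessian(function(t) profile_nll(ws, t, want_grad = FALSE)$nll,
                         th)
    cov_theta <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    hess_ok <- !is.null(cov_theta) && all(diag(cov_theta) > 0)
  } else {
    cov_theta <- NULL
    hess_ok <- FALSE
  }
  if (!hess_ok) {
    sd_theta <- rep(NA_real_, 4)
  } else {
    sd_theta <- sqrt(diag(cov_theta))
  }

  ## effective number of parameters: trace of the hat matrix mapping y to
  ## fitted latent values, p_D = p + tr(Kf Kinv) - tr(Kf Kinv H_beta)
  Kf <- pf$cv$K
  diag(Kf) <- diag(Kf) - pf$cv$nugget
  W <- pf$Kinv %*% ws$X
  p_d <- ncol(ws$X) + sum(Kf * pf$Kinv) -
    sum(diag(cov_beta %*% (t(W) %*% Kf %*% W)))
  dic <- -2 * loglik + 2 * p_d

  summaries <- fit_summaries(beta, cov_beta, th, sd_theta)

  structure(
    list(model = model, summaries = summaries,
         loglik = loglik, dic = dic, p_d = p_d,
         marginal_lik_note = paste(
           "loglik is the Gaussian-process marginal likelihood over the",
           "latent field at the optimized covariance parameters"),
         convergence = list(status = best$convergence,
                            message = best$message,
                            iterations = unname(n_iter),
                            hessian_ok = hess_ok),
         theta = th, cov_theta = if (hess_ok) cov_theta else NULL,
         cov_beta = cov_beta,
         data = data, response = response, covariates = covariates,
         X = ws$X, y = y, points = points,
         chol_R = pf$R, alpha = pf$alpha),
    class = "u5_fit")
}

## Table-style parameter summary: mean, sd, 5/50/95 quantiles. Covariance
## parameters are summarized by back-transforming Gaussian quantiles on the
## optimization scale (monotone transforms), with delta-method sd.
fit_summaries <- function(beta, cov_beta, th, sd_theta) {
  z <- stats::qnorm(c(0.05, 0.5, 0.95))
  beta_sd <- sqrt(diag(cov_beta))
  rows_beta <- tibble::tibble(
    parameter = names(beta), mean = unname(beta), sd = beta_sd,
    q5 = beta + z[1] * beta_sd, q50 = beta, q95 = beta + z[3] * beta_sd)
  tr <- list(
    list(name = "rho", f = tanh, df = function(t) 1 - tanh(t)^2, i = 3),
    list(name = "nugget", f = exp, df = exp, i = 4),
    list(name = "sigma2", f = exp, df = exp, i = 1),
    list(name = "range_deg",
         f = function(t) sqrt(8) * exp(-t),
         df = function(t) sqrt(8) * exp(-t), i = 2))
  rows_theta <- purrr::map_dfr(tr, function(p) {
    t0 <- th[p$i]; s0 <- sd_theta[p$i]
    q <- sort(p$f(t0 + z * s0))
    tibble::tibble(parameter = p$name, mean = p$f(t0),
                   sd = abs(p$df(t0)) * s0,
                   q5 = q[1], q50 = p$f(t0), q95 = q[3])
  })
  dplyr::bind_rows(rows_beta, rows_theta)
}

#' @export
print.u5_fit <- function(x, ...) {
  cat(sprintf("<u5_fit> n = %d clusters, %d covariates\n",
              length(x$y), length(x$covariates)))
  cat(sprintf("  loglik %.3f, DIC %.3f, p_D %.2f, convergence %d\n",
              x$loglik, x$dic, x$p_d, x$convergence$status))
  print(as.data.frame(x$summaries), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted-parameter summary table
#'
#' @param x A `u5_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `parameter`, `mean`, `sd`,
#'   `q5`, `q50`, `q95` (90% central interval endpoints).
#' @method tidy u5_fit
#' @export
tidy.u5_fit <- function(x, ...) x$summaries

#' One-row model-level summary
#'
#' @param x A `u5_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `loglik`, `dic`, `p_d`, `sigma2`, `nugget`,
#'   `rho`, `range_deg`, `converged`.
#' @method glance u5_fit
#' @export
glance.u5_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$y), loglik = x$loglik, dic = x$dic, p_d = x$p_d,
    sigma2 = x$model$sigma2, nugget = x$model$nugget, rho = x$model$rho,
    range_deg = range_from_kappa(x$model$kappa),
    converged = x$convergence$status == 0)
}

#' Kriging prediction at arbitrary points
#'
#' Universal-kriging conditional mean and standard deviation of the latent
#' proportion at new space-time points, given a fitted model:
#' \eqn{\mu^* = x^{*\prime}\beta + k^{*\prime} K^{-1} (y - X\beta)} and
#' \eqn{v^* = \sigma^2 - k^{*\prime} K^{-1} k^* + m' (X'K^{-1}X)^{-1} m}
#' with \eqn{m = x^* - X'K^{-1}k^*} (the fixed-effect uncertainty term,
#' optional).
#'
#' @param fit A `u5_fit`.
#' @param newdata Data frame with `lon`, `lat`, `time` and every covariate
#'   column used in the fit.
#' @param level Central credible level for `lower` / `upper` (default 0.95).
#' @param include_beta_var Include the fixed-effect uncertainty term
#'   (default TRUE).
#' @return A tibble: `mean`, `sd`, `lower`, `upper` (unclipped latent scale).
#' @export
predict_points <- function(fit, newdata, level = 0.95,
                           include_beta_var = TRUE) {
  stopifnot(inherits(fit, "u5_fit"),
            all(c("lon", "lat", "time") %in% names(newdata)),
            all(fit$covariates %in% names(newdata)))
  Xs <- cbind(intercept = 1,
              as.matrix(tibble::as_tibble(newdata)[, fit$covariates,
                                                   drop = FALSE]))
  m <- nrow(newdata)
  d <- dist_degrees(cbind(fit$points$lon, fit$points$lat),
                    cbind(newdata$lon, newdata$lat))
  tl <- abs(outer(fit$points$time, newdata$time, "-"))
  kstar <- matrix(matern_cov(c(d), fit$model$sigma2, fit$model$kappa),
                  nrow(d), ncol(d)) * fit$model$rho^tl
  mu <- drop(Xs %*% fit$model$beta) + drop(crossprod(kstar, fit$alpha))
  ## latent variance via the stored Cholesky factor
  Vk <- backsolve(fit$chol_R, kstar, transpose = TRUE)
  var_lat <- pmax(0, fit$model$sigma2 - colSums(Vk * Vk))
  if (include_beta_var) {
    KinvX <- backsolve(fit$chol_R,
                       backsolve(fit$chol_R, fit$X, transpose = TRUE))
    M <- t(Xs) - crossprod(KinvX, kstar)   # p x m
    var_lat <- var_lat + colSums(M * (fit$cov_beta %*% M))
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  sdv <- sqrt(var_lat)
  tibble::tibble(mean = mu, sd = sdv,
                 lower = mu - zq * sdv, upper = mu + zq * sdv)
}

#' Predict a gridded proportion surface
#'
#' Applies [predict_points()] over every valid cell of a covariate stack at a
#' given survey wave, in memory-bounded tiles, producing per-cell posterior
#' mean and central credible bounds. Cells without covariates (masked out)
#' propagate nodata. Values are clipped to \[0, 1\] by default, with the
#' number of clipped cells recorded.
#'
#' @param object A `u5_fit`.
#' @param stack A `u5_stack` covering the covariates used in the fit.
#' @param wave Integer wave index to predict at (within 1 of observed waves).
#' @param level Central credible level (default 0.95; 0.90 matches the
#'   5%-95% summary-table style).
#' @param include_beta_var Include fixed-effect uncertainty (default TRUE).
#' @param clip Clip mean/bounds to \[0, 1\] (default TRUE; count recorded).
#' @param tile Cells per prediction tile (default 4000).
#' @param ... Unused.
#' @return An object of class `u5_surface`: `grid`, `time`, `level`, matrices
#'   `mean`, `lower`, `upper`, and `n_clipped`.
#' @export
predict.u5_fit <- function(object, stack, wave, level = 0.95,
                           include_beta_var = TRUE, clip = TRUE,
                           tile = 4000, ...) {
  stopifnot(inherits(stack, "u5_stack"))
  if (min(abs(wave - unique(object$points$time))) > 1) {
    stop("prediction wave is more than one wave outside the observed range")
  }
  miss <- setdiff(object$covariates, names(stack$layers))
  if (length(miss)) stop("stack lacks covariates: ",
                         paste(miss, collapse = ", "))
  grid <- stack$grid
  co <- grid_coords(grid)
  valid <- which(c(stack$mask))
  mean_m <- lower_m <- upper_m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  for (start in seq(1, length(valid), by = tile)) {
    idx <- valid[start:min(start + tile - 1, length(valid))]
    nd <- tibble::tibble(lon = co$x[idx], lat = co$y[idx],
                         time = as.integer(wave))
    for (nm in object$covariates) nd[[nm]] <- stack$layers[[nm]][idx]
    pr <- predict_points(object, nd, level = level,
                         include_beta_var = include_beta_var)
    mean_m[idx] <- pr$mean
    lower_m[idx] <- pr$lower
    upper_m[idx] <- pr$upper
  }
  n_clipped <- 0L
  if (clip) {
    vals <- c(mean_m[valid], lower_m[valid], upper_m[valid])
    n_clipped <- sum(vals < 0 | vals > 1, na.rm = TRUE)
    mean_m[] <- pmin(1, pmax(0, mean_m))
    lower_m[] <- pmin(1, pmax(0, lower_m))
    upper_m[] <- pmin(1, pmax(0, upper_m))
  }
  structure(list(grid = grid, time = as.integer(wave), level = level,
                 mean = mean_m, lower = lower_m, upper = upper_m,
                 n_clipped = n_clipped),
            class = "u5_surface")
}

#' @export
print.u5_surface <- function(x, ...) {
  v <- x$mean[!is.na(x$mean)]
  cat(sprintf(
    "<u5_surface> wave %d, %d x %d, level %.2f, mean range [%.4f, %.4f], %d clipped\n",
    x$time, x$grid$n_rows, x$grid$n_cols, x$level, min(v), max(v),
    x$n_clipped))
  invisible(x)
}

#' @rdname predict.u5_fit
#' @param x A `u5_surface`.
#' @return For `as_tibble`: tibble with `row`, `col`, `x`, `y`, `mean`,
#'   `lower`, `upper`, `width`.
#' @method as_tibble u5_surface
#' @export
as_tibble.u5_surface <- function(x, ...) {
  out <- grid_coords(x$grid)   # its `x` column would mask the argument in
  out$mean <- c(x$mean)        # a data-masked verb, so assign directly
  out$lower <- c(x$lower)
  out$upper <- c(x$upper)
  out$width <- c(x$upper) - c(x$lower)
  out
}

#' Map a prediction surface
#'
#' @param object A `u5_surface`.
#' @param what One of `"mean"` or `"width"` (upper minus lower bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot u5_surface
#' @export
autoplot.u5_surface <- function(object, what = c("mean", "width"), ...) {
  what <- match.arg(what)
  df <- as_tibble.u5_surface(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = what,
                  title = sprintf("Under-5 proportion (%s), wave %d",
                                  what, object$time))
}

#' Compare fitted models by DIC
#'
#' Ranks a set of fits of different covariate combinations (on the same
#' response data) by DIC, with log-likelihood breaking ties.
#'
#' @param fits Named list of `u5_fit` objects sharing the response vector.
#' @return A tibble: `model`, `covariates`, `dic`, `p_d`, `loglik`,
#'   `delta_dic`, `rank`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  y0 <- fits[[1]]$y
  for (f in fits) {
    if (!isTRUE(all.equal(f$y, y0))) {
      stop("fits were made on different response vectors")
    }
  }
  if (is.null(names(fits))) names(fits) <- paste0("model_", seq_along(fits))
  out <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm,
                   covariates = paste(f$covariates, collapse = "+"),
                   dic = f$dic, p_d = f$p_d, loglik = f$loglik)
  })
  out <- dplyr::arrange(out, .data$dic, dplyr::desc(.data$loglik))
  dplyr::mutate(out, delta_dic = .data$dic - .data$dic[1],
                rank = dplyr::row_number())
}
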