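# Independent brute-force oracles and tiny fixture builders. The oracles
# deliberately avoid the package's computational paths (Cholesky solves):
# they use eigen decompositions and explicit inverses on small instances.

# scalar, loop-based space-time covariance matrix
oracle_cov_matrix <- function(points, model, nugget = TRUE) {
  n <- nrow(points)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      h <- sqrt((points$lon[i] - points$lon[j])^2 +
                  (points$lat[i] - points$lat[j])^2)
      K[i, j] <- st_cov(h, points$time[i] - points$time[j], model)
      if (nugget && i == j) K[i, j] <- K[i, j] + model$nugget
    }
  }
  K
}

# multivariate normal log-density via eigen decomposition
oracle_mvn_logdens <- function(y, mu, K) {
  e <- eigen(K, symmetric = TRUE)
  r <- y - mu
  z <- t(e$vectors) %*% r
  -0.5 * length(y) * log(2 * pi) - 0.5 * sum(log(e$values)) -
    0.5 * sum(z^2 / e$values)
}

# kriging mean/variance at one point via explicit inverse
oracle_krige <- function(K, kstar, xstar, X, beta, y, sigma2,
                         cov_beta = NULL) {
  Kinv <- solve(K)
  mu <- sum(xstar * beta) + drop(t(kstar) %*% Kinv %*% (y - X %*% beta))
  v <- sigma2 - drop(t(kstar) %*% Kinv %*% kstar)
  if (!is.null(cov_beta)) {
    m <- xstar - drop(t(X) %*% Kinv %*% kstar)
    v <- v + drop(t(m) %*% cov_beta %*% m)
  }
  list(mean = mu, var = v)
}

# delete-one conditional Gaussian density (CPO) by direct conditioning
oracle_cpo <- function(i, K, X, beta, y) {
  mu_all <- drop(X %*% beta)
  ki <- K[-i, i]
  Kmm <- K[-i, -i]
  w <- solve(Kmm, ki)
  mu <- mu_all[i] + sum(w * (y[-i] - mu_all[-i]))
  v <- K[i, i] - sum(w * ki)
  dnorm(y[i], mu, sqrt(v))
}

# exhaustive best-subset via stats::lm / stats::logLik (independent route)
oracle_best_subset <- function(data, response, candidates) {
  p <- length(candidates)
  best <- NULL
  for (code in 0:(2^p - 1)) {
    s <- candidates[bitwAnd(code, 2^(seq_len(p) - 1)) > 0]
    f <- if (length(s)) {
      stats::lm(stats::reformulate(s, response), data = data)
    } else {
      stats::lm(stats::reformulate("1", response), data = data)
    }
    b <- -2 * as.numeric(stats::logLik(f)) + (length(s) + 2) * log(nrow(data))
    if (is.null(best) || b < best$bic - 1e-12) {
      best <- list(subset = sort(s), bic = b)
    }
  }
  best
}

# small covariate stack + survey for fit-level tests
tiny_stack <- function(grid_size = 30, cell = 0.25, seed = 42) {
  gen_covariate_stack(raster_grid(0, 0, cell, grid_size, grid_size),
                      seed = seed, mask_frac = 0)
}

# u5_fit object with KNOWN covariance parameters (no optimizer): computes the
# GLS beta and the pieces predict_points()/loo_cpo() need, so prediction
# formulas can be tested in isolation from estimation.
fit_with_known_model <- function(model, data, covariates,
                                 response = "p_under5") {
  X <- cbind(intercept = 1, as.matrix(data[, covariates, drop = FALSE]))
  y <- data[[response]]
  points <- data[, c("lon", "lat", "time")]
  K <- build_cov_matrix(points, model)
  R <- chol(K)
  u <- backsolve(R, y, transpose = TRUE)
  V <- backsolve(R, X, transpose = TRUE)
  A <- crossprod(V)
  beta <- solve(A, drop(crossprod(V, u)))
  model$beta <- stats::setNames(drop(beta), colnames(X))
  alpha <- backsolve(R, u - drop(V %*% beta))
  structure(
    list(model = model, cov_beta = solve(A), data = tibble::as_tibble(data),
         response = response, covariates = covariates, X = X, y = y,
         points = points, chol_R = R, alpha = alpha,
         loglik = NA_real_, dic = NA_real_, p_d = NA_real_,
         convergence = list(status = 0L)),
    class = "u5_fit")
}
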