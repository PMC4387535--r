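test_that("holdout split sizes, reproducibility and stratification", {
  cl <- tibble::tibble(id = 1:1624, urban = rep(c(TRUE, FALSE), c(500, 1124)))
  sp <- holdout_split(cl, 0.10, seed = 5)
  expect_equal(nrow(sp$test), 162)
  expect_equal(nrow(sp$train), 1462)
  expect_identical(sp$holdout_ids, holdout_split(cl, 0.10, seed = 5)$holdout_ids)
  expect_false(identical(sp$holdout_ids, holdout_split(cl, 0.10, 6)$holdout_ids))
  sp2 <- holdout_split(tibble::tibble(x = 1:10), 0.5, seed = 1)
  expect_equal(nrow(sp2$test), 5)
  expect_equal(nrow(sp2$train), 5)
  spu <- holdout_split(cl, 0.10, seed = 7, stratify_urban = TRUE)
  expect_equal(sum(spu$test$urban), 50)
  expect_error(holdout_split(cl, 0.6))
})

test_that("holdout metrics reproduce hand-computed values and identities", {
  m <- holdout_metrics(c(0.1, 0.2, 0.3), c(0.12, 0.18, 0.33))
  expect_equal(m$mpe, 0.01, tolerance = 1e-12)
  expect_equal(m$mae, 0.07 / 3, tolerance = 1e-10)
  expect_equal(m$rmse, sqrt(0.0017 / 3), tolerance = 1e-10)
  ## exact agreement and constant shift
  obs <- c(0.1, 0.25, 0.4, 0.3)
  p <- holdout_metrics(obs, obs)
  expect_equal(c(p$mpe, p$mae, p$rmse), c(0, 0, 0))
  expect_equal(p$pearson_r, 1)
  s <- holdout_metrics(obs, obs + 0.05)
  expect_equal(c(s$mpe, s$mae, s$rmse), c(0.05, 0.05, 0.05))
  expect_equal(s$pearson_r, 1)
  expect_warning(holdout_metrics(obs, rep(0.2, 4)), "zero variance")
})

test_that("metric inequalities hold on fuzzed inputs", {
  set.seed(91)
  for (k in 1:50) {
    n <- sample(2:40, 1)
    obs <- runif(n); pred <- obs + rnorm(n, sd = 0.2)
    m <- holdout_metrics(obs, pred)
    expect_gte(m$mae, abs(m$mpe) - 1e-12)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
})

test_that("closed-form CPO equals the delete-one conditioning oracle", {
  set.seed(95)
  n <- 25
  d <- tibble::tibble(lon = runif(n, 0, 4), lat = runif(n, 0, 4),
                      time = sample(0:1, n, TRUE), a = rnorm(n))
  d$p_under5 <- 0.2 + 0.04 * d$a + rnorm(n, sd = 0.05)
  m <- stgp_model(beta = c(intercept = 0, a = 0), sigma2 = 0.004,
                  kappa = 1, nugget = 0.002, rho = 0.4)
  fit <- fit_with_known_model(m, d, "a")
  res <- loo_cpo(fit)
  K <- build_cov_matrix(d, m)
  for (i in seq_len(n)) {
    expect_equal(res$cpo[i],
                 oracle_cpo(i, K, fit$X, fit$model$beta, fit$y),
                 tolerance = 1e-8)
  }
  expect_true(all(res$cpo > 0))
})

test_that("an extreme outlier strictly decreases its own CPO", {
  set.seed(97)
  n <- 40
  d <- tibble::tibble(lon = runif(n, 0, 4), lat = runif(n, 0, 4), time = 0L)
  d$p_under5 <- rnorm(n, 0.2, 0.04)
  m <- stgp_model(beta = c(intercept = 0.2), sigma2 = 0.002, kappa = 1,
                  nugget = 0.001, rho = 0)
  base <- loo_cpo(fit_with_known_model(m, d, character()))
  d2 <- d
  d2$p_under5[7] <- 0.95
  out <- loo_cpo(fit_with_known_model(m, d2, character()))
  expect_lt(out$cpo[7], base$cpo[7])
})

test_that("iid-model CPO reduces to the documented closed form", {
  ## sigma2 = 0: CPO_i = N(y_i; x_i' beta_gls, nugget), beta held at the
  ## full-data estimate (no per-deletion adjustment)
  set.seed(101)
  n <- 30
  d <- tibble::tibble(lon = runif(n), lat = runif(n), time = 0L)
  d$p_under5 <- rnorm(n, 0.2, 0.05)
  m <- stgp_model(beta = c(intercept = 0), sigma2 = 0, kappa = 1,
                  nugget = 0.0025, rho = 0)
  fit <- fit_with_known_model(m, d, character())
  res <- loo_cpo(fit)
  expect_equal(res$cpo,
               dnorm(d$p_under5, mean(d$p_under5), sqrt(0.0025)),
               tolerance = 1e-10)
})

test_that("two-point semivariogram is the exact squared half-difference", {
  r <- c(0.3, 0.1)
  many <- c(r, rnorm(30, 0, 0.1))  # n >= 30 guard needs padding
  ## padding points sit on a coarse grid, pairwise spacing 5 > max_dist,
  ## so the only pair within range is (1, 2) at distance 1
  loc <- tibble::tibble(lon = c(0, 1, 100 + 5 * (0:29 %% 6)),
                        lat = c(0, 0, 100 + 5 * (0:29 %/% 6)))
  sv <- suppressWarnings(
    residual_semivariogram(many, loc, n_bins = 1, max_dist = 1.5,
                           n_perm = 19, seed = 1))
  ## only the (1,2) pair is within max_dist
  expect_equal(sv$n_pairs[1], 1L)
  expect_equal(sv$gamma[1], 0.5 * (0.3 - 0.1)^2)
})

test_that("pair counts are conserved across bins", {
  set.seed(103)
  n <- 60
  loc <- tibble::tibble(lon = runif(n, 0, 5), lat = runif(n, 0, 5))
  r <- rnorm(n)
  maxd <- 20  # beyond the largest separation: every pair binned
  sv <- suppressWarnings(
    residual_semivariogram(r, loc, n_bins = 10, max_dist = maxd,
                           n_perm = 9, seed = 2))
  expect_equal(sum(sv$n_pairs), n * (n - 1) / 2)
  expect_true(all(sv$lower[!sv$empty] <= sv$upper[!sv$empty]))
  expect_s3_class(autoplot(sv), "ggplot")
})

test_that("iid residuals stay inside the envelopes, GP residuals breach them", {
  set.seed(107)
  n <- 120
  loc <- tibble::tibble(lon = runif(n, 0, 10), lat = runif(n, 0, 10))
  inside <- numeric(8)
  for (k in 1:8) {
    sv <- residual_semivariogram(rnorm(n), loc, n_bins = 10, n_perm = 99,
                                 seed = 200 + k)
    ok <- !sv$empty
    inside[k] <- mean(sv$gamma[ok] >= sv$lower[ok] &
                        sv$gamma[ok] <= sv$upper[ok])
  }
  expect_gte(mean(inside), 0.9)
  ## strongly autocorrelated residuals: short-range bins drop below the
  ## lower envelope
  m <- stgp_model(beta = c(intercept = 0), sigma2 = 1, kappa = sqrt(8) / 3,
                  nugget = 0, rho = 0)
  breach <- 0
  reps <- 5
  for (k in seq_len(reps)) {
    gp <- sim_matern_gp(dplyr::mutate(loc, time = 0L), m, seed = 300 + k)
    sv <- residual_semivariogram(gp, loc, n_bins = 10, n_perm = 99,
                                 seed = 400 + k)
    if (any(sv$gamma[1:2] < sv$lower[1:2], na.rm = TRUE)) breach <- breach + 1
  }
  expect_gte(breach, reps - 1)  # >= 80%
})
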