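# Prediction-equation tests use fit_with_known_model() (helper) so the
# kriging algebra is exercised independently of the optimizer.

make_points <- function(n, seed, waves = 1, extent = 5) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, tibble::tibble(
    lon = runif(n, 0, extent), lat = runif(n, 0, extent),
    time = rep(seq_len(waves) - 1L, length.out = n)))
}

test_that("nugget-free kriging interpolates the observations exactly", {
  set.seed(43)
  n <- 30
  d <- make_points(n, 43)
  d$a <- rnorm(n)
  d$p_under5 <- 0.2 + 0.03 * d$a + rnorm(n, sd = 0.05)
  m <- stgp_model(beta = c(intercept = 0, a = 0), sigma2 = 0.01,
                  kappa = sqrt(8) / 2, nugget = 0, rho = 0)
  fit <- fit_with_known_model(m, d, "a")
  pr <- predict_points(fit, d)
  expect_equal(pr$mean, d$p_under5, tolerance = 1e-8)
  expect_lt(max(pr$sd^2), 1e-10)
})

test_that("predictions decay to the fixed-effects surface far from data", {
  set.seed(47)
  n <- 40
  d <- make_points(n, 47, extent = 2)
  d$p_under5 <- rnorm(n, 0.2, 0.05)
  m <- stgp_model(beta = c(intercept = 0.2), sigma2 = 0.004,
                  kappa = sqrt(8) / 0.5, nugget = 0.001, rho = 0)
  fit <- fit_with_known_model(m, d, character())
  far <- tibble::tibble(lon = 80, lat = 80, time = 0L)
  pr <- predict_points(fit, far, include_beta_var = FALSE)
  expect_equal(pr$mean, unname(fit$model$beta["intercept"]), tolerance = 1e-6)
  expect_equal(pr$sd^2, m$sigma2, tolerance = 1e-6)
})

test_that("kriging mean and variance match the explicit-inverse oracle", {
  set.seed(53)
  n <- 25
  d <- make_points(n, 53, waves = 2)
  d$a <- rnorm(n)
  d$p_under5 <- 0.2 + 0.05 * d$a + rnorm(n, sd = 0.06)
  m <- stgp_model(beta = c(intercept = 0, a = 0), sigma2 = 0.005,
                  kappa = 1.1, nugget = 0.002, rho = -0.3)
  fit <- fit_with_known_model(m, d, "a")
  K <- build_cov_matrix(d, m)
  newpts <- tibble::tibble(lon = runif(30, 0, 5), lat = runif(30, 0, 5),
                           time = sample(0:1, 30, replace = TRUE),
                           a = rnorm(30))
  pr <- predict_points(fit, newpts)
  pr0 <- predict_points(fit, newpts, include_beta_var = FALSE)
  for (j in seq_len(30)) {
    h <- sqrt((d$lon - newpts$lon[j])^2 + (d$lat - newpts$lat[j])^2)
    kstar <- st_cov(h, d$time - newpts$time[j], m)
    xstar <- c(1, newpts$a[j])
    orc <- oracle_krige(K, kstar, xstar, fit$X, fit$model$beta,
                        fit$y, m$sigma2, fit$cov_beta)
    orc0 <- oracle_krige(K, kstar, xstar, fit$X, fit$model$beta,
                         fit$y, m$sigma2)
    expect_equal(pr$mean[j], orc$mean, tolerance = 1e-8)
    expect_equal(pr$sd[j]^2, orc$var, tolerance = 1e-8)
    expect_equal(pr0$sd[j]^2, orc0$var, tolerance = 1e-8)
  }
})

test_that("prediction variance grows with distance from the data", {
  ## radial design: observations in a ring, predictions along a transect
  theta <- seq(0, 2 * pi, length.out = 41)[-41]
  d <- tibble::tibble(lon = cos(theta), lat = sin(theta), time = 0L,
                      p_under5 = rnorm(40, 0.2, 0.03))
  m <- stgp_model(beta = c(intercept = 0.2), sigma2 = 0.004,
                  kappa = sqrt(8) / 2, nugget = 0.001, rho = 0)
  fit <- fit_with_known_model(m, d, character())
  transect <- tibble::tibble(lon = seq(1, 8, by = 0.25), lat = 0, time = 0L)
  pr <- predict_points(fit, transect, include_beta_var = FALSE)
  expect_true(all(diff(pr$sd) > -1e-12))
})

test_that("gridded prediction matches pointwise prediction and clips safely", {
  st <- tiny_stack(12, seed = 61)
  sv <- simulate_survey(st, default_u5_model(), n_clusters = 80, n_waves = 2,
                        seed = 63)
  cl <- extract_covariates(sv$clusters, st)
  fit <- fit_with_known_model(default_u5_model(), cl, c("accessibility"))
  surf <- predict(fit, st, wave = 1, level = 0.95, tile = 37)
  expect_s3_class(surf, "u5_surface")
  expect_true(all(surf$lower <= surf$mean + 1e-12, na.rm = TRUE))
  expect_true(all(surf$mean <= surf$upper + 1e-12, na.rm = TRUE))
  expect_true(all(surf$mean >= 0 & surf$mean <= 1, na.rm = TRUE))
  ## tile boundaries do not change results
  surf2 <- predict(fit, st, wave = 1, level = 0.95, tile = 1000)
  expect_equal(surf$mean, surf2$mean, tolerance = 1e-12)
  ## spot-check one cell against predict_points
  co <- grid_coords(st$grid)
  i <- which(c(st$mask))[20]
  nd <- tibble::tibble(lon = co$x[i], lat = co$y[i], time = 1L,
                       accessibility = st$layers$accessibility[i])
  pr <- predict_points(fit, nd, level = 0.95)
  expect_equal(surf$mean[i], min(1, max(0, pr$mean)), tolerance = 1e-12)
  expect_error(predict(fit, st, wave = 5), "outside")
  expect_s3_class(autoplot(surf), "ggplot")
  expect_s3_class(autoplot(surf, "width"), "ggplot")
})

test_that("pure-noise data drives the fitted spatial variance to zero", {
  ## generator has sigma2 = 0: the fit should attribute variance to the
  ## nugget, recover beta within 3 SE, and shrink sigma2 to noise level
  st <- tiny_stack(25, cell = 0.4, seed = 67)
  m0 <- stgp_model(beta = c(intercept = 0.18, accessibility = 0.03),
                   sigma2 = 0, kappa = sqrt(8) / 2, nugget = 0.0025, rho = 0)
  ok_beta <- 0; ok_s2 <- 0
  reps <- 10
  for (k in seq_len(reps)) {
    sv <- simulate_survey(st, m0, n_clusters = 250, n_waves = 1,
                          seed = 700 + k)
    cl <- extract_covariates(sv$clusters, st)
    f <- stgp_fit(cl, "accessibility", n_starts = 2, laplace = FALSE)
    se <- sqrt(diag(f$cov_beta))
    if (all(abs(f$model$beta - m0$beta[names(f$model$beta)]) <= 3 * se)) {
      ok_beta <- ok_beta + 1
    }
    if (f$model$sigma2 < f$model$nugget / 10) ok_s2 <- ok_s2 + 1
  }
  expect_gte(ok_beta, reps - 2)
  expect_gte(ok_s2, reps - 1)  # >= 90%
})

test_that("a rho = 0 fit reproduces the pooled pure-spatial likelihood", {
  set.seed(71)
  n <- 60
  d <- make_points(n, 71, waves = 3)
  d$p_under5 <- rnorm(n, 0.2, 0.05)
  m <- stgp_model(beta = c(intercept = 0.2), sigma2 = 0.003, kappa = 1,
                  nugget = 0.002, rho = 0)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  ll_st <- log_marginal_likelihood(m, X, d$p_under5, d)
  pooled <- dplyr::mutate(d, time = 0L)
  ## with rho = 0 there is no cross-wave covariance: separated waves behave
  ## like independent spatial datasets, but pooling changes within-wave
  ## pairs; instead compare against the block-diagonal oracle
  ll_blocks <- sum(vapply(split(seq_len(n), d$time), function(idx) {
    oracle_mvn_logdens(d$p_under5[idx], rep(0.2, length(idx)),
                       oracle_cov_matrix(d[idx, ], m))
  }, numeric(1)))
  expect_equal(ll_st, ll_blocks, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(
    ll_st, log_marginal_likelihood(m, X, d$p_under5, pooled))))
})

test_that("model comparison ranks by DIC and rejects mismatched responses", {
  st <- tiny_stack(20, seed = 73)
  m <- default_u5_model()
  sv <- simulate_survey(st, m, n_clusters = 150, n_waves = 2, seed = 75)
  cl <- extract_covariates(sv$clusters, st)
  f1 <- stgp_fit(cl, c("accessibility", "evi"), n_starts = 2,
                 laplace = FALSE)
  f2 <- stgp_fit(cl, c("accessibility"), n_starts = 2, laplace = FALSE)
  cmp <- compare_models(list(ae = f1, a = f2, dup = f1))
  expect_equal(nrow(cmp), 3)
  expect_true(all(is.finite(cmp$dic)))
  expect_true(!is.unsorted(cmp$dic))
  expect_equal(cmp$delta_dic[1], 0)
  ## duplicate fits tie exactly
  expect_equal(cmp$dic[cmp$model == "ae"], cmp$dic[cmp$model == "dup"])
  cl2 <- cl
  cl2$p_under5 <- rev(cl2$p_under5)
  f3 <- stgp_fit(cl2, "accessibility", n_starts = 1, laplace = FALSE)
  expect_error(compare_models(list(f1, f3)), "different response")
})

test_that("tidy and glance expose the summary tables", {
  st <- tiny_stack(15, seed = 81)
  sv <- simulate_survey(st, default_u5_model(), n_clusters = 100,
                        n_waves = 2, seed = 83)
  cl <- extract_covariates(sv$clusters, st)
  f <- stgp_fit(cl, "accessibility", n_starts = 2)
  td <- tidy(f)
  expect_true(all(c("intercept", "accessibility", "rho", "nugget", "sigma2",
                    "range_deg") %in% td$parameter))
  expect_true(all(td$q5 <= td$q50 & td$q50 <= td$q95, na.rm = TRUE))
  gl <- glance(f)
  expect_equal(gl$n, 100)
  expect_gte(f$p_d, 0)
  expect_equal(gl$dic, -2 * f$loglik + 2 * f$p_d)
})
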