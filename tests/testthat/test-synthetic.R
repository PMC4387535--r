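test_that("covariate stack standardizes continuous layers over the mask", {
  g <- raster_grid(3, 4, 0.2, 50, 50)
  st <- gen_covariate_stack(g, seed = 1)
  for (nm in c("accessibility", "evi", "nightlights")) {
    v <- st$layers[[nm]][st$mask]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  lc <- st$layers$landcover[st$mask]
  expect_true(all(lc %in% 0:5))
  ## urban indicator derivable from the nightlights 90th percentile
  urb <- urban_mask(st)
  expect_equal(mean(urb[st$mask]), 0.1, tolerance = 0.02)
  ## masked-in cells are finite
  for (l in st$layers) expect_true(all(is.finite(l[st$mask])))
})

test_that("covariate stack is seed-deterministic and seed-sensitive", {
  g <- raster_grid(0, 0, 0.2, 50, 50)
  a <- gen_covariate_stack(g, seed = 1)
  b <- gen_covariate_stack(g, seed = 1)
  expect_identical(a$layers, b$layers)
  expect_identical(a$mask, b$mask)
  c_ <- gen_covariate_stack(g, seed = 2)
  expect_false(identical(a$layers, c_$layers))
  expect_error(gen_covariate_stack(raster_grid(0, 0, 1, 1, 1), seed = 1),
               "degenerate")
})

test_that("Matern GP draws reproduce the theoretical covariance at a point pair", {
  ## two fixed points, many replicate draws: empirical covariance within 5%
  m <- stgp_model(beta = c(intercept = 0), sigma2 = 1,
                  kappa = sqrt(8) / 2, nugget = 0, rho = 0)
  pts <- tibble::tibble(lon = c(0, 0.7), lat = c(0, 0), time = c(0L, 0L))
  draws <- sim_matern_gp(pts, m, seed = 10, n = 5000)
  emp <- cov(t(draws))
  theo <- st_cov(0.7, 0, m)
  expect_equal(emp[1, 2], theo, tolerance = 0.05)
  expect_equal(emp[1, 1], 1, tolerance = 0.05)
  ## degenerate and deterministic cases
  m0 <- stgp_model(beta = c(intercept = 0), sigma2 = 0,
                   kappa = 1, nugget = 0, rho = 0)
  expect_identical(sim_matern_gp(pts, m0, seed = 1), c(0, 0))
  expect_identical(sim_matern_gp(pts, m, seed = 3),
                   sim_matern_gp(pts, m, seed = 3))
})

test_that("displacement respects urban/rural caps and the far-rural fraction", {
  n <- 10000
  lon <- runif(n, 3, 10); lat <- runif(n, 4, 11)
  ## urban: never beyond 2 km
  d_urb <- displace_location(lon, lat, urban = rep(TRUE, n), seed = 1)
  km <- sqrt((d_urb$lon - lon)^2 + (d_urb$lat - lat)^2) * KM_PER_DEGREE
  expect_lte(max(km), 2 + 1e-6)
  ## rural: caps at 5 km except ~1% up to 10 km
  d_rur <- displace_location(lon, lat, urban = rep(FALSE, n), seed = 2)
  km <- sqrt((d_rur$lon - lon)^2 + (d_rur$lat - lat)^2) * KM_PER_DEGREE
  expect_lte(max(km), 10 + 1e-6)
  expect_lt(abs(mean(d_rur$far) - 0.01), 0.005)
  expect_lte(mean(km > 5), mean(d_rur$far))  # only far clusters can exceed 5 km
  ## zero caps leave coordinates untouched; same seed reproduces
  d0 <- displace_location(lon, lat, rep(FALSE, n), seed = 3,
                          rural_max_km = 0, far_max_km = 0)
  expect_equal(d0$lon, lon)
  expect_equal(d0$lat, lat)
  expect_identical(displace_location(lon, lat, rep(TRUE, n), seed = 9),
                   displace_location(lon, lat, rep(TRUE, n), seed = 9))
})

test_that("intercept-only noiseless survey returns the intercept exactly", {
  st <- tiny_stack(15, seed = 2)
  m <- stgp_model(beta = c(intercept = 0.18), sigma2 = 0, kappa = 1,
                  nugget = 0, rho = 0)
  sv <- simulate_survey(st, m, n_clusters = 40, n_waves = 1, seed = 4)
  expect_true(all(sv$clusters$p_under5 == 0.18))
  expect_true(all(sv$clusters$time == 0L))
  expect_equal(sv$truth$n_clipped, 0)
})

test_that("survey observations satisfy the record invariants", {
  st <- tiny_stack(20, seed = 6)
  sv <- simulate_survey(st, default_u5_model(), n_clusters = 120,
                        n_waves = 3, seed = 8)
  cl <- sv$clusters
  expect_true(all(cl$p_under5 >= 0 & cl$p_under5 <= 1))
  expect_true(all(cl$n_under5 <= cl$n_people))
  expect_true(all(abs(cl$p_under5 - cl$n_under5 / cl$n_people) <=
                    0.5 / cl$n_people + 1e-9))
  expect_true(all(cl$time %in% 0:2))
  expect_true(all(table(cl$time) >= 39))
  expect_true(all(cl$zone_id %in% 1:9))
  ## deterministic under the seed
  sv2 <- simulate_survey(st, default_u5_model(), n_clusters = 120,
                         n_waves = 3, seed = 8)
  expect_identical(sv$clusters, sv2$clusters)
  ## capacity guard
  expect_error(simulate_survey(st, default_u5_model(), n_clusters = 1e5,
                               n_waves = 1, seed = 1), "exceeds")
})

test_that("study-scale surveys have the expected mean and variance budget", {
  ## mean near the 0.18 intercept; variance within the plausibility band
  ## implied by sigma2 + nugget + covariate contributions
  g <- raster_grid(3, 4, 0.2, 50, 50)
  st <- gen_covariate_stack(g, seed = 3)
  m <- default_u5_model()
  means <- vars <- numeric(10)
  for (k in 1:10) {
    sv <- simulate_survey(st, m, n_clusters = 1624, n_waves = 3, seed = 100 + k)
    means[k] <- mean(sv$clusters$p_under5)
    vars[k] <- var(sv$clusters$p_under5)
  }
  expect_gte(mean(means), 0.16)
  expect_lte(mean(means), 0.20)
  expect_gte(mean(vars), 0.001)
  expect_lte(mean(vars), 0.006)
})

test_that("variance budget holds with rho = 0 and no spatial structure", {
  ## iid regime: Var(p) ~ sigma2 + nugget within Monte-Carlo error
  st <- tiny_stack(40, cell = 1, seed = 9)   # large extent, weak correlation
  m <- stgp_model(beta = c(intercept = 0.5), sigma2 = 0.002,
                  kappa = sqrt(8) / 0.5, nugget = 0.003, rho = 0)
  v <- replicate(6, {
    sv <- simulate_survey(st, m, n_clusters = 600, n_waves = 1,
                          seed = sample.int(1e6, 1))
    var(sv$clusters$p_under5)
  })
  expect_equal(mean(v), 0.005, tolerance = 0.15)
})

test_that("zone and population rasters are valid and deterministic", {
  g <- raster_grid(0, 0, 0.25, 30, 30)
  z <- gen_zone_raster(g, n_zones = 7, seed = 5)
  expect_setequal(unique(c(z$values)), 1:7)
  expect_identical(z$values, gen_zone_raster(g, n_zones = 7, seed = 5)$values)
  st <- gen_covariate_stack(g, seed = 11)
  pop <- gen_population_raster(g, seed = 6, total = 5e5, stack = st)
  expect_equal(sum(pop$values, na.rm = TRUE), 5e5)
  expect_true(all(pop$values[st$mask] >= 0))
  expect_true(all(is.na(pop$values[!st$mask])))
})
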