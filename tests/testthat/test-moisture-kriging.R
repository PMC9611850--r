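# Gaussian random field with a known exponential variogram on given points,
# drawn by Cholesky factorisation — the independent field generator for the
# parameter-recovery tests.
grf_exponential <- function(pts, nugget, sill, range_m, seed) {
  set.seed(seed)
  lat0 <- mean(pts$lat)
  xy <- cbind((pts$lon - mean(pts$lon)) * 110574 * cos(lat0 * pi / 180),
              (pts$lat - lat0) * 110574)
  D <- as.matrix(stats::dist(xy))
  C <- nugget * diag(nrow(pts)) + sill * exp(-3 * D / range_m)
  as.numeric(t(chol(C)) %*% rnorm(nrow(pts)))
}

random_points <- function(n, seed, span_deg = 2e-3) {
  set.seed(seed)
  data.frame(lat = 37.93 + runif(n) * span_deg,
             lon = 15.93 + runif(n) * span_deg)
}

test_that("covariate link is linear with clipping to the sensor range", {
  pts <- random_points(5, 1)
  pts$rainfall_mm <- c(0, 10, 20, 30, 400)
  est <- estimate_moisture_at_points(pts, c(intercept = 0.1, rainfall_mm = 0.005))
  expect_equal(est$moisture_estimate[1:4], 0.1 + 0.005 * c(0, 10, 20, 30))
  expect_equal(est$moisture_estimate[5], 0.57)  # clipped
  flat <- estimate_moisture_at_points(pts, c(intercept = 0.3))
  expect_true(all(flat$moisture_estimate == 0.3))
  expect_error(estimate_moisture_at_points(pts, c(intercept = 0, ndvi = 1)),
               class = "missing_data_error")
})

test_that("kriging weights sum to one and a single sample is returned everywhere", {
  vgm <- variogram_model("spherical", 0.05, 1, 40)
  one <- data.frame(lat = 37.93, lon = 15.93, value = 0.31)
  tg <- random_points(7, 3)
  kr <- krige(one, vgm, tg)
  expect_true(all(kr$estimate == 0.31))
  set.seed(6)
  for (k in 1:10) {
    s <- random_points(sample(5:20, 1), 100 + k)
    s$value <- runif(nrow(s), 0.1, 0.4)
    kr <- krige(s, vgm, tg)
    expect_equal(unname(rowSums(attr(kr, "weights"))), rep(1, 7),
                 tolerance = 1e-12)
  }
})

test_that("with zero nugget, kriging interpolates samples exactly", {
  s <- random_points(9, 5)
  s$value <- runif(9, 0.1, 0.4)
  vgm <- variogram_model("exponential", 0, 1, 30)
  kr <- krige(s, vgm, s[, c("lat", "lon")])
  expect_equal(kr$estimate, s$value, tolerance = 1e-8)
  # continuity: estimates at shrinking offsets converge to the sample value
  offs <- c(1e-5, 1e-6, 1e-7)
  errs <- vapply(offs, function(o) {
    abs(krige(s, vgm, data.frame(lat = s$lat[1] + o, lon = s$lon[1]))$estimate -
          s$value[1])
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("duplicate sample locations are rejected as singular geometry", {
  s <- data.frame(lat = c(37.93, 37.93), lon = c(15.93, 15.93),
                  value = c(0.2, 0.3))
  expect_error(krige(s, variogram_model("exponential", 0, 1, 30),
                     data.frame(lat = 37.931, lon = 15.931)),
               class = "geometry_error")
})

test_that("kriging weights equal an independently assembled dense solve", {
  vgm <- variogram_model("exponential", 0.1, 0.8, 25)
  set.seed(12)
  for (k in 1:10) {
    n <- sample(5:20, 1)
    s <- random_points(n, 200 + k)
    s$value <- runif(n, 0.1, 0.4)
    tg <- random_points(3, 300 + k)
    kr <- krige(s, vgm, tg)
    W <- attr(kr, "weights")
    lat0 <- mean(s$lat)
    # oracle: assemble and invert the augmented system from scratch
    G <- matrix(0, n + 1, n + 1)
    for (a in seq_len(n)) for (b in seq_len(n)) if (a != b) {
      h <- oracle_dist_m(s$lat[a], s$lon[a], s$lat[b], s$lon[b], lat0)
      G[a, b] <- vgm$nugget + vgm$sill * (1 - exp(-3 * h / vgm$range_m))
    }
    G[n + 1, seq_len(n)] <- 1; G[seq_len(n), n + 1] <- 1
    Ginv <- solve(G)
    for (t in seq_len(nrow(tg))) {
      g0 <- vapply(seq_len(n), function(a) {
        h <- oracle_dist_m(s$lat[a], s$lon[a], tg$lat[t], tg$lon[t], lat0)
        vgm$nugget + vgm$sill * (1 - exp(-3 * h / vgm$range_m))
      }, numeric(1))
      w_oracle <- (Ginv %*% c(g0, 1))[seq_len(n)]
      expect_equal(unname(W[t, ]), as.numeric(w_oracle), tolerance = 1e-8)
    }
  }
})

test_that("variogram fitting recovers range and plateau of a simulated field", {
  pts <- random_points(200, 1)
  pts$value <- grf_exponential(pts, nugget = 0.1, sill = 1, range_m = 30,
                               seed = 1)
  fv <- fit_variogram(pts)
  expect_lt(abs(fv$range_m - 30) / 30, 0.30)
  # nugget/partial-sill split is weakly identified from one realisation;
  # the plateau (their sum) is the recoverable quantity
  expect_lt(abs((fv$nugget + fv$sill) - 1.1) / 1.1, 0.25)
})

test_that("pure-nugget fields fit an essentially flat variogram", {
  pts <- random_points(150, 2)
  set.seed(2)
  pts$value <- rnorm(150)
  fv <- fit_variogram(pts)
  ev <- attr(fv, "empirical")
  gam <- semivariance(fv, range(ev$h))
  expect_gt(gam[1] / gam[2], 0.6)   # near-flat over observed lags
  expect_lt(abs((fv$nugget + fv$sill) - var(pts$value)) / var(pts$value), 0.3)
})

test_that("identical sample values collapse the fitted sill to zero", {
  pts <- random_points(30, 3)
  pts$value <- 0.25
  fv <- fit_variogram(pts)
  expect_lt(fv$sill, 1e-6)
  expect_error(fit_variogram(random_points(5, 4)),
               class = "insufficient_data_error")
})

test_that("calibration recovers planted coefficients present in the grid", {
  pts <- random_points(40, 7)
  pts$ndvi <- runif(40, 0.2, 0.8)
  truth <- c(intercept = 0.05, ndvi = 0.3)
  vgm_true <- variogram_model("exponential", 0, 0.01, 50)
  smp <- estimate_moisture_at_points(pts, truth)
  sens_loc <- random_points(6, 8)
  kr <- krige(smp, vgm_true, sens_loc)
  sensors <- tibble::tibble(lat = sens_loc$lat, lon = sens_loc$lon,
                            timestamp = "2021-07-01T00:00:00Z",
                            kind = "soil_moisture_vwc", value = kr$estimate)
  grid <- expand.grid(nugget = c(0, 0.05), sill = c(0.01, 0.1),
                      range_m = c(20, 50), intercept = c(0.05, 0.2),
                      ndvi = c(-0.3, 0.3, 0.6))
  cal <- calibrate_against_sensors(pts, sensors, grid)
  expect_equal(cal$coefficients[["intercept"]], 0.05)
  expect_equal(cal$coefficients[["ndvi"]], 0.3)
  expect_lt(cal$mae, 1e-10)

  # single configuration grid returns that configuration with its residual
  g1 <- data.frame(nugget = 0.01, sill = 0.02, range_m = 30,
                   intercept = 0.1, ndvi = 0.1)
  cal1 <- calibrate_against_sensors(pts, sensors, g1)
  expect_equal(cal1$vgm$range_m, 30)
  expect_equal(length(cal1$residuals), 6)
  expect_error(calibrate_against_sensors(
    pts, sensors[sensors$kind == "temperature", ], g1), class = "kind_error")
})

test_that("the calibrated surface tracks the simulator moisture field", {
  sc <- fixture_scene(size_m = 30, gt_res_m = 0.1, noise_sd = 0.01, seed = 5)
  g <- sc$grid
  set.seed(15)
  pts <- data.frame(
    lat = runif(60, g$lat_origin - (g$n_rows - 1) * g$pixel_height,
                g$lat_origin - g$pixel_height),
    lon = runif(60, g$lon_origin + g$pixel_width,
                g$lon_origin + (g$n_cols - 1) * g$pixel_width))
  pts$proxy <- sample_sensors(sc, pts, noise_sd = 0, seed = 1)$value
  sensors <- sample_sensors(sc, random_points_in(g, 10, 16),
                            noise_sd = 0.01, seed = 2)
  grid <- expand.grid(nugget = c(0, 1e-4), sill = c(1e-3, 5e-3),
                      range_m = c(7.5, 15, 30), intercept = 0, proxy = 1)
  cal <- calibrate_against_sensors(pts, sensors, grid)
  smp <- estimate_moisture_at_points(pts, cal$coefficients)
  held_out <- random_points_in(g, 40, 17)
  kr <- krige(smp, cal$vgm, held_out)
  truth <- sample_sensors(sc, held_out, noise_sd = 0, seed = 1)$value
  expect_lt(mean(abs(kr$estimate - truth)), 1.5 * 0.01)
})
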