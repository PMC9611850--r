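test_that("footprint matching agrees with a brute-force point-in-box oracle", {
  gp <- fixture_grid_pair(sat_rows = 3, sat_cols = 4, ratio = 7)
  corr <- match_footprints(gp$sat, gp$uav)
  expect_true(all(corr$counts == 49))
  expect_equal(max(abs(corr$coverage_fraction - 1)), 0, tolerance = 1e-9)

  # oracle: explicit half-open box test on every UAV centre
  idx <- expand.grid(u = 0:(gp$uav$n_rows - 1), v = 0:(gp$uav$n_cols - 1))
  ctr <- pixel_center(gp$uav, idx$u, idx$v)
  oracle <- matrix(NA_integer_, gp$uav$n_rows, gp$uav$n_cols)
  for (i in 0:(gp$sat$n_rows - 1)) for (j in 0:(gp$sat$n_cols - 1)) {
    top <- pixel_corner(gp$sat, i, j)
    bot <- pixel_corner(gp$sat, i + 1, j + 1)
    inb <- ctr$lon >= top$lon & ctr$lon < bot$lon &
           ctr$lat <= top$lat & ctr$lat > bot$lat
    oracle[cbind(idx$u[inb] + 1, idx$v[inb] + 1)] <- i * gp$sat$n_cols + j
  }
  got <- corr$cell_row * gp$sat$n_cols + corr$cell_col
  expect_equal(got, oracle)
})

test_that("a UAV centre on a shared cell boundary lands in exactly one cell", {
  # odd ratio puts centres exactly on interior satellite edges: centre of
  # uav column v has lon offset (v + 0.5) * px; with ratio 1 the centre of a
  # 2x2 sat grid's interior corner is hit by a 4x4 uav grid of half the pixel
  sat <- geo_grid(2, 2, 38, 16, 2e-4, 2e-4)
  uav <- geo_grid(4, 4, lat_origin = 38 + 0.5e-4, lon_origin = 16 - 0.5e-4,
                  pixel_height = 1e-4, pixel_width = 1e-4)
  corr <- match_footprints(sat, uav)
  assigned <- !is.na(corr$cell_row)
  lin <- corr$cell_row * 2 + corr$cell_col
  # every assigned pixel is in exactly one cell by construction of the maps;
  # totals must not double-count
  expect_equal(sum(corr$counts), sum(assigned))
})

test_that("partial UAV coverage yields a proportional coverage fraction", {
  gp <- fixture_grid_pair(sat_rows = 1, sat_cols = 1, ratio = 10)
  half <- geo_grid(10, 5, gp$uav$lat_origin, gp$uav$lon_origin,
                   gp$uav$pixel_height, gp$uav$pixel_width)
  corr <- match_footprints(gp$sat, half)
  expect_equal(corr$coverage_fraction[1, 1], 0.5, tolerance = 1e-9)
})

test_that("non-overlapping extents warn and flag an empty correspondence", {
  sat <- geo_grid(2, 2, 38, 16, 1e-4, 1e-4)
  uav <- geo_grid(4, 4, 50, 100, 1e-5, 1e-5)
  expect_warning(corr <- match_footprints(sat, uav),
                 class = "no_overlap_warning")
  expect_true(corr$empty)
})

test_that("satellite NDVI delegates to the per-pixel engine", {
  r <- fixture_raster(matrix(0.1, 2, 2), matrix(0.4, 2, 2))
  m <- ndvi_sat(r)
  expect_equal(m$provenance, "sat")
  expect_equal(m$values, ndvi(r)$values)
  expect_equal(m$values[1, 1], 0.6)
})

test_that("aggregation reproduces constant fields and arithmetic means", {
  gp <- fixture_grid_pair(sat_rows = 2, sat_cols = 2, ratio = 10)
  # constant NDVI: red chosen so (nir - red)/(nir + red) = 0.25
  r <- multispectral_raster(gp$uav, list(
    red = matrix(0.3, 20, 20), nir = matrix(0.5, 20, 20)))
  corr <- match_footprints(gp$sat, gp$uav)
  for (den in c("restricted", "printed")) {
    m <- aggregate_ndvi(r, corr, which = "all", denominator = den)
    expect_equal(m$values, matrix(0.25, 2, 2))
  }
  # half the pixels at NDVI 0.2, half at 0.8 -> mean 0.5
  nir <- matrix(0, 20, 20); red <- matrix(0, 20, 20)
  top <- matrix(rep(c(TRUE, FALSE), length.out = 400), 20, 20)
  nir[top] <- 0.6; red[top] <- 0.4    # 0.2
  nir[!top] <- 0.9; red[!top] <- 0.1  # 0.8
  m <- aggregate_ndvi(multispectral_raster(gp$uav, list(red = red, nir = nir)),
                      corr, which = "all")
  expect_equal(m$values, matrix(0.5, 2, 2))
})

test_that("canopy aggregation with an all-canopy mask equals whole-cell aggregation", {
  gp <- fixture_grid_pair(sat_rows = 2, sat_cols = 2, ratio = 8)
  set.seed(10)
  r <- multispectral_raster(gp$uav, list(red = matrix(runif(256, 0.05, 0.3), 16),
                                         nir = matrix(runif(256, 0.3, 0.9), 16)))
  corr <- match_footprints(gp$sat, gp$uav)
  all_mask <- partition_from_mask(gp$uav, matrix(TRUE, 16, 16))
  expect_equal(aggregate_ndvi(r, corr, mask = all_mask, which = "vin")$values,
               aggregate_ndvi(r, corr, which = "all")$values)
})

test_that("printed-denominator components add up; restricted mode reconstructs with weights", {
  set.seed(77)
  gp <- fixture_grid_pair(sat_rows = 3, sat_cols = 3, ratio = 6)
  corr <- match_footprints(gp$sat, gp$uav)
  n <- gp$uav$n_rows
  for (trial in 1:25) {
    r <- multispectral_raster(gp$uav, list(
      red = matrix(runif(n^2, 0.05, 0.4), n),
      nir = matrix(runif(n^2, 0.2, 0.9), n)))
    mask <- partition_from_mask(gp$uav, matrix(runif(n^2) < runif(1, 0.2, 0.8), n))
    whole_p <- aggregate_ndvi(r, corr, which = "all", denominator = "printed")
    vin_p <- aggregate_ndvi(r, corr, mask, "vin", "printed", min_coverage = 0)
    int_p <- aggregate_ndvi(r, corr, mask, "int", "printed", min_coverage = 0)
    vsum <- ifelse(is.na(vin_p$values), 0, vin_p$values) +
            ifelse(is.na(int_p$values), 0, int_p$values)
    expect_equal(vsum, whole_p$values, tolerance = 1e-14)

    whole_r <- aggregate_ndvi(r, corr, which = "all")
    vin_r <- aggregate_ndvi(r, corr, mask, "vin", min_coverage = 0)
    int_r <- aggregate_ndvi(r, corr, mask, "int", min_coverage = 0)
    n_vin <- rowsum_cells(mask$vin_mask, corr)
    n_int <- rowsum_cells(mask$int_mask, corr)
    recon <- (n_vin * zero_na(vin_r$values) + n_int * zero_na(int_r$values)) /
      (n_vin + n_int)
    expect_equal(recon, whole_r$values, tolerance = 1e-14)
  }
})

test_that("cells below the coverage floor or with empty selections are nodata", {
  gp <- fixture_grid_pair(sat_rows = 1, sat_cols = 2, ratio = 10)
  half <- geo_grid(10, 15, gp$uav$lat_origin, gp$uav$lon_origin,
                   gp$uav$pixel_height, gp$uav$pixel_width)
  corr <- match_footprints(gp$sat, half)
  r <- multispectral_raster(half, list(red = matrix(0.2, 10, 15),
                                       nir = matrix(0.6, 10, 15)))
  m <- aggregate_ndvi(r, corr, which = "all", min_coverage = 0.95)
  expect_equal(m$values[1, 1], 0.5)
  expect_true(is.na(m$values[1, 2]))  # only half covered
  # empty canopy selection -> nodata even at full coverage
  corr2 <- match_footprints(gp$sat, gp$uav)
  r2 <- multispectral_raster(gp$uav, list(red = matrix(0.2, 10, 20),
                                          nir = matrix(0.6, 10, 20)))
  none <- partition_from_mask(gp$uav, matrix(FALSE, 10, 20))
  m2 <- aggregate_ndvi(r2, corr2, none, "vin")
  expect_true(all(is.na(m2$values)))
})

test_that("map comparison statistics match an independent recomputation", {
  g <- geo_grid(5, 5, 38, 16, 1e-4, 1e-4)
  set.seed(8)
  av <- matrix(runif(25, 0.2, 0.8), 5); bv <- matrix(runif(25, 0.2, 0.8), 5)
  av[2, 2] <- NA
  a <- ndvi_map(g, av); b <- ndvi_map(g, bv)
  st <- compare_maps(a, b)
  ok <- !is.na(av)
  expect_equal(st$bias, mean(bv[ok] - av[ok]))
  expect_equal(st$rmse, sqrt(mean((bv[ok] - av[ok])^2)))
  expect_equal(st$correlation, cor(av[ok], bv[ok]))
  expect_equal(st$n, sum(ok))

  same <- compare_maps(a, a)
  expect_equal(same$bias, 0); expect_equal(same$rmse, 0)
  expect_equal(same$correlation, 1)
  shift <- ndvi_map(g, av + 0.1)
  st2 <- compare_maps(a, shift)
  expect_equal(st2$bias, 0.1); expect_equal(st2$rmse, 0.1, tolerance = 1e-12)
  expect_equal(st2$correlation, 1)

  tiny <- ndvi_map(geo_grid(1, 2, 38, 16, 1e-4, 1e-4),
                   matrix(c(0.1, NA), 1, 2))
  expect_error(compare_maps(tiny, tiny), class = "insufficient_data_error")
})
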