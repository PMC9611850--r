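# Shared fixtures: small synthetic scenes and ad-hoc grids/rasters built in
# code at test time.

# A noise-free vineyard scene whose canopy NDVI is exactly `canopy_ndvi`:
# rows 2 m apart, 1 m canopy, soil NDVI ~0.15 — the surveyed geometry.
fixture_scene <- function(canopy_ndvi = 0.8, size_m = 20, azimuth = 0,
                          gt_res_m = 0.05, noise_sd = 0,
                          vigour_noise_sd = 0, seed = 1) {
  simulate_scene(sim_config(
    field_width_m = size_m, field_height_m = size_m,
    row_spacing_m = 2, canopy_width_m = 1, row_azimuth_deg = azimuth,
    vigour_base = vigour_for_canopy_ndvi(canopy_ndvi),
    gt_res_m = gt_res_m, noise_sd = noise_sd,
    vigour_noise_sd = vigour_noise_sd, seed = seed))
}

# Plain raster from explicit band matrices on an arbitrary small grid.
fixture_raster <- function(red, nir, radiometry = "reflectance") {
  g <- geo_grid(nrow(red), ncol(red), lat_origin = 38, lon_origin = 16,
                pixel_height = 1e-5, pixel_width = 1e-5)
  multispectral_raster(g, list(red = red, nir = nir), radiometry = radiometry)
}

# UAV grid nested inside a satellite grid with an exact integer pixel ratio.
fixture_grid_pair <- function(sat_rows = 3, sat_cols = 3, ratio = 20,
                              sat_px_deg = 1e-4) {
  sat <- geo_grid(sat_rows, sat_cols, lat_origin = 38, lon_origin = 16,
                  pixel_height = sat_px_deg, pixel_width = sat_px_deg)
  uav <- geo_grid(sat_rows * ratio, sat_cols * ratio, lat_origin = 38,
                  lon_origin = 16, pixel_height = sat_px_deg / ratio,
                  pixel_width = sat_px_deg / ratio)
  list(sat = sat, uav = uav)
}

# Circular distance between azimuths on [0, 180).
azimuth_error <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Independent metre distance for oracles (equirectangular at reference lat).
oracle_dist_m <- function(lat1, lon1, lat2, lon2, lat0) {
  mlat <- 110574
  mlon <- 110574 * cos(lat0 * pi / 180)
  sqrt(((lat1 - lat2) * mlat)^2 + ((lon1 - lon2) * mlon)^2)
}

# Per-satellite-cell count of TRUE pixels in a UAV-grid mask.
rowsum_cells <- function(mask, corr) {
  sat <- corr$sat_grid
  lin <- corr$cell_row * sat$n_cols + corr$cell_col + 1L
  keep <- mask & !is.na(lin)
  matrix(tabulate(lin[keep], nbins = sat$n_rows * sat$n_cols),
         sat$n_rows, sat$n_cols, byrow = TRUE)
}

zero_na <- function(m) ifelse(is.na(m), 0, m)

# n random locations strictly inside a grid's extent.
random_points_in <- function(g, n, seed) {
  set.seed(seed)
  data.frame(
    lat = runif(n, g$lat_origin - (g$n_rows - 1) * g$pixel_height,
                g$lat_origin - g$pixel_height),
    lon = runif(n, g$lon_origin + g$pixel_width,
                g$lon_origin + (g$n_cols - 1) * g$pixel_width))
}
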