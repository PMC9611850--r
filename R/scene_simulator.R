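# Synthetic vineyard-scene simulator.
#
# Emulates the study geometry — parallel vine rows 2 m apart with ~1 m wide
# canopy strips — on a metric layout converted to WGS84 degrees with a local
# scale factor at the scene latitude. Ground truth (vigour, canopy mask, soil
# moisture, red/NIR reflectance) lives on a fine grid; render_uav() and
# render_satellite() average it down to the centimetric and decametric pixel
# sizes of the two platforms.

# Canopy/soil reflectance model: chosen so canopy NDVI spans ~0.3-0.85 over
# vigour in (0,1] and bare/inter-row soil sits near NDVI 0.15, the typical
# vine/soil contrast in multispectral surveys.
CANOPY_RED_0 <- 0.18; CANOPY_RED_SLOPE <- -0.12
CANOPY_NIR_0 <- 0.25; CANOPY_NIR_SLOPE <- 0.55
SOIL_RED <- 0.22; SOIL_NIR <- 0.30

canopy_reflectance <- function(vigour) {
  list(red = CANOPY_RED_0 + CANOPY_RED_SLOPE * vigour,
       nir = CANOPY_NIR_0 + CANOPY_NIR_SLOPE * vigour)
}

#' Vigour level producing a given canopy NDVI
#'
#' Inverts the simulator's linear canopy reflectance model, handy for setting
#' up scenes with a prescribed canopy NDVI.
#' @param ndvi Target canopy NDVI.
#' @return Vigour in (0, 1].
#' @export
vigour_for_canopy_ndvi <- function(ndvi) {
  # solve (nir - red)/(nir + red) = ndvi for vigour, both linear in vigour
  a <- CANOPY_NIR_0 - CANOPY_RED_0; b <- CANOPY_NIR_SLOPE - CANOPY_RED_SLOPE
  c0 <- CANOPY_NIR_0 + CANOPY_RED_0; d <- CANOPY_NIR_SLOPE + CANOPY_RED_SLOPE
  (ndvi * c0 - a) / (b - ndvi * d)
}

#' Simulator configuration
#'
#' Defaults reproduce the surveyed vineyard's geometry: rows 2 m apart
#' (centre to centre, leaving a 1 m bare gap), canopy strips about 1 m wide.
#'
#' @param field_width_m,field_height_m Field extent in metres (east, north).
#' @param row_spacing_m Row centre-to-centre spacing, metres.
#' @param canopy_width_m Canopy strip width, metres; must be < spacing.
#' @param row_azimuth_deg Row direction, degrees clockwise from north.
#' @param vigour_base Mean vigour, unitless in (0, 1].
#' @param vigour_gradient Length-2 vector, vigour change per metre (east,
#'   north).
#' @param soil_ndvi_mean Approximate NDVI of the inter-row soil (fixed by the
#'   soil reflectance model; retained for reference).
#' @param moisture_range_m Spatial correlation length of the soil-moisture
#'   field, metres.
#' @param noise_sd Reflectance noise s.d. added per ground-truth pixel.
#' @param vigour_noise_sd Amplitude of the smooth spatial vigour variation
#'   (unitless vigour; 0 gives a scene whose canopy NDVI is exactly the value
#'   implied by `vigour_base`).
#' @param gt_res_m Ground-truth grid resolution, metres (must be <= any
#'   rendered GSD).
#' @param scene_lat,scene_lon Upper-left corner of the scene, WGS84 degrees.
#' @param seed Integer seed; the scene is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(field_width_m = 50, field_height_m = 50,
                       row_spacing_m = 2, canopy_width_m = 1,
                       row_azimuth_deg = 0, vigour_base = 0.6,
                       vigour_gradient = c(0, 0), soil_ndvi_mean = 0.15,
                       moisture_range_m = 15, noise_sd = 0.01,
                       vigour_noise_sd = 0.05, gt_res_m = 0.05,
                       scene_lat = 37.93, scene_lon = 15.93, seed = 1L) {
  cfg <- list(field_width_m = field_width_m, field_height_m = field_height_m,
              row_spacing_m = row_spacing_m, canopy_width_m = canopy_width_m,
              row_azimuth_deg = row_azimuth_deg, vigour_base = vigour_base,
              vigour_gradient = vigour_gradient,
              soil_ndvi_mean = soil_ndvi_mean,
              moisture_range_m = moisture_range_m, noise_sd = noise_sd,
              vigour_noise_sd = vigour_noise_sd,
              gt_res_m = gt_res_m, scene_lat = scene_lat,
              scene_lon = scene_lon, seed = as.integer(seed))
  if (cfg$canopy_width_m <= 0 || cfg$canopy_width_m >= cfg$row_spacing_m)
    vf_stop("canopy width must be positive and smaller than the row spacing",
            "config_error")
  if (cfg$vigour_base <= 0 || cfg$vigour_base > 1)
    vf_stop("vigour_base must lie in (0, 1]", "config_error")
  if (cfg$noise_sd < 0) vf_stop("noise_sd must be >= 0", "config_error")
  class(cfg) <- "sim_config"
  cfg
}

# metres per degree of longitude at the scene latitude
m_per_deg_lon <- function(lat) M_PER_DEG_LAT * cos(lat * pi / 180)

# Grid whose pixels are square res_m metres, anchored at the scene corner.
metric_grid <- function(lat0, lon0, width_m, height_m, res_m) {
  geo_grid(n_rows = floor(height_m / res_m), n_cols = floor(width_m / res_m),
           lat_origin = lat0, lon_origin = lon0,
           pixel_height = res_m / M_PER_DEG_LAT,
           pixel_width = res_m / m_per_deg_lon(lat0))
}

# East/north metre coordinates of all pixel centres of a metric grid.
grid_center_xy <- function(grid, lat0, lon0) {
  ll <- grid_center_latlon(grid)
  list(x = (ll$lon - lon0) * m_per_deg_lon(lat0),
       y = (lat0 - ll$lat) * M_PER_DEG_LAT)   # y grows southward from corner
}

# Smooth Gaussian random field on an nr x nc grid, correlation length range_px
# (pixels), normalised to zero mean / unit sd. White noise convolved with a
# Gaussian kernel via FFT (circular boundary; harmless for synthetic ground
# truth and keeps the cost O(n log n) at any correlation length).
gaussian_field <- function(nr, nc, range_px) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_px < 1e-9) return(z)
  gauss_1d <- function(n, s) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (d / s)^2)
    k / sum(k)
  }
  K <- outer(gauss_1d(nr, range_px), gauss_1d(nc, range_px))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic vineyard scene
#'
#' Produces ground truth at `gt_res_m` resolution: a canopy mask of parallel
#' strips (`canopy_width_m` wide, every `row_spacing_m`, at `row_azimuth_deg`),
#' a vigour field (base + linear gradient + smooth noise, clipped to \[0,1\]),
#' a spatially correlated soil-moisture field within the sensor range
#' \[0, 0.57\] VWC, and red/NIR reflectance derived from vigour on canopy and a
#' fixed soil signature elsewhere.
#'
#' @param config A [sim_config()].
#' @return A `vineyard_scene` with fields `grid`, `canopy_mask`,
#'   `vigour_field`, `moisture_field`, `red`, `nir`, `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- metric_grid(config$scene_lat, config$scene_lon,
                   config$field_width_m, config$field_height_m,
                   config$gt_res_m)
  xy <- grid_center_xy(g, config$scene_lat, config$scene_lon)
  x <- matrix(xy$x, g$n_rows, g$n_cols, byrow = TRUE)
  y <- matrix(xy$y, g$n_rows, g$n_cols)

  # signed distance across rows: project onto the axis perpendicular to the
  # row direction (azimuth measured clockwise from north)
  az <- config$row_azimuth_deg * pi / 180
  s <- x * cos(az) - (-y) * sin(az)   # north = -y (y grows southward)
  frac <- (s / config$row_spacing_m) %% 1
  half_frac <- (config$canopy_width_m / config$row_spacing_m) / 2
  canopy <- frac < half_frac | frac >= 1 - half_frac

  range_px <- config$moisture_range_m / config$gt_res_m
  vig_noise <- if (config$vigour_noise_sd > 0)
    gaussian_field(g$n_rows, g$n_cols, range_px / 2) * config$vigour_noise_sd
  else 0
  vigour <- config$vigour_base +
    config$vigour_gradient[1] * x + config$vigour_gradient[2] * (-y) +
    vig_noise
  vigour <- pmin(pmax(vigour, 0), 1)

  moist <- 0.22 + 0.08 * gaussian_field(g$n_rows, g$n_cols, range_px)
  moist <- pmin(pmax(moist, 0), VWC_MAX)

  cr <- canopy_reflectance(vigour)
  red <- ifelse(canopy, cr$red, SOIL_RED)
  nir <- ifelse(canopy, cr$nir, SOIL_NIR)
  if (config$noise_sd > 0) {
    red <- red + matrix(stats::rnorm(length(red), sd = config$noise_sd),
                        nrow(red))
    nir <- nir + matrix(stats::rnorm(length(nir), sd = config$noise_sd),
                        nrow(nir))
  }
  red <- pmin(pmax(red, 0), 1)
  nir <- pmin(pmax(nir, 0), 1)

  structure(list(grid = g, canopy_mask = canopy, vigour_field = vigour,
                 moisture_field = moist, red = red, nir = nir,
                 config = config),
            class = "vineyard_scene")
}

# Block-average a matrix by integer factor f, truncating trailing partial
# blocks (the rendered extent is the largest aligned multiple of the GSD).
block_mean <- function(m, f) {
  nr <- (nrow(m) %/% f) * f; nc <- (ncol(m) %/% f) * f
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  # sum over row blocks then column blocks
  rs <- rowsum(m, rep(seq_len(nr %/% f), each = f))
  cs <- t(rowsum(t(rs), rep(seq_len(nc %/% f), each = f)))
  cs <- cs / (f * f)
  dimnames(cs) <- NULL
  cs
}

render_at_gsd <- function(scene, gsd_m) {
  res <- scene$config$gt_res_m
  if (gsd_m < res - 1e-12)
    vf_stop("requested GSD is finer than the ground-truth resolution",
            "resolution_error")
  f <- round(gsd_m / res)
  if (abs(gsd_m / res - f) > 1e-6)
    vf_stop("GSD must be an integer multiple of the ground-truth resolution",
            "resolution_error")
  g <- scene$grid
  red <- block_mean(scene$red, f)
  nir <- block_mean(scene$nir, f)
  out_grid <- geo_grid(nrow(red), ncol(red), g$lat_origin, g$lon_origin,
                       g$pixel_height * f, g$pixel_width * f)
  multispectral_raster(out_grid, list(red = red, nir = nir),
                       radiometry = "reflectance")
}

#' Render the scene at UAV resolution
#'
#' Each output pixel is the area-weighted (block) mean of the ground-truth
#' reflectance it covers.
#' @param scene A `vineyard_scene`.
#' @param gsd_m Ground sampling distance in metres (default 0.05, i.e. 5 cm).
#' @return An `ms_raster`.
#' @export
render_uav <- function(scene, gsd_m = 0.05) render_at_gsd(scene, gsd_m)

#' Render the scene at satellite resolution
#'
#' Decametric pixels mix canopy and soil reflectance within each footprint;
#' NDVI of the rendered pixel is the NDVI of mean reflectances, not the mean
#' of sub-pixel NDVIs — the mixing bias the multi-resolution decomposition is
#' built to expose.
#' @param scene A `vineyard_scene`.
#' @param gsd_m Ground sampling distance in metres (default 10).
#' @return An `ms_raster`.
#' @export
render_satellite <- function(scene, gsd_m = 10) render_at_gsd(scene, gsd_m)

#' Sample point sensors from the scene's moisture field
#'
#' Reads the moisture field at the ground-truth pixel nearest each location,
#' adds Gaussian noise and clips to the sensor calibration range \[0, 0.57\]
#' VWC.
#'
#' @param scene A `vineyard_scene`.
#' @param locations Data frame with columns `lat`, `lon` inside the scene
#'   extent.
#' @param noise_sd Noise s.d. in VWC units.
#' @param seed Integer seed.
#' @param timestamp ISO-8601 timestamp stamped on every reading.
#' @return A tibble of sensor readings (lat, lon, timestamp, kind, value).
#' @export
sample_sensors <- function(scene, locations, noise_sd = 0.02, seed = 1L,
                           timestamp = "2021-07-01T09:40:00Z") {
  g <- scene$grid
  u <- floor((g$lat_origin - locations$lat) / g$pixel_height)
  v <- floor((locations$lon - g$lon_origin) / g$pixel_width)
  if (any(u < 0 | u >= g$n_rows | v < 0 | v >= g$n_cols))
    vf_stop("sensor location outside the scene extent", "bounds_error")
  vals <- scene$moisture_field[cbind(u + 1, v + 1)]
  set.seed(seed)
  if (noise_sd > 0) vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
  vals <- pmin(pmax(vals, 0), VWC_MAX)
  tibble::tibble(lat = locations$lat, lon = locations$lon,
                 timestamp = timestamp, kind = "soil_moisture_vwc",
                 value = vals)
}
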