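# Georeferenced raster / point data model shared by all stages.
#
# All coordinates are geographic WGS84 degrees. Grids are row-major with the
# origin at the upper-left corner: latitude decreases with row index, longitude
# increases with column index. Pixel indices are 0-based throughout, matching
# the usual raster convention. Nodata is NA internally.

# Approximate metres per degree at mid latitudes; used only to lay metric field
# geometry onto a geographic grid and to project small scenes back to metres.
M_PER_DEG_LAT <- 110574

#' Construct a geographic grid
#'
#' A `geo_grid` describes the footprint of a row-major raster in WGS84 degrees:
#' the latitude/longitude of the upper-left corner and the (positive) pixel
#' sizes in degrees. Latitude decreases with row index and longitude increases
#' with column index.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param lat_origin,lon_origin Upper-left corner of pixel (0,0), degrees.
#' @param pixel_height,pixel_width Pixel size in degrees, positive magnitudes.
#' @return An object of class `geo_grid`.
#' @export
geo_grid <- function(n_rows, n_cols, lat_origin, lon_origin,
                     pixel_height, pixel_width) {
  if (n_rows < 1 || n_cols < 1)
    vf_stop("grid must have at least one row and one column", "grid_error")
  if (pixel_height <= 0 || pixel_width <= 0)
    vf_stop("pixel sizes must be positive", "grid_error")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 lat_origin = lat_origin, lon_origin = lon_origin,
                 pixel_height = pixel_height, pixel_width = pixel_width),
            class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  cat(sprintf("<geo_grid> %d x %d px, UL (%.6f, %.6f), pixel %.3g x %.3g deg\n",
              x$n_rows, x$n_cols, x$lat_origin, x$lon_origin,
              x$pixel_height, x$pixel_width))
  invisible(x)
}

#' Centre coordinates of a pixel
#'
#' @param grid A `geo_grid`.
#' @param u,v 0-based row and column indices (vectorised).
#' @return A list with numeric vectors `lat` and `lon`.
#' @export
pixel_center <- function(grid, u, v) {
  if (any(u < 0) || any(u >= grid$n_rows) || any(v < 0) || any(v >= grid$n_cols))
    vf_stop("pixel index out of range", "index_error")
  list(lat = grid$lat_origin - (u + 0.5) * grid$pixel_height,
       lon = grid$lon_origin + (v + 0.5) * grid$pixel_width)
}

#' Upper-left corner coordinates of a pixel
#'
#' Indices up to `n_rows` / `n_cols` are allowed so the lower-right grid corner
#' is addressable.
#' @inheritParams pixel_center
#' @return A list with numeric vectors `lat` and `lon`.
#' @export
pixel_corner <- function(grid, u, v) {
  if (any(u < 0) || any(u > grid$n_rows) || any(v < 0) || any(v > grid$n_cols))
    vf_stop("pixel index out of range", "index_error")
  list(lat = grid$lat_origin - u * grid$pixel_height,
       lon = grid$lon_origin + v * grid$pixel_width)
}

# Matrices of all pixel-centre coordinates (n_rows x n_cols).
grid_center_latlon <- function(grid) {
  lat <- grid$lat_origin - (seq_len(grid$n_rows) - 0.5) * grid$pixel_height
  lon <- grid$lon_origin + (seq_len(grid$n_cols) - 0.5) * grid$pixel_width
  list(lat = lat, lon = lon)
}

grids_equal <- function(a, b, tol = 1e-12) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lat_origin - b$lat_origin) < tol &&
    abs(a$lon_origin - b$lon_origin) < tol &&
    abs(a$pixel_height - b$pixel_height) < tol &&
    abs(a$pixel_width - b$pixel_width) < tol
}

#' Construct a multispectral raster
#'
#' Bands are named matrices sharing the grid shape; at least `red` and `nir`
#' must be present. The `radiometry` tag records whether values are surface
#' reflectance in \[0,1\] or raw digital numbers; mixing the two in one stack is
#' rejected downstream because band ratios are only scale-invariant when both
#' bands share a scale.
#'
#' @param grid A `geo_grid`.
#' @param bands Named list of numeric matrices (`n_rows` x `n_cols`).
#' @param radiometry `"reflectance"` or `"dn"`.
#' @param nodata_mask Logical matrix, `TRUE` where a pixel is invalid; default
#'   all valid.
#' @return An object of class `ms_raster`.
#' @export
multispectral_raster <- function(grid, bands, radiometry = "reflectance",
                                 nodata_mask = NULL) {
  radiometry <- match.arg(radiometry, c("reflectance", "dn"))
  if (!all(c("red", "nir") %in% names(bands)))
    vf_stop("raster must contain at least 'red' and 'nir' bands",
            "band_missing_error")
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b) || nrow(b) != grid$n_rows || ncol(b) != grid$n_cols)
      vf_stop(sprintf("band '%s' shape does not match grid", nm), "grid_error")
  }
  if (radiometry == "reflectance") {
    rng <- range(unlist(lapply(bands, range, na.rm = TRUE)), na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      vf_stop("reflectance values must lie in [0, 1]", "radiometry_error")
  }
  if (is.null(nodata_mask))
    nodata_mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  structure(list(grid = grid, bands = bands, radiometry = radiometry,
                 nodata_mask = nodata_mask),
            class = "ms_raster")
}

#' Construct an NDVI (single-index) map
#'
#' @param grid A `geo_grid`.
#' @param values Numeric matrix in \[-1, 1\]; NA marks nodata.
#' @param provenance One of `"sat"`, `"uav"`, `"vin"`, `"int"`.
#' @return An object of class `ndvi_map`.
#' @export
ndvi_map <- function(grid, values, provenance = "uav") {
  provenance <- match.arg(provenance, c("sat", "uav", "vin", "int"))
  if (!is.matrix(values) || nrow(values) != grid$n_rows ||
      ncol(values) != grid$n_cols)
    vf_stop("values shape does not match grid", "grid_error")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
    vf_stop("index values must lie in [-1, 1]", "range_error")
  structure(list(grid = grid, values = values,
                 nodata_mask = is.na(values), provenance = provenance),
            class = "ndvi_map")
}

SENSOR_KINDS <- c("soil_moisture_vwc", "temperature", "humidity", "pressure",
                  "leaf_wetness", "ph")
VWC_MAX <- 0.57  # sensor calibration ceiling, volumetric water content

#' Read a point-sensor table
#'
#' Expects a delimited text file with header `lat,lon,timestamp,kind,value`.
#' Per-kind physical invariants are enforced: soil-moisture VWC must lie within
#' the sensor calibration range \[0, 0.57\] m3/m3 and pH within \[0, 14\].
#'
#' @param path CSV file path.
#' @return A tibble with columns lat, lon, timestamp, kind, value.
#' @export
read_sensor_table <- function(path) {
  if (!file.exists(path)) vf_stop(paste("no such file:", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "timestamp", "kind", "value")
  if (!all(need %in% names(df)))
    vf_stop("sensor table must have columns lat,lon,timestamp,kind,value",
            "format_error")
  if (nrow(df) == 0) return(tibble::as_tibble(df[, need]))
  bad_kind <- setdiff(unique(df$kind), SENSOR_KINDS)
  if (length(bad_kind))
    vf_stop(paste("unknown sensor kind:", paste(bad_kind, collapse = ", ")),
            "kind_error")
  vwc <- df$value[df$kind == "soil_moisture_vwc"]
  if (length(vwc) && (any(vwc < 0) || any(vwc > VWC_MAX)))
    vf_stop(sprintf(
      "soil-moisture VWC outside the sensor calibration range [0, %.2f]",
      VWC_MAX), "range_error")
  ph <- df$value[df$kind == "ph"]
  if (length(ph) && (any(ph < 0) || any(ph > 14)))
    vf_stop("pH outside [0, 14]", "range_error")
  tibble::as_tibble(df[, need])
}

# ---------------------------------------------------------------------------
# Raster I/O: multiband float32 TIFF + JSON georeferencing sidecar.
#
# Planes are stored affinely rescaled into [0, 1] (the TIFF writer's float
# range); the sidecar records grid, band order, radiometry and per-file
# scale/offset so read_raster restores original units. The nodata mask rides
# as a trailing 0/1 band.

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a raster to disk
#'
#' Writes a multiband float32 TIFF together with a JSON sidecar
#' (`<path>.aux.json`) holding the georeferencing, band map, radiometry and
#' value scaling; the nodata mask is stored as a trailing 0/1 band. Accepts a
#' `ms_raster` or an `ndvi_map` (written as a single-band index raster).
#'
#' @param raster `ms_raster` or `ndvi_map`.
#' @param path Output file path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    vf_stop(paste("file exists (use overwrite = TRUE):", path), "io_error")
  if (!dir.exists(dirname(path)))
    vf_stop(paste("parent directory does not exist:", dirname(path)),
            "io_error")

  if (inherits(raster, "ndvi_map")) {
    planes <- list(index = raster$values)
    scale <- 2; offset <- -1   # [-1,1] -> [0,1]
    meta_extra <- list(kind = "ndvi_map", provenance = raster$provenance)
    mask <- raster$nodata_mask
  } else if (inherits(raster, "ms_raster")) {
    planes <- raster$bands
    if (raster$radiometry == "reflectance") {
      scale <- 1; offset <- 0
    } else {
      mx <- max(1, unlist(lapply(planes, max, na.rm = TRUE)))
      scale <- mx; offset <- 0
    }
    meta_extra <- list(kind = "ms_raster", radiometry = raster$radiometry)
    mask <- raster$nodata_mask
  } else {
    vf_stop("write_raster expects an ms_raster or ndvi_map", "type_error")
  }

  g <- if (inherits(raster, "ndvi_map")) raster$grid else raster$grid
  arr <- array(0, dim = c(g$n_rows, g$n_cols, length(planes) + 1L))
  for (k in seq_along(planes)) {
    p <- (planes[[k]] - offset) / scale
    p[is.na(p) | mask] <- 0
    arr[, , k] <- p
  }
  arr[, , length(planes) + 1L] <- ifelse(mask, 0, 1)
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- c(list(
    grid = list(n_rows = g$n_rows, n_cols = g$n_cols,
                lat_origin = g$lat_origin, lon_origin = g$lon_origin,
                pixel_height = g$pixel_height, pixel_width = g$pixel_width),
    crs = "WGS84 geographic degrees",
    bands = as.list(stats::setNames(seq_along(planes), names(planes))),
    mask_band = length(planes) + 1L,
    scale = scale, offset = offset), meta_extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a raster from disk
#'
#' Reads a multiband TIFF written by [write_raster()] (or any TIFF with a
#' compatible `.aux.json` sidecar) and restores the original grid, band values
#' and nodata mask. Index rasters round-trip as `ndvi_map` objects.
#'
#' @param path File path.
#' @return An `ms_raster` or `ndvi_map`, matching what was written.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) vf_stop(paste("no such file:", path), "io_error")
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    vf_stop(paste("missing georeferencing sidecar:", sp), "format_error")
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!identical(meta$crs, "WGS84 geographic degrees"))
    vf_stop(paste("unsupported CRS:", meta$crs), "unsupported_crs_error")
  arr <- suppressWarnings(tiff::readTIFF(path))
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1L))
  g <- geo_grid(meta$grid$n_rows, meta$grid$n_cols, meta$grid$lat_origin,
                meta$grid$lon_origin, meta$grid$pixel_height,
                meta$grid$pixel_width)
  mask <- arr[, , meta$mask_band, drop = TRUE] < 0.5
  mask <- matrix(mask, g$n_rows, g$n_cols)
  restore <- function(k) {
    p <- matrix(arr[, , k, drop = TRUE], g$n_rows, g$n_cols)
    p <- p * meta$scale + meta$offset
    p[mask] <- NA_real_
    p
  }
  band_idx <- meta$bands
  if (identical(meta$kind, "ndvi_map")) {
    return(ndvi_map(g, restore(band_idx[["index"]]),
                    provenance = meta$provenance))
  }
  if (!all(c("red", "nir") %in% names(band_idx)))
    vf_stop("raster lacks required red/nir bands", "band_missing_error")
  bands <- lapply(band_idx, restore)
  r <- multispectral_raster(g, bands, radiometry = meta$radiometry,
                            nodata_mask = mask)
  r
}
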