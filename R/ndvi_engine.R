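# Per-pixel NDVI and vigour classification.

#' Compute NDVI per pixel
#'
#' NDVI = (NIR - Red) / (NIR + Red), evaluated per pixel on whichever
#' radiometry the raster declares (the ratio is scale-invariant within one
#' radiometry; mixed stacks are rejected at construction). Pixels where
#' NIR + Red = 0 are undefined and map to nodata rather than zero — a zero
#' would masquerade as moderate vigour.
#'
#' @param raster An `ms_raster` with `red` and `nir` bands.
#' @param provenance Provenance tag for the output map.
#' @return An `ndvi_map` with values in \[-1, 1\] and NA nodata.
#' @export
ndvi <- function(raster, provenance = "uav") {
  stopifnot(inherits(raster, "ms_raster"))
  red <- raster$bands$red
  nir <- raster$bands$nir
  if (is.null(red) || is.null(nir))
    vf_stop("raster must contain 'red' and 'nir' bands", "band_missing_error")
  denom <- nir + red
  vals <- (nir - red) / denom
  vals[denom == 0] <- NA_real_
  vals[raster$nodata_mask] <- NA_real_
  vals[is.na(red) | is.na(nir)] <- NA_real_
  ndvi_map(raster$grid, vals, provenance = provenance)
}

#' Classify an NDVI map into low/medium/high vigour
#'
#' Class boundaries follow the half-open convention: `low` iff value < t_low;
#' `medium` iff t_low <= value < t_high; `high` iff value >= t_high. In
#' `"tertiles"` mode the thresholds are the 33.3/66.7 empirical percentiles of
#' the non-nodata values.
#'
#' @param map An `ndvi_map`.
#' @param thresholds Numeric `c(t_low, t_high)` with t_low < t_high, or the
#'   string `"tertiles"`.
#' @return A `vigour_map`: list with `grid`, `classes` (character matrix with
#'   values `"low"`, `"medium"`, `"high"` or NA), and `thresholds`.
#' @export
classify_vigour <- function(map, thresholds = "tertiles") {
  stopifnot(inherits(map, "ndvi_map"))
  v <- map$values
  if (identical(thresholds, "tertiles")) {
    ok <- v[!is.na(v)]
    if (!length(ok)) vf_stop("all-nodata map in tertile mode", "empty_map_error")
    thresholds <- unname(stats::quantile(ok, c(1 / 3, 2 / 3), type = 7))
  }
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2])
    vf_stop("thresholds must satisfy t_low < t_high", "threshold_error")
  cls <- matrix(NA_character_, nrow(v), ncol(v))
  cls[!is.na(v) & v < thresholds[1]] <- "low"
  cls[!is.na(v) & v >= thresholds[1] & v < thresholds[2]] <- "medium"
  cls[!is.na(v) & v >= thresholds[2]] <- "high"
  structure(list(grid = map$grid, classes = cls,
                 thresholds = c(t_low = thresholds[1], t_high = thresholds[2])),
            class = "vigour_map")
}
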