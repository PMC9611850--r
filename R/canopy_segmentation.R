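# Canopy / inter-row partition of the UAV grid.
#
# The three-way NDVI decomposition needs disjoint canopy (P_vin) and inter-row
# (P_int) pixel sets covering every valid UAV pixel. They are produced by NDVI
# thresholding (Otsu or fixed) followed by light morphological cleanup, with a
# projection-profile estimator for the row azimuth.

#' Estimate the vine-row azimuth from an NDVI map
#'
#' Projects pixel centres onto the axis perpendicular to each candidate row
#' direction and bins NDVI along it; the true azimuth maximises the variance of
#' that 1-D profile (rows stack on top of each other). Searches 0-180 degrees
#' in `step_deg` steps, then refines around the best candidate.
#'
#' @param map An `ndvi_map` with periodic row structure.
#' @param step_deg Coarse search step, degrees (default 0.5).
#' @param min_variance_ratio Structure detector: if the best profile variance
#'   is below this multiple of the same statistic computed on spatially
#'   shuffled values (a permutation null), the map is declared structureless
#'   (default 1.2) and NA is returned with a warning.
#' @param bin_m Profile bin width in metres (default half the pixel size).
#' @return Azimuth in \[0, 180) degrees clockwise from north, or NA.
#' @export
estimate_row_orientation <- function(map, step_deg = 0.5,
                                     min_variance_ratio = 1.2, bin_m = NULL) {
  stopifnot(inherits(map, "ndvi_map"))
  g <- map$grid
  lat0 <- g$lat_origin; lon0 <- g$lon_origin
  xy <- grid_center_xy(g, lat0, lon0)
  px_m <- g$pixel_height * M_PER_DEG_LAT
  if (is.null(bin_m)) bin_m <- px_m / 2
  ok <- !is.na(map$values)
  x <- matrix(xy$x, g$n_rows, g$n_cols, byrow = TRUE)[ok]
  y <- -matrix(xy$y, g$n_rows, g$n_cols)[ok]   # northing
  v <- map$values[ok]

  profile_var <- function(vals, az_deg) {
    az <- az_deg * pi / 180
    s <- x * cos(az) - y * sin(az)          # coordinate across rows
    b <- floor((s - min(s)) / bin_m) + 1L
    cnt <- tabulate(b)
    occ <- cnt > 0
    stats::var(rowsum(vals, b)[, 1] / cnt[occ])
  }

  cand <- seq(0, 180 - step_deg, by = step_deg)
  vars <- vapply(cand, function(a) profile_var(v, a), numeric(1))
  # permutation null: the same statistic on spatially shuffled values gives
  # the no-structure level of the max profile variance
  v_null <- v[order(stats::runif(length(v)))]
  null_max <- max(vapply(cand, function(a) profile_var(v_null, a), numeric(1)))
  if (max(vars) < min_variance_ratio * null_max) {
    vf_warn("no periodic row structure detected; azimuth undefined",
            "no_rows_warning")
    return(NA_real_)
  }
  best <- cand[which.max(vars)]
  ref <- stats::optimize(function(a) profile_var(v, a),
                         interval = c(best - step_deg, best + step_deg),
                         maximum = TRUE)
  ref$maximum %% 180
}

#' Segment canopy from inter-row soil
#'
#' Thresholds the NDVI map (Otsu's between-class-variance maximiser on a
#' 256-bin histogram, or a fixed threshold; pixels with NDVI >= threshold are
#' canopy), then applies morphological opening (disc radius 2 pixels) and
#' removes connected components smaller than `min_area_m2`. The inter-row mask
#' is the complement over valid pixels, so the two masks partition the valid
#' pixel set by construction.
#'
#' @param map An `ndvi_map` on the UAV grid.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold NDVI threshold when `method = "fixed"`.
#' @param opening_radius_px Disc radius of the morphological opening, pixels
#'   (default 2; 0 disables).
#' @param min_area_m2 Minimum connected-component area retained in the canopy
#'   mask, square metres (default 0.1).
#' @return A `pixel_partition`: `grid`, `vin_mask`, `int_mask`, `threshold`.
#' @export
segment_canopy <- function(map, method = c("otsu", "fixed"), threshold = NULL,
                           opening_radius_px = 2, min_area_m2 = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(map, "ndvi_map"))
  v <- map$values
  valid <- !is.na(v)
  if (method == "otsu") {
    vals <- v[valid]
    if (length(unique(vals)) < 2)
      vf_stop("degenerate histogram: need >= 2 distinct values for Otsu",
              "degenerate_histogram_error")
    img <- (v + 1) / 2            # rescale [-1,1] -> [0,1] for EBImage
    img[!valid] <- 0
    t01 <- EBImage::otsu(img, range = c(0, 1), levels = 256)
    threshold <- t01 * 2 - 1
  } else if (is.null(threshold)) {
    vf_stop("method = 'fixed' requires a threshold", "threshold_error")
  }
  vin <- valid & v >= threshold

  if (opening_radius_px > 0 && any(vin)) {
    brush <- EBImage::makeBrush(2L * opening_radius_px + 1L, shape = "disc")
    vin <- EBImage::opening(vin * 1, brush) > 0.5
  }
  if (min_area_m2 > 0 && any(vin)) {
    px_area <- (map$grid$pixel_height * M_PER_DEG_LAT) *
      (map$grid$pixel_width * m_per_deg_lon(map$grid$lat_origin))
    min_px <- ceiling(min_area_m2 / px_area)
    if (min_px > 1) {
      lab <- EBImage::bwlabel(vin * 1)
      sz <- tabulate(lab[lab > 0])
      drop <- which(sz < min_px)
      if (length(drop)) vin[lab %in% drop] <- FALSE
    }
  }
  vin <- vin & valid
  int <- valid & !vin
  structure(list(grid = map$grid, vin_mask = vin, int_mask = int,
                 threshold = threshold),
            class = "pixel_partition")
}

#' Build a partition from a known canopy mask
#'
#' Utility for working with simulator ground truth or externally supplied
#' masks.
#' @param grid The UAV `geo_grid`.
#' @param canopy_mask Logical matrix, TRUE on canopy.
#' @param valid Logical matrix of valid pixels (default all).
#' @return A `pixel_partition`.
#' @export
partition_from_mask <- function(grid, canopy_mask, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, grid$n_rows, grid$n_cols)
  structure(list(grid = grid, vin_mask = canopy_mask & valid,
                 int_mask = valid & !canopy_mask, threshold = NA_real_),
            class = "pixel_partition")
}

#' Intersection over union of two masks
#' @param a,b Logical matrices of equal shape.
#' @return IoU in \[0, 1\].
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
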