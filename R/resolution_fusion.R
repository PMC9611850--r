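# Core computation: match UAV pixel centres to satellite pixel footprints and
# aggregate per-pixel UAV NDVI over whole-cell / canopy / inter-row subsets.

#' Match UAV pixels to satellite cell footprints
#'
#' A UAV pixel belongs to satellite cell (i, j) iff its centre lies in the
#' half-open footprint box: longitude in \[west corner, east corner) and
#' latitude in (south corner, north corner]. Half-open boxes tile the plane, so
#' every pixel centre is assigned to at most one cell. Membership is a
#' point-in-box test on the pixel centre, not an area intersection.
#'
#' @param sat_grid,uav_grid `geo_grid`s in WGS84 degrees with overlapping
#'   extents.
#' @return A `cell_correspondence`: `cell_row`/`cell_col` (matrices over the
#'   UAV grid, 0-based satellite indices or NA), `counts` and
#'   `coverage_fraction` (matrices over the satellite grid; coverage is member
#'   count times the UAV/satellite pixel-area ratio).
#' @export
match_footprints <- function(sat_grid, uav_grid) {
  ll <- grid_center_latlon(uav_grid)
  # 0-based satellite cell indices per UAV row / column of centres
  i_of_row <- floor((sat_grid$lat_origin - ll$lat) / sat_grid$pixel_height)
  # top edge inclusive: centre exactly on alpha_s(i,j) belongs to cell i
  on_top <- (sat_grid$lat_origin - ll$lat) / sat_grid$pixel_height
  i_of_row[abs(on_top - round(on_top)) < 1e-9] <-
    round(on_top[abs(on_top - round(on_top)) < 1e-9])
  j_of_col <- floor((ll$lon - sat_grid$lon_origin) / sat_grid$pixel_width)
  i_of_row[i_of_row < 0 | i_of_row >= sat_grid$n_rows] <- NA
  j_of_col[j_of_col < 0 | j_of_col >= sat_grid$n_cols] <- NA

  cell_row <- matrix(i_of_row, uav_grid$n_rows, uav_grid$n_cols)
  cell_col <- matrix(j_of_col, uav_grid$n_rows, uav_grid$n_cols,
                     byrow = TRUE)
  cell_row[is.na(cell_col)] <- NA
  cell_col[is.na(cell_row)] <- NA

  lin <- cell_row * sat_grid$n_cols + cell_col   # 0-based linear sat id
  counts <- matrix(0L, sat_grid$n_rows, sat_grid$n_cols)
  tab <- tabulate(lin + 1L, nbins = sat_grid$n_rows * sat_grid$n_cols)
  counts <- matrix(tab, sat_grid$n_rows, sat_grid$n_cols, byrow = TRUE)

  area_ratio <- (uav_grid$pixel_height * uav_grid$pixel_width) /
    (sat_grid$pixel_height * sat_grid$pixel_width)
  cov <- pmin(counts * area_ratio, 1)

  empty <- all(counts == 0)
  if (empty)
    vf_warn("satellite and UAV extents do not overlap: empty correspondence",
            "no_overlap_warning")
  structure(list(sat_grid = sat_grid, uav_grid = uav_grid,
                 cell_row = cell_row, cell_col = cell_col,
                 counts = counts, coverage_fraction = cov, empty = empty),
            class = "cell_correspondence")
}

#' UAV member pixels of one satellite cell
#'
#' @param corr A `cell_correspondence`.
#' @param i,j 0-based satellite cell indices.
#' @return Two-column matrix of 0-based UAV (u, v) indices.
#' @export
cell_members <- function(corr, i, j) {
  hit <- which(corr$cell_row == i & corr$cell_col == j, arr.ind = TRUE)
  cbind(u = hit[, 1] - 1L, v = hit[, 2] - 1L)
}

#' Satellite NDVI map
#'
#' Per-pixel NDVI on the satellite raster (delegates to [ndvi()]), tagged with
#' provenance `"sat"`.
#' @param raster Satellite `ms_raster`.
#' @return An `ndvi_map`.
#' @export
ndvi_sat <- function(raster) ndvi(raster, provenance = "sat")

#' Aggregate UAV NDVI into satellite cells
#'
#' Per satellite cell, sums the per-UAV-pixel NDVI over the selected pixel set
#' (`all` = every member pixel; `vin` = canopy pixels; `int` = inter-row
#' pixels, per the supplied partition) and divides by a cardinality:
#' \describe{
#'   \item{`restricted`}{the size of the selected set — a true mean of the
#'     selected pixels (default).}
#'   \item{`printed`}{the size of the full member set `|P(i,j)|`, so the three
#'     components satisfy whole = canopy + inter-row exactly per cell.}
#' }
#' Cells whose UAV coverage falls below `min_coverage`, or whose selected set
#' is empty, are nodata.
#'
#' @param uav UAV `ms_raster` (NDVI computed internally) or a precomputed
#'   `ndvi_map` on the UAV grid.
#' @param corr A `cell_correspondence` built from the same UAV grid.
#' @param mask A `pixel_partition` (required for `which` = `"vin"`/`"int"`).
#' @param which `"all"`, `"vin"` or `"int"`.
#' @param denominator `"restricted"` or `"printed"`.
#' @param min_coverage Minimum cell coverage fraction (default 0.95).
#' @return An `ndvi_map` on the satellite grid.
#' @export
aggregate_ndvi <- function(uav, corr, mask = NULL,
                           which = c("all", "vin", "int"),
                           denominator = c("restricted", "printed"),
                           min_coverage = 0.95) {
  which <- match.arg(which)
  denominator <- match.arg(denominator)
  stopifnot(inherits(corr, "cell_correspondence"))
  nd <- if (inherits(uav, "ndvi_map")) uav else ndvi(uav)
  if (!grids_equal(nd$grid, corr$uav_grid))
    vf_stop("UAV raster grid does not match the correspondence", "grid_error")
  if (which != "all") {
    if (is.null(mask))
      vf_stop("a pixel partition is required for which = 'vin'/'int'",
              "grid_error")
    if (!grids_equal(mask$grid, nd$grid))
      vf_stop("mask grid does not match the UAV grid", "grid_error")
  }

  sat <- corr$sat_grid
  ncell <- sat$n_rows * sat$n_cols
  lin <- corr$cell_row * sat$n_cols + corr$cell_col + 1L  # 1-based linear id
  valid <- !is.na(nd$values) & !is.na(lin)

  sel <- switch(which,
                all = valid,
                vin = valid & mask$vin_mask,
                int = valid & mask$int_mask)

  sums <- numeric(ncell)
  agg <- tapply(nd$values[sel], lin[sel], sum)
  sums[as.integer(names(agg))] <- agg
  n_sel <- tabulate(lin[sel], nbins = ncell)
  n_all <- tabulate(lin[valid], nbins = ncell)

  denom <- if (denominator == "restricted") n_sel else n_all
  out <- ifelse(denom > 0 & n_sel > 0, sums / denom, NA_real_)
  out <- matrix(out, sat$n_rows, sat$n_cols, byrow = TRUE)
  out[corr$coverage_fraction < min_coverage] <- NA_real_
  prov <- c(all = "uav", vin = "vin", int = "int")[[which]]
  ndvi_map(sat, out, provenance = prov)
}

#' Compare two maps on a shared grid
#'
#' @param a,b `ndvi_map`s on the same grid with at least two jointly valid
#'   cells.
#' @return One-row tibble: `bias` (mean of b - a), `rmse`, `correlation`, `n`.
#' @export
compare_maps <- function(a, b) {
  stopifnot(inherits(a, "ndvi_map"), inherits(b, "ndvi_map"))
  if (!grids_equal(a$grid, b$grid))
    vf_stop("maps are on different grids", "grid_error")
  ok <- !is.na(a$values) & !is.na(b$values)
  n <- sum(ok)
  if (n < 2)
    vf_stop("fewer than 2 jointly valid cells", "insufficient_data_error")
  x <- a$values[ok]; y <- b$values[ok]
  d <- y - x
  corr <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (all(abs(d - d[1]) < 1e-15)) 1 else NA_real_
  } else stats::cor(x, y)
  tibble::tibble(bias = mean(d), rmse = sqrt(mean(d^2)),
                 correlation = corr, n = n)
}
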