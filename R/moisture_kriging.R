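# Soil-moisture data fusion by ordinary kriging.
#
# Covariates (rainfall, NDVI, soil class, ...) observed at target points yield
# moisture estimates via a linear link; those estimates are kriged to the
# locations of in-situ capacitance sensors, and the variogram parameters plus
# link coefficients are tuned by exhaustive grid search until the kriged and
# measured values agree — the calibrated configuration then extends to
# neighbouring, unsensed areas.

#' Variogram model
#'
#' @param family `"exponential"`, `"spherical"` or `"gaussian"`.
#' @param nugget Nugget variance, >= 0.
#' @param sill Partial sill (variance above the nugget), > 0.
#' @param range_m Range parameter in metres, > 0.
#' @return A `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                            nugget, sill, range_m) {
  family <- match.arg(family)
  if (nugget < 0 || sill <= 0 || range_m <= 0)
    vf_stop("need nugget >= 0, sill > 0, range_m > 0", "variogram_error")
  structure(list(family = family, nugget = nugget, sill = sill,
                 range_m = range_m), class = "variogram_model")
}

#' Model semivariance at lag distances
#'
#' gamma(0) = 0 exactly (the nugget is the limit from above); gamma is
#' non-decreasing in h for all three families.
#' @param vgm A `variogram_model`.
#' @param h Lag distances, metres.
#' @return Semivariance values.
#' @export
semivariance <- function(vgm, h) {
  structural <- switch(vgm$family,
    exponential = 1 - exp(-3 * h / vgm$range_m),
    gaussian = 1 - exp(-3 * (h / vgm$range_m)^2),
    spherical = ifelse(h >= vgm$range_m, 1,
                       1.5 * h / vgm$range_m - 0.5 * (h / vgm$range_m)^3))
  out <- vgm$nugget + vgm$sill * structural
  out[h == 0] <- 0
  out
}

# Local metric projection: azimuthal-equidistant about a reference point, which
# for field-scale extents reduces to scaling degrees by the metres-per-degree
# factors at the reference latitude. Degrees are anisotropic in metres, so
# distances are never taken on raw coordinates.
local_xy <- function(lat, lon, lat0 = NULL, lon0 = NULL) {
  if (is.null(lat0)) lat0 <- mean(lat)
  if (is.null(lon0)) lon0 <- mean(lon)
  list(x = (lon - lon0) * m_per_deg_lon(lat0),
       y = (lat - lat0) * M_PER_DEG_LAT, lat0 = lat0, lon0 = lon0)
}

dist_m <- function(lat1, lon1, lat2, lon2, lat0) {
  sqrt(((lon1 - lon2) * m_per_deg_lon(lat0))^2 +
       ((lat1 - lat2) * M_PER_DEG_LAT)^2)
}

#' Estimate soil moisture at points from covariates
#'
#' Linear link: moisture = intercept + sum(coeff_k * covariate_k), clipped to
#' the sensor calibration range \[0, 0.57\] VWC.
#'
#' @param points Data frame with `lat`, `lon` and one column per covariate.
#' @param coefficients Named numeric vector; must contain `intercept`, other
#'   names must match covariate columns.
#' @return A tibble of covariate samples with a `moisture_estimate` column.
#' @export
estimate_moisture_at_points <- function(points, coefficients) {
  if (!"intercept" %in% names(coefficients))
    vf_stop("coefficients must include an 'intercept'", "coefficient_error")
  covs <- setdiff(names(coefficients), "intercept")
  missing_cov <- setdiff(covs, names(points))
  if (length(missing_cov))
    vf_stop(paste("missing covariate at points:",
                  paste(missing_cov, collapse = ", ")), "missing_data_error")
  if (any(vapply(points[covs], function(x) any(is.na(x)), logical(1))))
    vf_stop("NA covariate value at a point", "missing_data_error")
  est <- rep(coefficients[["intercept"]], nrow(points))
  for (k in covs) est <- est + coefficients[[k]] * points[[k]]
  out <- tibble::as_tibble(points)
  out$moisture_estimate <- pmin(pmax(est, 0), VWC_MAX)
  out
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system (semivariance matrix augmented with a
#' Lagrange multiplier enforcing sum(weights) = 1) once for all targets;
#' distances are computed on the local metric projection.
#'
#' @param samples Data frame with `lat`, `lon` and a value column
#'   (`moisture_estimate` or `value`).
#' @param vgm A `variogram_model`.
#' @param targets Data frame with `lat`, `lon`.
#' @return A tibble with `lat`, `lon`, `estimate`, `variance`; the kriging
#'   weight matrix (targets x samples) is attached as attribute `"weights"`.
#' @export
krige <- function(samples, vgm, targets) {
  z <- samples$moisture_estimate
  if (is.null(z)) z <- samples$value
  if (is.null(z)) vf_stop("samples need a value column", "format_error")
  n <- nrow(samples)
  if (n < 1) vf_stop("need at least one sample", "insufficient_data_error")
  lat0 <- mean(samples$lat)

  if (n == 1) {
    est <- rep(z, nrow(targets))
    h0 <- dist_m(targets$lat, targets$lon, samples$lat, samples$lon, lat0)
    return(structure(tibble::tibble(lat = targets$lat, lon = targets$lon,
                                    estimate = est,
                                    variance = 2 * semivariance(vgm, h0)),
                     weights = matrix(1, nrow(targets), 1)))
  }

  H <- as.matrix(stats::dist(cbind((samples$lon - mean(samples$lon)) *
                                     m_per_deg_lon(lat0),
                                   (samples$lat - lat0) * M_PER_DEG_LAT)))
  if (any(H[upper.tri(H)] < 1e-9))
    vf_stop("duplicate sample locations make the kriging system singular",
            "geometry_error")
  A <- rbind(cbind(semivariance(vgm, H), 1), c(rep(1, n), 0))

  h_t <- outer(seq_len(nrow(targets)), seq_len(n), function(ti, si)
    dist_m(targets$lat[ti], targets$lon[ti],
           samples$lat[si], samples$lon[si], lat0))
  B <- rbind(t(semivariance(vgm, h_t)), 1)
  sol <- solve(A, B)                       # (n+1) x n_targets
  W <- t(sol[seq_len(n), , drop = FALSE])  # targets x samples
  mu <- sol[n + 1, ]
  est <- as.numeric(W %*% z)
  varr <- rowSums(W * t(B[seq_len(n), , drop = FALSE])) + mu
  structure(tibble::tibble(lat = targets$lat, lon = targets$lon,
                           estimate = est, variance = pmax(varr, 0)),
            weights = W)
}

#' Empirical semivariogram
#'
#' @param samples Data frame with `lat`, `lon` and a value column.
#' @param n_bins Number of lag bins (default 15) up to half the maximum
#'   pairwise distance.
#' @return Tibble with `h` (bin-mean lag, m), `gamma` (mean semivariance),
#'   `n_pairs`.
#' @export
empirical_variogram <- function(samples, n_bins = 15) {
  z <- samples$moisture_estimate
  if (is.null(z)) z <- samples$value
  lat0 <- mean(samples$lat)
  xy <- cbind((samples$lon - mean(samples$lon)) * m_per_deg_lon(lat0),
              (samples$lat - lat0) * M_PER_DEG_LAT)
  H <- as.matrix(stats::dist(xy))
  iu <- upper.tri(H)
  h <- H[iu]
  gsq <- 0.5 * outer(z, z, "-")[iu]^2
  hmax <- max(h) / 2
  keep <- h <= hmax & h > 0
  b <- factor(pmin(floor(h[keep] / (hmax / n_bins)) + 1L, n_bins),
              levels = seq_len(n_bins))
  out <- tibble::tibble(
    h = as.numeric(tapply(h[keep], b, mean)),
    gamma = as.numeric(tapply(gsq[keep], b, mean)),
    n_pairs = as.integer(tabulate(b, nbins = n_bins)))
  out[out$n_pairs > 0, ]
}

#' Fit a variogram model to samples
#'
#' Weighted least squares (weights = pair count / squared lag, emphasising the
#' informative short lags) of the chosen family to the
#' empirical semivariogram, parameters constrained to `bounds`.
#'
#' @param samples Data frame with `lat`, `lon` and a value column (>= 10
#'   rows).
#' @param family Variogram family.
#' @param bounds List with `nugget`, `sill`, `range_m`, each `c(lo, hi)`;
#'   defaults are data-driven.
#' @return A `variogram_model` with the empirical variogram attached as
#'   attribute `"empirical"`.
#' @export
fit_variogram <- function(samples, family = "exponential", bounds = NULL) {
  if (nrow(samples) < 10)
    vf_stop("need at least 10 samples to fit a variogram",
            "insufficient_data_error")
  ev <- empirical_variogram(samples)
  ev <- ev[is.finite(ev$gamma), ]
  z <- samples$moisture_estimate
  if (is.null(z)) z <- samples$value
  vz <- stats::var(z)
  if (vz < 1e-20) {
    vgm <- variogram_model(family, nugget = 0, sill = 1e-12,
                           range_m = max(ev$h))
    attr(vgm, "empirical") <- ev
    return(vgm)
  }
  if (is.null(bounds))
    bounds <- list(nugget = c(0, vz), sill = c(1e-10, 4 * vz),
                   range_m = c(max(ev$h) / 100, 4 * max(ev$h)))
  w <- ev$n_pairs / ev$h^2   # short lags carry the shape information
  obj <- function(p) {
    vgm <- variogram_model(family, nugget = p[1], sill = max(p[2], 1e-12),
                           range_m = max(p[3], 1e-9))
    sum(w * (semivariance(vgm, ev$h) - ev$gamma)^2)
  }
  start <- c(nugget = min(ev$gamma) / 2, sill = max(vz, 1e-10),
             range_m = max(ev$h) / 3)
  lo <- c(bounds$nugget[1], bounds$sill[1], bounds$range_m[1])
  hi <- c(bounds$nugget[2], bounds$sill[2], bounds$range_m[2])
  fit <- stats::optim(pmin(pmax(start, lo), hi), obj, method = "L-BFGS-B",
                      lower = lo, upper = hi)
  vgm <- variogram_model(family, nugget = fit$par[1],
                         sill = max(fit$par[2], 1e-12),
                         range_m = max(fit$par[3], 1e-9))
  attr(vgm, "empirical") <- ev
  vgm
}

#' Calibrate kriging against in-situ sensors
#'
#' Exhaustive search over a parameter grid of variogram parameters and
#' covariate-link coefficients: for each configuration, moisture is estimated
#' at the covariate points, kriged to the sensor locations, and scored by mean
#' absolute error against the measured values. Ties break toward the smaller
#' nugget, then the smaller range.
#'
#' @param covariate_points Data frame with `lat`, `lon` and covariate columns.
#' @param sensor_readings Sensor tibble (as from [read_sensor_table()] or
#'   [sample_sensors()]); only `soil_moisture_vwc` rows are used.
#' @param param_grid Data frame; columns `nugget`, `sill`, `range_m`,
#'   optionally `family`, plus `intercept` and one column per covariate
#'   coefficient.
#' @return List: `vgm` (winning `variogram_model`), `coefficients` (named
#'   vector), `residuals` (per sensor), `mae`, `grid_mae` (score per
#'   configuration).
#' @export
calibrate_against_sensors <- function(covariate_points, sensor_readings,
                                      param_grid) {
  sens <- sensor_readings[sensor_readings$kind == "soil_moisture_vwc", ]
  if (nrow(sens) < 1)
    vf_stop("no soil-moisture sensor readings to calibrate against",
            "kind_error")
  if (nrow(param_grid) < 1) vf_stop("empty parameter grid", "config_error")
  vg_cols <- c("nugget", "sill", "range_m")
  if (!all(vg_cols %in% names(param_grid)))
    vf_stop("param_grid needs columns nugget, sill, range_m", "config_error")
  coef_cols <- setdiff(names(param_grid), c(vg_cols, "family"))
  if (!"intercept" %in% coef_cols)
    vf_stop("param_grid needs an 'intercept' column", "config_error")
  targets <- sens[, c("lat", "lon")]

  score <- numeric(nrow(param_grid))
  resids <- vector("list", nrow(param_grid))
  for (r in seq_len(nrow(param_grid))) {
    fam <- if ("family" %in% names(param_grid))
      param_grid$family[r] else "exponential"
    vgm <- variogram_model(fam, param_grid$nugget[r], param_grid$sill[r],
                           param_grid$range_m[r])
    coefs <- stats::setNames(as.numeric(param_grid[r, coef_cols]), coef_cols)
    smp <- estimate_moisture_at_points(covariate_points, coefs)
    kr <- krige(smp, vgm, targets)
    resids[[r]] <- kr$estimate - sens$value
    score[r] <- mean(abs(resids[[r]]))
  }
  ord <- order(score, param_grid$nugget, param_grid$range_m)
  best <- ord[1]
  fam <- if ("family" %in% names(param_grid))
    param_grid$family[best] else "exponential"
  list(vgm = variogram_model(fam, param_grid$nugget[best],
                             param_grid$sill[best], param_grid$range_m[best]),
       coefficients = stats::setNames(as.numeric(param_grid[best, coef_cols]),
                                      coef_cols),
       residuals = resids[[best]], mae = score[best], grid_mae = score)
}
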