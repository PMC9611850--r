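# End-to-end pipeline: simulate -> ndvi -> segment -> fuse -> krige/calibrate
# -> advise -> route, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' A single nested list drives every stage; unknown keys are rejected by
#' [validate_config()]. One global seed fans out deterministically to
#' per-stage seeds (`stage_seed = (seed * 1000 + stage index) mod 2^31`), so a
#' partial rerun of any stage reproduces the full run's values.
#'
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, field_width_m = 50, field_height_m = 50,
                    row_spacing_m = 2, canopy_width_m = 1,
                    row_azimuth_deg = 0, vigour_base = 0.7,
                    gt_res_m = 0.1, noise_sd = 0.01,
                    uav_gsd_m = 0.1, sat_gsd_m = 10, n_sensors = 12,
                    sensor_noise_sd = 0.01),
    segment = list(enabled = TRUE, method = "otsu"),
    fuse = list(denominator = "restricted", min_coverage = 0.95,
                which = c("all", "vin", "int")),
    krige = list(family = "exponential",
                 nugget_grid = c(0, 1e-4), range_grid_m = c(10, 20, 40),
                 sill_grid = c(1e-3, 5e-3), n_covariate_points = 60),
    advise = list(moisture_min = 0.22, ndvi_min = 0.55,
                  depot = NULL),
    route = list(pop_size = 60, generations = 150, crossover_rate = 0.9,
                 mutation_rate = 0.2)),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks the key schema against [default_pipeline_config()] (unknown keys are
#' rejected, missing keys filled from the defaults) and cross-stage
#' dependencies (canopy/inter-row fusion requires segmentation).
#'
#' @param config A `pipeline_config` or plain named list.
#' @return The completed, validated `pipeline_config`.
#' @export
validate_config <- function(config) {
  ref <- unclass(default_pipeline_config())
  config <- unclass(config)
  bad <- setdiff(names(config), names(ref))
  if (length(bad))
    vf_stop(paste("unknown config keys:", paste(bad, collapse = ", ")),
            "config_error")
  for (stage in names(ref)) {
    if (is.null(config[[stage]])) { config[[stage]] <- ref[[stage]]; next }
    if (is.list(ref[[stage]])) {
      bad <- setdiff(names(config[[stage]]), names(ref[[stage]]))
      if (length(bad))
        vf_stop(paste0("unknown config keys in '", stage, "': ",
                       paste(bad, collapse = ", ")), "config_error")
      config[[stage]] <- utils::modifyList(ref[[stage]], config[[stage]])
    }
  }
  if (any(c("vin", "int") %in% config$fuse$which) && !config$segment$enabled)
    vf_stop("fusing 'vin'/'int' requires the segmentation stage", "config_error")
  structure(config, class = "pipeline_config")
}

stage_seed <- function(seed, k) as.integer((seed * 1000 + k) %% .Machine$integer.max)

write_geojson_points <- function(df, path, properties = setdiff(names(df), c("lat", "lon"))) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = as.list(df[i, properties, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_geojson_route <- function(plan, path) {
  coords <- mapply(function(lo, la) c(lo, la), plan$waypoints$lon,
                   plan$waypoints$lat, SIMPLIFY = FALSE)
  jsonlite::write_json(list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      geometry = list(type = "LineString", coordinates = coords),
      properties = list(total_length_m = plan$total_length_m,
                        objective_value = plan$objective_value,
                        seed = plan$seed, generations = plan$generations)))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate, NDVI, segmentation, footprint matching + the three
#' aggregated NDVI maps, kriging calibration against the simulated sensors,
#' attention-point detection and GA route planning, writing every product and
#' a manifest (config, per-stage seeds, outputs with MD5 checksums) under
#' `out_dir`. Rerunning with an identical config reproduces identical
#' checksums.
#'
#' @param config A `pipeline_config` (validated on entry).
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(config = unclass(config), stages = list())
  outputs <- character()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # -- simulate ------------------------------------------------------------
  sc <- config$simulate
  cfg <- sim_config(field_width_m = sc$field_width_m,
                    field_height_m = sc$field_height_m,
                    row_spacing_m = sc$row_spacing_m,
                    canopy_width_m = sc$canopy_width_m,
                    row_azimuth_deg = sc$row_azimuth_deg,
                    vigour_base = sc$vigour_base, gt_res_m = sc$gt_res_m,
                    noise_sd = sc$noise_sd, seed = stage_seed(seed, 1))
  scene <- simulate_scene(cfg)
  uav <- render_uav(scene, sc$uav_gsd_m)
  sat <- render_satellite(scene, sc$sat_gsd_m)
  set.seed(stage_seed(seed, 2))
  g <- scene$grid
  sensor_loc <- data.frame(
    lat = stats::runif(sc$n_sensors,
                       g$lat_origin - (g$n_rows - 1) * g$pixel_height,
                       g$lat_origin - g$pixel_height),
    lon = stats::runif(sc$n_sensors,
                       g$lon_origin + g$pixel_width,
                       g$lon_origin + (g$n_cols - 1) * g$pixel_width))
  sensors <- sample_sensors(scene, sensor_loc, noise_sd = sc$sensor_noise_sd,
                            seed = stage_seed(seed, 3))
  f_uav <- file.path(out_dir, "uav.tif")
  f_sat <- file.path(out_dir, "sat.tif")
  write_raster(uav, f_uav, overwrite = TRUE)
  write_raster(sat, f_sat, overwrite = TRUE)
  f_sens <- file.path(out_dir, "sensors.csv")
  utils::write.csv(sensors, f_sens, row.names = FALSE)
  outputs <- c(outputs, f_uav, f_sat, f_sens)
  note("simulate", seed = cfg$seed,
       outputs = basename(c(f_uav, f_sat, f_sens)))

  # -- ndvi ----------------------------------------------------------------
  nd_uav <- ndvi(uav)
  nd_sat <- ndvi_sat(sat)
  f_ndvi <- file.path(out_dir, "ndvi_uav.tif")
  write_raster(nd_uav, f_ndvi, overwrite = TRUE)
  outputs <- c(outputs, f_ndvi)
  note("ndvi", outputs = basename(f_ndvi))

  # -- segment -------------------------------------------------------------
  part <- NULL
  if (config$segment$enabled) {
    part <- segment_canopy(nd_uav, method = config$segment$method)
    note("segment", threshold = part$threshold,
         canopy_fraction = mean(part$vin_mask))
  }

  # -- fuse ----------------------------------------------------------------
  corr <- match_footprints(sat$grid, uav$grid)
  fused <- list()
  for (w in config$fuse$which) {
    m <- aggregate_ndvi(nd_uav, corr, mask = part, which = w,
                        denominator = config$fuse$denominator,
                        min_coverage = config$fuse$min_coverage)
    f <- file.path(out_dir, paste0("ndvi_", m$provenance, "_agg.tif"))
    write_raster(m, f, overwrite = TRUE)
    outputs <- c(outputs, f)
    fused[[w]] <- m
  }
  cmp <- compare_maps(fused$all, nd_sat)
  note("fuse", outputs = paste0("ndvi_", vapply(fused, function(m) m$provenance,
                                                ""), "_agg.tif"),
       sat_vs_uav_bias = cmp$bias, sat_vs_uav_rmse = cmp$rmse)

  # -- krige / calibrate ---------------------------------------------------
  kc <- config$krige
  set.seed(stage_seed(seed, 4))
  cov_pts <- data.frame(
    lat = stats::runif(kc$n_covariate_points,
                       g$lat_origin - (g$n_rows - 1) * g$pixel_height,
                       g$lat_origin - g$pixel_height),
    lon = stats::runif(kc$n_covariate_points,
                       g$lon_origin + g$pixel_width,
                       g$lon_origin + (g$n_cols - 1) * g$pixel_width))
  # moisture covariate read from the scene field (stand-in for rainfall/NDVI
  # driven regression; the true link is identity)
  u <- floor((g$lat_origin - cov_pts$lat) / g$pixel_height) + 1
  v <- floor((cov_pts$lon - g$lon_origin) / g$pixel_width) + 1
  cov_pts$moisture_proxy <- scene$moisture_field[cbind(u, v)]
  grid_df <- expand.grid(nugget = kc$nugget_grid, sill = kc$sill_grid,
                         range_m = kc$range_grid_m)
  grid_df$intercept <- 0
  grid_df$moisture_proxy <- 1
  cal <- calibrate_against_sensors(cov_pts, sensors, grid_df)
  smp <- estimate_moisture_at_points(cov_pts, cal$coefficients)
  sat_ctr <- grid_center_latlon(sat$grid)
  targets <- expand.grid(lat = sat_ctr$lat, lon = sat_ctr$lon)
  kr <- krige(smp, cal$vgm, targets)
  moist_mat <- matrix(kr$estimate, sat$grid$n_rows, sat$grid$n_cols)
  f_kr <- file.path(out_dir, "moisture_kriged.csv")
  utils::write.csv(kr, f_kr, row.names = FALSE)
  outputs <- c(outputs, f_kr)
  note("krige", mae = cal$mae, nugget = cal$vgm$nugget, sill = cal$vgm$sill,
       range_m = cal$vgm$range_m, outputs = basename(f_kr))

  # -- advise --------------------------------------------------------------
  av <- config$advise
  ndvi_vin_map <- if (!is.null(fused$vin)) fused$vin else fused$all
  pts <- detect_attention_points(ndvi_vin_map, moist_mat,
                                 rules = list(moisture_min = av$moisture_min,
                                              ndvi_min = av$ndvi_min))
  f_pts <- file.path(out_dir, "attention_points.geojson")
  write_geojson_points(pts, f_pts)
  outputs <- c(outputs, f_pts)
  f_alerts <- file.path(out_dir, "alerts.jsonl")
  con <- file(f_alerts, "w")
  if (nrow(pts)) for (i in seq_len(nrow(pts))) {
    reasons <- c("irrigation", "fertilisation")[c(pts$irrigation[i],
                                                  pts$fertilisation[i])]
    for (rs in reasons)
      writeLines(jsonlite::toJSON(list(reason = rs,
                                       cell = c(pts$row[i], pts$col[i]),
                                       severity = pts$severity[i]),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  close(con)
  outputs <- c(outputs, f_alerts)
  note("advise", n_points = nrow(pts), outputs = basename(c(f_pts, f_alerts)))

  # -- route ---------------------------------------------------------------
  depot <- av$depot
  if (is.null(depot)) depot <- c(g$lat_origin, g$lon_origin)
  rt <- config$route
  plan <- withCallingHandlers(
    plan_route(pts, depot,
               ga = list(pop_size = rt$pop_size, generations = rt$generations,
                         crossover_rate = rt$crossover_rate,
                         mutation_rate = rt$mutation_rate,
                         seed = stage_seed(seed, 5))),
    vinefuse_warning = function(w) invokeRestart("muffleWarning"))
  f_rt <- file.path(out_dir, "route.geojson")
  write_geojson_route(plan, f_rt)
  outputs <- c(outputs, f_rt)
  note("route", total_length_m = plan$total_length_m,
       objective_value = plan$objective_value,
       n_waypoints = nrow(plan$waypoints), outputs = basename(f_rt))

  # -- manifest ------------------------------------------------------------
  outputs <- c(outputs, paste0(grep("\\.tif$", outputs, value = TRUE),
                               ".aux.json"))
  checks <- tools::md5sum(sort(unique(outputs)))
  manifest$outputs <- lapply(stats::setNames(names(checks), basename(names(checks))),
                             function(p) unname(checks[p]))
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
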