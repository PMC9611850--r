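# Attention-point alerting and GA route ordering.
#
# Cells whose canopy NDVI or soil moisture falls below management thresholds
# become attention points (irrigation / fertilisation reasons, severity = sum
# of threshold-shortfall fractions); a permutation-encoded genetic algorithm
# orders the visit so a tractor covers them efficiently, trading leg distance
# against visiting severe points early.

#' Detect irrigation/fertilisation attention points
#'
#' @param ndvi_vin Canopy `ndvi_map` on the management (satellite) grid.
#' @param moisture Matrix of VWC on the same grid, or an `ndvi_map`-shaped
#'   object whose `values` hold VWC.
#' @param rules List with `moisture_min` (VWC) and `ndvi_min` (NDVI);
#'   a cell is flagged for irrigation iff moisture < moisture_min and for
#'   fertilisation iff canopy NDVI < ndvi_min.
#' @return Tibble: `lat`, `lon` (cell centre), `row`, `col` (0-based),
#'   logical `irrigation`, `fertilisation`, and `severity` (sum over triggered
#'   reasons of (threshold - value) / threshold). Nodata cells are never
#'   flagged.
#' @export
detect_attention_points <- function(ndvi_vin, moisture,
                                    rules = list(moisture_min = 0.15,
                                                 ndvi_min = 0.4)) {
  stopifnot(inherits(ndvi_vin, "ndvi_map"))
  mo <- if (is.matrix(moisture)) moisture else moisture$values
  g <- ndvi_vin$grid
  if (!all(dim(mo) == c(g$n_rows, g$n_cols)))
    vf_stop("moisture layer does not share the NDVI grid", "grid_error")
  nv <- ndvi_vin$values
  irr <- !is.na(mo) & mo < rules$moisture_min
  fert <- !is.na(nv) & nv < rules$ndvi_min
  hit <- which(irr | fert, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(tibble::tibble(lat = numeric(), lon = numeric(),
                          row = integer(), col = integer(),
                          irrigation = logical(), fertilisation = logical(),
                          severity = numeric()))
  u <- unname(hit[, 1]) - 1L; v <- unname(hit[, 2]) - 1L
  ctr <- pixel_center(g, u, v)
  sev <- unname(ifelse(irr[hit], (rules$moisture_min - mo[hit]) / rules$moisture_min,
                0) +
         ifelse(fert[hit], (rules$ndvi_min - nv[hit]) / rules$ndvi_min, 0))
  out <- tibble::tibble(lat = unname(ctr$lat), lon = unname(ctr$lon),
                        row = u, col = v,
                        irrigation = irr[hit], fertilisation = fert[hit],
                        severity = sev)
  out[order(out$row, out$col), ]
}

# total length + severity-rank penalty of each permutation row of P
# (matrix pop x n of 1-based point indices); D is the (n+1) x (n+1) distance
# matrix with the depot at index n+1.
route_objective_pop <- function(P, D, severity, w_dist, w_priority) {
  n <- ncol(P); depot <- n + 1L
  len <- D[cbind(rep(depot, nrow(P)), P[, 1])] +
         D[cbind(P[, n], rep(depot, nrow(P)))]
  if (n > 1)
    for (k in seq_len(n - 1))
      len <- len + D[cbind(P[, k], P[, k + 1])]
  pri <- if (w_priority != 0) {
    sev_m <- matrix(severity[t(P)], nrow(P), n, byrow = TRUE)
    as.numeric(sev_m %*% seq_len(n))
  } else 0
  list(len = len, obj = w_dist * len + w_priority * pri)
}

# order crossover (OX): copy a random slice from parent a, fill the rest in
# parent-b order
ox_crossover <- function(a, b) {
  n <- length(a)
  cut <- sort(sample.int(n, 2))
  child <- integer(n)
  seg <- a[cut[1]:cut[2]]
  child[cut[1]:cut[2]] <- seg
  rest <- b[!(b %in% seg)]
  child[-(cut[1]:cut[2])] <- rest
  child
}

#' Plan a visiting route over attention points
#'
#' Permutation-encoded genetic algorithm: tournament selection (size 3), order
#' crossover, segment-inversion mutation and elitism of one, minimising
#' `w_dist * total_length + w_priority * sum(visit_rank * severity)`. The
#' route starts and ends at the depot; leg distances are straight lines on the
#' local metric projection. Deterministic given `ga$seed`.
#'
#' @param points Tibble from [detect_attention_points()] (needs `lat`, `lon`,
#'   `severity`).
#' @param depot `c(lat, lon)` of the start/end point.
#' @param ga List: `pop_size` (default 100), `generations` (300),
#'   `crossover_rate` (0.9), `mutation_rate` (0.2), `seed` (1).
#' @param weights `c(w_dist, w_priority)`; default `c(1, 0)` = shortest tour.
#' @return A `route_plan`: `order` (visit order, 1-based into `points`),
#'   `waypoints` (tibble, depot first and last), `total_length_m`,
#'   `objective_value`, `seed`, `generations`, `history` (best objective per
#'   generation).
#' @export
plan_route <- function(points, depot,
                       ga = list(), weights = c(w_dist = 1, w_priority = 0)) {
  ga <- utils::modifyList(list(pop_size = 100L, generations = 300L,
                               crossover_rate = 0.9, mutation_rate = 0.2,
                               seed = 1L), ga)
  n <- nrow(points)
  if (n == 0) {
    vf_warn("no attention points: returning a depot-only route",
            "empty_route_warning")
    wp <- tibble::tibble(lat = depot[1], lon = depot[2], label = "depot")
    return(structure(list(order = integer(), waypoints = wp,
                          total_length_m = 0, objective_value = 0,
                          seed = ga$seed, generations = 0L,
                          history = numeric()),
                     class = "route_plan"))
  }
  lat <- c(points$lat, depot[1]); lon <- c(points$lon, depot[2])
  lat0 <- mean(lat)
  D <- as.matrix(stats::dist(cbind((lon - mean(lon)) * m_per_deg_lon(lat0),
                                   (lat - lat0) * M_PER_DEG_LAT)))
  sev <- points$severity
  w_dist <- weights[[1]]; w_priority <- weights[[2]]

  set.seed(ga$seed)
  if (n == 1) {
    best <- 1L
    sc <- route_objective_pop(matrix(1L, 1, 1), D, sev, w_dist, w_priority)
    history <- rep(sc$obj, 1)
    best_len <- sc$len; best_obj <- sc$obj
    gens <- 0L
  } else {
    pop <- t(replicate(ga$pop_size, sample.int(n)))
    sc <- route_objective_pop(pop, D, sev, w_dist, w_priority)
    history <- numeric(ga$generations)
    for (g in seq_len(ga$generations)) {
      fit <- sc$obj
      elite_i <- which.min(fit)
      newpop <- matrix(0L, ga$pop_size, n)
      newpop[1, ] <- pop[elite_i, ]
      for (k in 2:ga$pop_size) {
        # tournament selection, size 3
        t1 <- sample.int(ga$pop_size, 3); p1 <- pop[t1[which.min(fit[t1])], ]
        if (stats::runif(1) < ga$crossover_rate) {
          t2 <- sample.int(ga$pop_size, 3)
          p2 <- pop[t2[which.min(fit[t2])], ]
          child <- ox_crossover(p1, p2)
        } else child <- p1
        if (stats::runif(1) < ga$mutation_rate) {
          # segment inversion (2-opt move): the standard tour mutation
          sw <- sort(sample.int(n, 2))
          child[sw[1]:sw[2]] <- child[sw[2]:sw[1]]
        }
        newpop[k, ] <- child
      }
      pop <- newpop
      sc <- route_objective_pop(pop, D, sev, w_dist, w_priority)
      history[g] <- min(sc$obj)
    }
    best_i <- which.min(sc$obj)
    best <- pop[best_i, ]
    best_len <- sc$len[best_i]; best_obj <- sc$obj[best_i]
    gens <- ga$generations
  }
  wp <- tibble::tibble(
    lat = c(depot[1], points$lat[best], depot[1]),
    lon = c(depot[2], points$lon[best], depot[2]),
    label = c("depot", paste0("point_", best), "depot"))
  structure(list(order = best, waypoints = wp, total_length_m = best_len,
                 objective_value = best_obj, seed = ga$seed,
                 generations = gens, history = history),
            class = "route_plan")
}

#' Exhaustive-optimum route objective (small n)
#'
#' Enumerates every permutation; usable as an independent optimality check for
#' up to ~9 points.
#' @inheritParams plan_route
#' @return List: `order`, `objective_value`, `total_length_m`.
#' @export
brute_force_route <- function(points, depot,
                              weights = c(w_dist = 1, w_priority = 0)) {
  n <- nrow(points)
  if (n > 9) vf_stop("brute force limited to 9 points", "config_error")
  lat <- c(points$lat, depot[1]); lon <- c(points$lon, depot[2])
  lat0 <- mean(lat)
  D <- as.matrix(stats::dist(cbind((lon - mean(lon)) * m_per_deg_lon(lat0),
                                   (lat - lat0) * M_PER_DEG_LAT)))
  perms <- all_permutations(n)
  sc <- route_objective_pop(perms, D, points$severity,
                            weights[[1]], weights[[2]])
  i <- which.min(sc$obj)
  list(order = perms[i, ], objective_value = sc$obj[i],
       total_length_m = sc$len[i])
}

# all n! permutations of 1..n as a matrix (recursive construction)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  storage.mode(out) <- "integer"
  out
}
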