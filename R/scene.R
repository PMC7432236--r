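#' Scene configuration for the synthetic district generator
#'
#' Bundles every knob of the synthetic scene: the analysis extent and grid
#' resolution, district composition (statistical zones, buildings,
#' population), the outdoor log-field model (median level, log-variance,
#' correlation range, hotspots), and the diurnal signal model for the
#' monitoring-network emulator.
#'
#' The defaults describe a dense European inner-city district: a 2 x 2 km
#' extent gridded at 100 m, about 24,000 inhabitants per square kilometre
#' with 14% children under 15, an outdoor downlink field with median about
#' 0.6 V/m, log-variance 0.35 and 300 m correlation range, plus two localized
#' hotspots, and afternoon-peaking diurnal network-load curves for the three
#' downlink monitoring bands (900/1800/2100 MHz).
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in metres (local planar
#'   projected frame).
#' @param cell_size grid cell edge in metres (default 100).
#' @param n_zones number of census zones tiling the extent.
#' @param n_buildings number of buildings.
#' @param field_params list: `median_level` (V/m), `log_var` (variance of the
#'   natural-log field), `range_m` (exponential correlation range),
#'   `hotspots` (list of `list(x, y, amp, radius)` additive log-mean bumps,
#'   or `NULL`).
#' @param diurnal_params list: `amplitude` and `phase_h` per monitoring band,
#'   `noise_sdlog` multiplicative measurement noise.
#' @param population list: `total` residents (default from 24,000 per km2),
#'   `child_fraction`, `occupational_total`.
#' @param seed integer run seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(extent = c(0, 0, 2000, 2000),
                         cell_size = 100,
                         n_zones = 12,
                         n_buildings = 150,
                         field_params = list(),
                         diurnal_params = list(),
                         population = list(),
                         seed = 1L) {
  stopifnot(length(extent) == 4, is.numeric(extent))
  width <- extent[3] - extent[1]
  height <- extent[4] - extent[2]
  if (width <= 0 || height <= 0) {
    stop_rfemap("scene extent must have positive area", "invalid_config")
  }
  if (cell_size <= 0) stop_rfemap("cell_size must be > 0", "invalid_config")

  fp <- utils::modifyList(list(
    median_level = 0.6,
    log_var = 0.35,
    range_m = 300,
    hotspots = list(
      list(x = extent[1] + 0.25 * width, y = extent[2] + 0.75 * height,
           amp = 0.7, radius = 250),
      list(x = extent[1] + 0.70 * width, y = extent[2] + 0.30 * height,
           amp = 0.7, radius = 250)
    ),
    band_shares = c(`800` = 0.35, `900` = 0.25, `1800` = 0.20,
                    `2100` = 0.12, `2600` = 0.08)
  ), field_params)
  if (fp$range_m <= 0) stop_rfemap("correlation range must be > 0", "invalid_config")
  if (fp$log_var < 0) stop_rfemap("log-variance must be >= 0", "invalid_config")

  dp <- utils::modifyList(list(
    bands = c("900", "1800", "2100"),
    amplitude = c(`900` = 0.40, `1800` = 0.45, `2100` = 0.50),
    phase_h = c(`900` = 15, `1800` = 16, `2100` = 16),
    noise_sdlog = 0.10
  ), diurnal_params)

  area_km2 <- width * height / 1e6
  pop <- utils::modifyList(list(
    total = round(24000 * area_km2),
    child_fraction = 0.14,
    occupational_total = round(0.45 * 24000 * area_km2)
  ), population)

  structure(list(
    extent = extent, cell_size = cell_size,
    n_zones = n_zones, n_buildings = n_buildings,
    field_params = fp, diurnal_params = dp, population = pop,
    drive_bands = c("800", "900", "1800", "2100", "2600"),
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' Build the analysis grid for a scene
#'
#' Tiles the extent with square cells of `cell_size` metres (the last row or
#' column overhangs if the extent is not an exact multiple).
#'
#' @param config a [scene_config()].
#' @return data frame with one row per cell: `cell_id`, `ix`, `iy`, bounds
#'   and centre coordinates.
#' @export
make_grid <- function(config) {
  e <- config$extent
  cs <- config$cell_size
  nx <- max(1L, as.integer(ceiling((e[3] - e[1]) / cs - 1e-9)))
  ny <- max(1L, as.integer(ceiling((e[4] - e[2]) / cs - 1e-9)))
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  xmin <- e[1] + (ix - 1) * cs
  ymin <- e[2] + (iy - 1) * cs
  data.frame(
    cell_id = sprintf("c%03d_%03d", ix, iy),
    ix = ix, iy = iy,
    xmin = xmin, ymin = ymin, xmax = xmin + cs, ymax = ymin + cs,
    x_center = xmin + cs / 2, y_center = ymin + cs / 2,
    stringsAsFactors = FALSE
  )
}

# Split the extent into n rectangular zones by recursive binary partition:
# always split the largest remaining rectangle across its longer side at a
# random fraction. Guarantees an exact tiling (zone areas sum to the extent).
partition_zones <- function(extent, n_zones) {
  rects <- list(rect(extent[1], extent[2], extent[3], extent[4]))
  while (length(rects) < n_zones) {
    areas <- vapply(rects, rect_area, numeric(1))
    k <- which.max(areas)
    r <- rects[[k]]
    f <- stats::runif(1, 0.35, 0.65)
    w <- r[["xmax"]] - r[["xmin"]]
    h <- r[["ymax"]] - r[["ymin"]]
    if (w >= h) {
      cut <- r[["xmin"]] + f * w
      a <- rect(r[["xmin"]], r[["ymin"]], cut, r[["ymax"]])
      b <- rect(cut, r[["ymin"]], r[["xmax"]], r[["ymax"]])
    } else {
      cut <- r[["ymin"]] + f * h
      a <- rect(r[["xmin"]], r[["ymin"]], r[["xmax"]], cut)
      b <- rect(r[["xmin"]], cut, r[["xmax"]], r[["ymax"]])
    }
    rects[[k]] <- a
    rects[[length(rects) + 1L]] <- b
  }
  rects
}

# Integer allocation by largest remainder so counts sum exactly to total.
largest_remainder <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- total * weights / sum(weights)
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the synthetic district: grid, census zones and buildings
#'
#' Emulates the geoprocessing inputs of a census-backed district: the analysis
#' grid, statistical zones carrying age-classed residential populations and
#' total housing areas, and buildings with footprints, floor counts and a
#' declared use (dwelling / office / mixed / unknown). Zone housing area is
#' the sum of the residential floor areas of intersecting buildings, so the
#' zones are fully covered and surface-ratio allocation conserves population
#' exactly. The district-level occupational population is carried as an
#' attribute (occupational counts are only published as aggregates).
#'
#' @param config a [scene_config()].
#' @return list with `grid`, `zones`, `buildings` data frames and
#'   `occupational_total`.
#' @export
gen_district <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(stage_seed(config$seed, "scene"))
  e <- config$extent
  grid <- make_grid(config)

  zr <- partition_zones(e, config$n_zones)
  zones <- do.call(rbind, lapply(seq_along(zr), function(i) {
    r <- zr[[i]]
    data.frame(zone_id = sprintf("z%02d", i),
               xmin = r[["xmin"]], ymin = r[["ymin"]],
               xmax = r[["xmax"]], ymax = r[["ymax"]])
  }))

  nb <- config$n_buildings
  if (nb > 0) {
    w <- stats::runif(nb, 10, 40)
    d <- stats::runif(nb, 10, 40)
    cx <- stats::runif(nb, e[1] + w / 2, e[3] - w / 2)
    cy <- stats::runif(nb, e[2] + d / 2, e[4] - d / 2)
    floors <- sample(1:7, nb, replace = TRUE)
    use <- sample(c("dwelling", "office", "mixed", "unknown"), nb,
                  replace = TRUE, prob = c(0.62, 0.20, 0.15, 0.03))
    res_share <- ifelse(use == "mixed", stats::runif(nb, 0.3, 0.8), NA_real_)
    buildings <- data.frame(
      building_id = sprintf("b%04d", seq_len(nb)),
      xmin = cx - w / 2, ymin = cy - d / 2,
      xmax = cx + w / 2, ymax = cy + d / 2,
      floors = floors, use = use, res_share = res_share,
      stringsAsFactors = FALSE
    )
    buildings <- classify_buildings(buildings)
  } else {
    buildings <- data.frame(
      building_id = character(0), xmin = numeric(0), ymin = numeric(0),
      xmax = numeric(0), ymax = numeric(0), floors = integer(0),
      use = character(0), res_share = numeric(0), typology = character(0),
      housing_area = numeric(0), office_area = numeric(0)
    )
  }

  # zone totals: housing area fully covered by member buildings
  S_j <- vapply(seq_len(nrow(zones)), function(j) {
    zj <- rect_from_row(zones, j)
    if (nrow(buildings) == 0) return(0)
    sum(vapply(seq_len(nrow(buildings)), function(i) {
      bi <- rect_from_row(buildings, i)
      frac <- rect_intersection_area(bi, zj) / rect_area(bi)
      frac * buildings$housing_area[i]
    }, numeric(1)))
  }, numeric(1))
  zones$housing_area <- S_j

  pop <- config$population
  n_child <- round(pop$total * pop$child_fraction)
  n_adult <- pop$total - n_child
  zones$pop_child <- largest_remainder(n_child, S_j)
  zones$pop_adult <- largest_remainder(n_adult, S_j)

  list(grid = grid, zones = zones, buildings = buildings,
       occupational_total = pop$occupational_total)
}

# Simulate a zero-mean Gaussian random field with exponential covariance
# C(h) = var * exp(-h / range) at arbitrary coordinates, by Cholesky
# factorization of the dense covariance (exact; intended for up to a few
# thousand points -- desk scale).
sim_gaussian_field <- function(x, y, var, range_m, max_n = 5000L) {
  n <- length(x)
  if (var <= 0) return(rep(0, n))
  if (n > max_n) {
    stop_rfemap(sprintf(
      "dense Cholesky field simulation limited to %d points", max_n),
      "invalid_config")
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  C <- var * exp(-d / range_m)
  diag(C) <- diag(C) + 1e-10 * var
  L <- chol(C)
  as.vector(crossprod(L, stats::rnorm(n)))
}

# log-mean surface: log median level plus smooth hotspot bumps
log_mean_surface <- function(x, y, fp) {
  mu <- rep(log(fp$median_level), length(x))
  for (h in fp$hotspots %||% list()) {
    d2 <- (x - h$x)^2 + (y - h$y)^2
    mu <- mu + h$amp * exp(-d2 / (2 * h$radius^2))
  }
  mu
}

#' Generate synthetic drive-test measurements
#'
#' Scatters measurement locations along random straight pseudo-street
#' segments (reproducing the uneven spatial density of a vehicle survey),
#' simulates a spatially correlated lognormal outdoor field (Gaussian random
#' field with exponential covariance on the natural-log scale plus hotspot
#' bumps in the log-mean), and records one row per location and downlink
#' band. Per-band levels are a fixed power split of the total field so the
#' root-sum-of-squares across bands returns the total. Timestamps advance by
#' 5 s per location, mimicking the survey cadence.
#'
#' @param config a [scene_config()].
#' @param n_points number of measurement locations (>= 1).
#' @param n_streets number of pseudo-street segments.
#' @return data frame: `point_id`, `x`, `y`, `band`, `E_vpm`, `timestamp`.
#' @export
gen_drive_test <- function(config, n_points = 1100, n_streets = 15) {
  stopifnot(inherits(config, "scene_config"), n_points >= 1)
  set.seed(stage_seed(config$seed, "drive"))
  e <- config$extent
  fp <- config$field_params

  # random street segments spanning the extent
  sx0 <- stats::runif(n_streets, e[1], e[3]); sy0 <- stats::runif(n_streets, e[2], e[4])
  sx1 <- stats::runif(n_streets, e[1], e[3]); sy1 <- stats::runif(n_streets, e[2], e[4])
  street <- sample.int(n_streets, n_points, replace = TRUE)
  t_along <- stats::runif(n_points)
  x <- sx0[street] + t_along * (sx1[street] - sx0[street]) + stats::rnorm(n_points, 0, 3)
  y <- sy0[street] + t_along * (sy1[street] - sy0[street]) + stats::rnorm(n_points, 0, 3)
  x <- pmin(pmax(x, e[1]), e[3])
  y <- pmin(pmax(y, e[2]), e[4])

  z <- log_mean_surface(x, y, fp) +
    sim_gaussian_field(x, y, fp$log_var, fp$range_m)
  E_tot <- exp(z)

  shares <- fp$band_shares / sum(fp$band_shares)
  bands <- names(shares)
  ts0 <- as.POSIXct("2026-03-02 09:00:00", tz = "UTC")
  out <- do.call(rbind, lapply(seq_along(bands), function(b) {
    data.frame(
      point_id = seq_len(n_points),
      x = x, y = y,
      band = bands[b],
      E_vpm = E_tot * sqrt(shares[[b]]),
      timestamp = format(ts0 + 5 * (seq_len(n_points) - 1),
                         "%Y-%m-%dT%H:%M:%SZ"),
      stringsAsFactors = FALSE
    )
  }))
  out[order(out$point_id, out$band), , drop = FALSE]
}

#' Diurnal shape curves of a scene configuration
#'
#' Returns the configured 24-value diurnal curve per monitoring band:
#' `shape(h) = 1 + amplitude * cos(2 * pi * (h - phase) / 24)`, which has
#' hour-mean exactly 1 (the mean normalized squared field over a day).
#'
#' @param config a [scene_config()].
#' @return matrix 24 x bands of eta values.
#' @export
diurnal_shape <- function(config) {
  dp <- config$diurnal_params
  h <- 0:23
  m <- vapply(dp$bands, function(b) {
    1 + dp$amplitude[[b]] * cos(2 * pi * (h - dp$phase_h[[b]]) / 24)
  }, numeric(24))
  rownames(m) <- h
  m
}

#' Generate synthetic monitoring-node time series
#'
#' Each node measures the electric field in the three downlink monitoring
#' bands at a fixed sampling period. The signal model is
#' `E = level * sqrt(shape(hour)) * noise`, where `level` differs between
#' nodes (lognormal across the network), `shape` is the configured diurnal
#' curve (so squared-field normalization recovers it), and `noise` is
#' multiplicative lognormal with mean 1.
#'
#' @param config a [scene_config()].
#' @param n_nodes number of nodes (36 and 10 mirror the two reference
#'   networks).
#' @param n_days days of data per node.
#' @param sample_period_min sampling period in minutes (5 or 15 typical).
#' @return data frame: `node_id`, `timestamp`, `band`, `E_vpm`.
#' @export
gen_sensor_series <- function(config, n_nodes = 36, n_days = 7,
                              sample_period_min = 15) {
  stopifnot(inherits(config, "scene_config"), n_nodes >= 1, n_days >= 1)
  set.seed(stage_seed(config$seed, "sensors"))
  dp <- config$diurnal_params
  shape <- diurnal_shape(config)
  levels <- exp(stats::rnorm(n_nodes, log(0.3), 0.4))

  per_day <- as.integer(24 * 60 / sample_period_min)
  t0 <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")
  times <- t0 + (seq_len(per_day * n_days) - 1) * sample_period_min * 60
  hours <- as.integer(format(times, "%H"))

  out <- vector("list", n_nodes * length(dp$bands))
  k <- 0
  for (i in seq_len(n_nodes)) {
    for (b in dp$bands) {
      k <- k + 1
      s <- sqrt(shape[hours + 1, b])
      noise <- if (dp$noise_sdlog > 0) {
        exp(stats::rnorm(length(times), -dp$noise_sdlog^2 / 2, dp$noise_sdlog))
      } else rep(1, length(times))
      out[[k]] <- data.frame(
        node_id = sprintf("n%02d", i),
        timestamp = format(times, "%Y-%m-%dT%H:%M:%SZ"),
        band = b,
        E_vpm = levels[i] * s * noise,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Default indoor room specification
#'
#' A 3 x 4 m room with a wall-mounted source (WLAN access point or femtocell)
#' and a child moving on the floor. The source is mounted near the ceiling
#' (2.0-2.5 m, the usual installation height for access points), the child's
#' torso centre sits at about 1 m. The analytic SAR ground truth is
#' `SAR = P0 * G(rotation) / max(d^2, d_min^2)`: inverse-square in the 3D
#' source-to-torso distance with a near-field clamp at `d_min = 0.3` m, and
#' a smooth posture modulation `G = 1 + gain_amp * cos(rotation)` (rotation
#' measured from facing the source wall; exposure is highest face-on).
#'
#' @param width,depth room dimensions in metres.
#' @param p0 source power scale (mW/kg at 1 m on-axis).
#' @param gain_amp angular modulation amplitude in `[0, 1)`.
#' @param d_min near-field distance clamp (m).
#' @param child_height torso height of the child (m).
#' @param src_height_range mounting-height range of the source (m).
#' @return list room specification with input-domain `bounds`.
#' @export
room_spec <- function(width = 3, depth = 4, p0 = 1, gain_amp = 0.3,
                      d_min = 0.3, child_height = 1.0,
                      src_height_range = c(2.0, 2.5)) {
  stopifnot(width > 0, depth > 0, d_min > 0)
  list(
    width = width, depth = depth, p0 = p0, gain_amp = gain_amp,
    d_min = d_min, child_height = child_height,
    bounds = rbind(
      src_wall_pos = c(0, width),
      src_height   = src_height_range,
      child_x      = c(0.1, width - 0.1),
      child_y      = c(0.1, depth - 0.1),
      child_rot    = c(0, 2 * pi)
    )
  )
}

#' Analytic indoor SAR ground truth
#'
#' Evaluates the synthetic whole-body SAR oracle of [room_spec()] at input
#' points. Inputs per row: source horizontal wall position, source height,
#' child x, child y, child rotation (radians). The source sits on the wall
#' `y = 0`.
#'
#' @param X matrix or data frame with 5 columns in the order above.
#' @param room a [room_spec()].
#' @return numeric SAR values (mW/kg).
#' @export
sar_oracle <- function(X, room = room_spec()) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == 5)
  sx <- X[, 1]; sz <- X[, 2]; cx <- X[, 3]; cy <- X[, 4]; rot <- X[, 5]
  d2 <- (sx - cx)^2 + cy^2 + (sz - room$child_height)^2
  G <- 1 + room$gain_amp * cos(rot)
  unname(room$p0 * G / pmax(d2, room$d_min^2))
}

#' Generate an indoor surrogate training set
#'
#' Draws `n_designs` space-filling points (Latin hypercube) in the
#' 5-dimensional input space of [room_spec()] and evaluates the analytic SAR
#' ground truth, producing the experimental set (X0, Y0) used to train the
#' low-rank surrogate.
#'
#' @param room a [room_spec()].
#' @param n_designs number of design points.
#' @param seed integer seed.
#' @param n_coefficients optional known coefficient count of the surrogate to
#'   be trained; if supplied and larger than `n_designs`, an
#'   underdetermined-design error is raised.
#' @return list with `X0` (n x 5 matrix), `Y0` (numeric), `bounds`, `room`.
#' @export
gen_indoor_training <- function(room = room_spec(), n_designs = 500,
                                seed = 1L, n_coefficients = NULL) {
  stopifnot(n_designs >= 1)
  if (!is.null(n_coefficients) && n_designs < n_coefficients) {
    stop_rfemap("n_designs below surrogate coefficient count",
                "underdetermined_design")
  }
  set.seed(stage_seed(seed, "indoor_design"))
  b <- room$bounds
  M <- nrow(b)
  U <- if (requireNamespace("lhs", quietly = TRUE)) {
    lhs::randomLHS(n_designs, M)
  } else {
    # stratified fallback: one uniform draw per equal-probability stratum
    # and dimension, independently permuted (a plain Latin hypercube)
    sapply(seq_len(M), function(i) {
      (sample.int(n_designs) - stats::runif(n_designs)) / n_designs
    })
  }
  X0 <- sapply(seq_len(M), function(i) b[i, 1] + U[, i] * (b[i, 2] - b[i, 1]))
  X0 <- matrix(X0, ncol = M, dimnames = list(NULL, rownames(b)))
  list(X0 = X0, Y0 = sar_oracle(X0, room), bounds = b, room = room)
}

#' Write a generated scene to disk
#'
#' Writes `measurements.csv`, `sensors.csv`, `zones.geojson`,
#' `buildings.geojson`, `grid.geojson` and a JSON `manifest.json` carrying
#' the generating configuration.
#'
#' @param scene list with `district`, `measurements`, `sensors` entries (see
#'   [simulate_scene()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scene$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$sensors, file.path(dir, "sensors.csv"),
                   row.names = FALSE)
  write_geojson_rects(scene$district$zones, file.path(dir, "zones.geojson"))
  write_geojson_rects(scene$district$buildings,
                      file.path(dir, "buildings.geojson"))
  write_geojson_rects(scene$district$grid, file.path(dir, "grid.geojson"))
  cfg <- scene$config
  cfg$class <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper running [gen_district()], [gen_drive_test()] and
#' [gen_sensor_series()] under one configuration.
#'
#' @param config a [scene_config()].
#' @param n_points drive-test locations.
#' @param n_nodes,n_days,sample_period_min monitoring-network shape.
#' @return list with `config`, `district`, `measurements`, `sensors`.
#' @export
simulate_scene <- function(config = scene_config(), n_points = 1100,
                           n_nodes = 36, n_days = 7,
                           sample_period_min = 15) {
  list(
    config = config,
    district = gen_district(config),
    measurements = gen_drive_test(config, n_points = n_points),
    sensors = gen_sensor_series(config, n_nodes = n_nodes, n_days = n_days,
                                sample_period_min = sample_period_min)
  )
}
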