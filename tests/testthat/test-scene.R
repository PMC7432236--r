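test_that("grid tiles the extent with the configured cell size", {
  cfg <- scene_config(extent = c(0, 0, 1000, 1000), cell_size = 100)
  grid <- make_grid(cfg)
  expect_equal(nrow(grid), 100)
  expect_equal(sort(unique(grid$ix)), 1:10)
  # survey-density convention: 1100 points over a 33 x 14 district grid
  cfg2 <- scene_config(extent = c(0, 0, 3300, 1400))
  expect_equal(nrow(make_grid(cfg2)), 462)
  expect_lt(abs(1100 / 462 - 2.4), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(extent = c(0, 0, 0, 1000)), class = "invalid_config")
  expect_error(scene_config(cell_size = 0), class = "invalid_config")
  expect_error(scene_config(field_params = list(range_m = -1)),
               class = "invalid_config")
})

test_that("a fixed seed reproduces the whole scene byte for byte", {
  s1 <- suppressWarnings(simulate_scene(small_config(seed = 7), n_points = 60,
                                        n_nodes = 2, n_days = 1))
  s2 <- suppressWarnings(simulate_scene(small_config(seed = 7), n_points = 60,
                                        n_nodes = 2, n_days = 1))
  expect_identical(s1$district, s2$district)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$sensors, s2$sensors)
})

test_that("district geometry satisfies the census-structure contracts", {
  cfg <- small_config(seed = 3)
  d <- suppressWarnings(gen_district(cfg))
  # zones tile the extent exactly
  zone_area <- sum((d$zones$xmax - d$zones$xmin) * (d$zones$ymax - d$zones$ymin))
  expect_equal(zone_area, 1000 * 1000)
  # every building lies inside the extent (hence in >= 1 zone)
  expect_true(all(d$buildings$xmin >= 0 & d$buildings$xmax <= 1000))
  expect_true(all(d$buildings$floors > 0))
  # population conservation against the configured totals
  pop <- cfg$population
  expect_identical(sum(d$zones$pop_child) + sum(d$zones$pop_adult),
                   as.integer(pop$total))
  # degenerate case: a district with no buildings is still a valid scene
  d0 <- gen_district(small_config(n_buildings = 0))
  expect_equal(nrow(d0$buildings), 0)
  expect_true(all(d0$zones$housing_area == 0))
})

test_that("drive test degenerates to the median level at zero log-variance", {
  cfg <- small_config(field_params = list(log_var = 0, hotspots = NULL))
  m <- gen_drive_test(cfg, n_points = 50)
  tot <- combine_bands(m)
  expect_equal(tot$E_vpm, rep(0.6, 50), tolerance = 1e-12)
})

test_that("vanishing correlation range produces spatially unstructured data", {
  cfg <- scene_config(field_params = list(range_m = 1e-6, hotspots = NULL),
                      seed = 5)
  m <- combine_bands(gen_drive_test(cfg, n_points = 2000))
  ev <- empirical_variogram(data.frame(x = m$x, y = m$y, E_vpm = m$E_vpm))
  # sill reached immediately: all bins fluctuate around the data variance
  s2 <- var(log(m$E_vpm))
  expect_true(all(abs(ev$gamma - s2) / s2 < 0.25))
})

test_that("sensor series follow the configured diurnal signal model", {
  cfg <- small_config(diurnal_params = list(
    amplitude = c(`900` = 0, `1800` = 0, `2100` = 0), noise_sdlog = 0))
  s <- gen_sensor_series(cfg, n_nodes = 3, n_days = 2)
  for (id in unique(s$node_id)) {
    v <- s$E_vpm[s$node_id == id & s$band == "900"]
    expect_equal(diff(range(v)), 0)
  }
  # node levels differ between nodes
  lv <- tapply(s$E_vpm[s$band == "900"], s$node_id[s$band == "900"], mean)
  expect_gt(diff(range(lv)), 0)
  # the two reference network sizes are expressible
  s36 <- gen_sensor_series(small_config(), n_nodes = 36, n_days = 1)
  expect_equal(length(unique(s36$node_id)), 36)
})

test_that("indoor SAR oracle matches direct formula evaluation", {
  room <- room_spec()
  X <- rbind(
    c(1.5, 2.2, 1.5, 2.0, 0),
    c(0.0, 2.0, 2.9, 3.9, pi),
    c(3.0, 2.5, 0.1, 0.1, pi / 2),
    c(1.0, 2.1, 1.0, 1.0, 1.0),
    c(2.0, 2.4, 2.0, 3.0, 5.0)
  )
  d2 <- (X[, 1] - X[, 3])^2 + X[, 4]^2 + (X[, 2] - 1.0)^2
  manual <- 1 * (1 + 0.3 * cos(X[, 5])) / pmax(d2, 0.3^2)
  expect_equal(sar_oracle(X, room), manual, tolerance = 1e-12)
  # co-located at the clamp distance gives the design maximum
  near <- c(1.5, 1.0 + 1e-9, 1.5, 1e-9, 0)
  expect_equal(sar_oracle(rbind(near), room_spec(src_height_range = c(0.5, 2.5))),
               (1 + 0.3) / 0.09, tolerance = 1e-6)
  # linearity in source power
  room2 <- room_spec(p0 = 2)
  expect_equal(sar_oracle(X, room2), 2 * sar_oracle(X, room), tolerance = 1e-12)
})

test_that("indoor training sets are space filling and in bounds", {
  tr <- gen_indoor_training(n_designs = 200, seed = 3)
  expect_equal(dim(tr$X0), c(200, 5))
  for (i in 1:5) {
    expect_true(all(tr$X0[, i] >= tr$bounds[i, 1] &
                      tr$X0[, i] <= tr$bounds[i, 2]))
    # Latin-hypercube stratification: every fifth of the range is hit
    f <- cut(tr$X0[, i], seq(tr$bounds[i, 1], tr$bounds[i, 2], length.out = 6))
    expect_true(all(table(f) > 0))
  }
  expect_error(gen_indoor_training(n_designs = 10, n_coefficients = 130),
               class = "underdetermined_design")
})

test_that("scene files are written as plain-text artifacts", {
  dir <- withr::local_tempdir()
  scn <- suppressWarnings(simulate_scene(small_config(), n_points = 40,
                                         n_nodes = 2, n_days = 1))
  write_scene(scn, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "measurements.csv", "sensors.csv", "zones.geojson",
    "buildings.geojson", "grid.geojson", "manifest.json")))))
  gj <- jsonlite::read_json(file.path(dir, "zones.geojson"))
  expect_identical(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 6)
})
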