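# Shared fixtures: small scenes and hand-built spatial data sets.

small_config <- function(seed = 1, n_buildings = 40, ...) {
  scene_config(extent = c(0, 0, 1000, 1000), n_zones = 6,
               n_buildings = n_buildings, seed = seed, ...)
}

# iid lognormal points with no spatial correlation
iid_points <- function(n, seed = 1, meanlog = 0, sdlog = 0.5, extent = 1000) {
  set.seed(seed)
  data.frame(
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    E_vpm = exp(rnorm(n, meanlog, sdlog))
  )
}

# spatially correlated lognormal points drawn straight from the generator
grf_points <- function(n, seed = 1, range_m = 300, log_var = 0.35,
                       extent = 2000) {
  cfg <- scene_config(extent = c(0, 0, extent, extent), seed = seed,
                      field_params = list(range_m = range_m,
                                          log_var = log_var,
                                          hotspots = NULL))
  combine_bands(gen_drive_test(cfg, n_points = n))
}

# one-building data frame for indoor profile tests
one_building <- function() data.frame(building_id = "b1")

rel_rms <- function(pred, truth) {
  sqrt(mean((pred - truth)^2)) / sqrt(mean(truth^2))
}

# smooth synthetic indoor path-loss family for the PCA+kriging surrogate:
# field at pixel r for a source at s, on a fixed room pixel grid
pathloss_map <- function(source, nx = 15, ny = 20, width = 3, depth = 4) {
  px <- (seq_len(nx) - 0.5) * width / nx
  py <- (seq_len(ny) - 0.5) * depth / ny
  g <- expand.grid(x = px, y = py)
  1 / (1 + sqrt((g$x - source[1])^2 + (g$y - source[2])^2))
}
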