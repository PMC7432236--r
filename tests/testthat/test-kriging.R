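test_that("back-transform follows the lognormal moment formulas", {
  expect_equal(backtransform(0, 0), list(z_lin = 1, s2_lin = 0))
  expect_equal(backtransform(log(2), 0), list(z_lin = 2, s2_lin = 0))
  expect_error(backtransform(0, -1), class = "invalid_variance")
  # Monte-Carlo moment oracle at arbitrary parameters
  set.seed(101)
  mu <- 0.3; s2 <- 0.2
  draws <- rlnorm(1e6, mu, sqrt(s2))
  bt <- backtransform(mu, s2)
  expect_equal(bt$z_lin, mean(draws), tolerance = 5e-3)
  expect_equal(bt$s2_lin, var(draws), tolerance = 2e-2)
})

test_that("variogram fitting rejects degenerate inputs", {
  pts <- iid_points(50)
  pts$E_vpm <- 1
  expect_error(fit_variogram(pts), class = "degenerate_field")
  expect_error(fit_variogram(iid_points(10)), class = "insufficient_data")
  expect_error(fit_variogram(data.frame(x = 1:40, y = 1:40, E_vpm = c(-1, rep(1, 39)))),
               class = "invalid_config")
})

test_that("iid data yield a structureless variogram (sill is all nugget)", {
  pts <- iid_points(2000, seed = 4)
  vg <- fit_variogram(pts)
  # no spatial structure: the short-range rise is tiny relative to the level
  g_short <- vg_short <- vg$nugget + vg$partial_sill * (1 - exp(-50 / vg$range_m))
  g_sill <- vg$nugget + vg$partial_sill
  expect_gt(g_short / g_sill, 0.7)
})

test_that("exponential range is recovered from simulated fields", {
  # two replicate scenes here; the 20-scene recovery study runs in the
  # acceptance suite
  r <- vapply(1:2, function(s) fit_variogram(grf_points(1000, seed = s))$range_m,
              numeric(1))
  expect_true(all(r > 100 & r < 700))
})

test_that("ordinary kriging is an exact interpolator with unit-sum weights", {
  pts <- iid_points(40, seed = 2)
  vg <- structure(list(model_family = "exponential", nugget = 0,
                       partial_sill = 0.3, range_m = 300),
                  class = "variogram_model")
  tgt <- c(pts$x[7], pts$y[7])
  est <- krige_point(pts, tgt, vg, neighborhood_radius = 1e4)
  expect_equal(est$z_log, log(pts$E_vpm[7]), tolerance = 1e-9)
  expect_equal(est$s2_log, 0, tolerance = 1e-9)
  # weights sum to one at arbitrary prediction locations
  for (tgt in list(c(100, 100), c(512, 77), c(900, 950))) {
    est <- krige_point(pts, tgt, vg, neighborhood_radius = 1e4)
    expect_equal(sum(est$weights), 1, tolerance = 1e-9)
  }
})

test_that("single-neighbor kriging reduces to the closed form", {
  pts <- data.frame(x = 0, y = 0, E_vpm = exp(1.3))
  vg <- structure(list(model_family = "exponential", nugget = 0.05,
                       partial_sill = 0.3, range_m = 300),
                  class = "variogram_model")
  est <- krige_point(pts, c(100, 0), vg, neighborhood_radius = 500)
  g <- 0.05 + 0.3 * (1 - exp(-100 / 300))
  expect_equal(est$weights, 1)
  expect_equal(est$z_log, 1.3)
  expect_equal(est$s2_log, 2 * g)  # 2*gamma(d) - gamma(0), gamma(0) = 0
})

test_that("kriging weights match an independent dense solve", {
  pts <- data.frame(x = c(0, 200, 100), y = c(0, 0, 180),
                    E_vpm = exp(c(0.2, -0.1, 0.5)))
  vg <- structure(list(model_family = "exponential", nugget = 0.02,
                       partial_sill = 0.25, range_m = 250),
                  class = "variogram_model")
  tgt <- c(80, 60)
  gam <- function(h) ifelse(h == 0, 0, 0.02 + 0.25 * (1 - exp(-h / 250)))
  D <- as.matrix(dist(pts[, c("x", "y")]))
  A <- rbind(cbind(gam(D), 1), c(1, 1, 1, 0))
  b <- c(gam(sqrt((pts$x - tgt[1])^2 + (pts$y - tgt[2])^2)), 1)
  sol <- solve(A, b)
  est <- krige_point(pts, tgt, vg, neighborhood_radius = 1e4)
  expect_equal(est$weights, unname(sol[1:3]), tolerance = 1e-10)
  expect_equal(est$z_log, unname(sum(sol[1:3] * log(pts$E_vpm))),
               tolerance = 1e-10)
  expect_equal(est$s2_log, unname(sum(sol[1:3] * b[1:3]) + sol[4]),
               tolerance = 1e-10)
})

test_that("no neighbor raises, and local equals global for a huge radius", {
  pts <- iid_points(60, seed = 9)
  vg <- fit_variogram(iid_points(60, seed = 9), min_points = 30)
  expect_error(krige_point(pts, c(1e6, 1e6), vg, neighborhood_radius = 100),
               class = "no_neighbor")
  a <- krige_point(pts, c(430, 210), vg, neighborhood_radius = 5000)
  b <- krige_point(pts, c(430, 210), vg, neighborhood_radius = 1e9)
  expect_identical(a$z_log, b$z_log)
  expect_identical(a$s2_log, b$s2_log)
})

test_that("grid kriging reproduces constants, samples, and flags gaps", {
  cfg <- scene_config(extent = c(0, 0, 500, 500))
  grid <- make_grid(cfg)
  # near-constant field: predictions stay within the jitter
  set.seed(8)
  pts <- data.frame(x = runif(80, 0, 500), y = runif(80, 0, 500),
                    E_vpm = 2 * exp(rnorm(80, 0, 1e-6)))
  vg <- structure(list(model_family = "exponential", nugget = 0,
                       partial_sill = 1e-12, range_m = 200),
                  class = "variogram_model")
  est <- krige_grid(pts, grid, vg, neighborhood_radius = 1e4)
  expect_true(all(abs(est$z_lin - 2) < 1e-4))
  # a cell centre that coincides with a measurement reproduces it
  pts2 <- rbind(pts, data.frame(x = 250, y = 250, E_vpm = 5))
  est2 <- krige_grid(pts2, grid, vg, neighborhood_radius = 1e4)
  hit <- est2[est2$x_center == 250 & est2$y_center == 250, ]
  expect_equal(hit$z_log, log(5), tolerance = 1e-6)
  # cells beyond the neighborhood fall back to the global mean, flagged
  pts3 <- data.frame(x = c(10, 20, 30), y = c(10, 20, 15), E_vpm = c(1, 2, 3))
  est3 <- krige_grid(pts3, grid, vg, neighborhood_radius = 50)
  far <- est3[est3$x_center > 400, ]
  expect_true(all(far$flagged))
  expect_equal(unique(far$z_log), mean(log(c(1, 2, 3))))
})

test_that("LOO-CV honors exclusion radii and degrades with them", {
  pts <- grf_points(120, seed = 3, extent = 1000)
  vg <- fit_variogram(pts)
  cv0 <- loo_cv(pts, vg, exclusion_radius = 0)
  expect_equal(nrow(cv0$table), 120)
  expect_equal(cv0$n_unpredictable, 0)
  # a near-constant field cross-validates with almost no error
  flat <- data.frame(x = runif(40, 0, 500), y = runif(40, 0, 500),
                     E_vpm = exp(rnorm(40, 0, 1e-8)))
  vgf <- structure(list(model_family = "exponential", nugget = 0,
                        partial_sill = 1e-15, range_m = 200),
                   class = "variogram_model")
  expect_lt(loo_cv(flat, vgf, neighborhood_radius = 1e4)$rmse, 1e-6)
  # mean RMSE over replicate scenes is non-decreasing in the exclusion radius
  rmse <- sapply(1:8, function(s) {
    p <- grf_points(100, seed = 100 + s, extent = 1000)
    v <- fit_variogram(p)
    c(loo_cv(p, v, 0)$rmse, loo_cv(p, v, 150)$rmse, loo_cv(p, v, 300)$rmse)
  })
  m <- rowMeans(rmse)
  expect_true(m[1] <= m[2] && m[2] <= m[3])
})

test_that("grid kriging beats the no-interpolation baseline on a known field", {
  # simulate the log-field jointly at samples and cell centres, then compare
  cfg <- scene_config(extent = c(0, 0, 1000, 1000), seed = 12,
                      field_params = list(hotspots = NULL))
  grid <- make_grid(cfg)
  set.seed(31)
  n <- 300
  sx <- runif(n, 0, 1000); sy <- runif(n, 0, 1000)
  x <- c(sx, grid$x_center); y <- c(sy, grid$y_center)
  z <- log(0.6) + rfemap:::sim_gaussian_field(x, y, 0.35, 300)
  pts <- data.frame(x = sx, y = sy, E_vpm = exp(z[1:n]))
  vg <- fit_variogram(pts)
  est <- krige_grid(pts, grid, vg)
  truth <- z[(n + 1):length(z)]
  rmse <- sqrt(mean((est$z_log - truth)^2))
  expect_lt(rmse, 0.5 * sqrt(0.35))
})
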