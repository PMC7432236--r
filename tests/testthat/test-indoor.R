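test_that("separable rank-1 targets are recovered to machine precision", {
  set.seed(1)
  N <- 400
  X <- matrix(runif(N * 3, -1, 1), N, 3)
  f <- function(X) (1 + X[, 1] + X[, 1]^2) * (2 - X[, 2]) * (0.5 + X[, 3]^3)
  m <- lra_fit(X, f(X), rank = 1, degree = 4,
               bounds = cbind(rep(-1, 3), rep(1, 3)))
  Xh <- matrix(runif(200 * 3, -1, 1), 200, 3)
  expect_lt(rel_rms(lra_predict(m, Xh), f(Xh)), 1e-8)
  expect_lt(m$training_rmse / sqrt(mean(f(X)^2)), 1e-8)
})

test_that("a sum of two separable terms is recovered at rank 2", {
  set.seed(2)
  N <- 400
  X <- matrix(runif(N * 3, -1, 1), N, 3)
  g <- function(X) {
    (1 + X[, 1] + X[, 1]^2) * (2 - X[, 2]) * (0.5 + X[, 3]^3) +
      (X[, 1]^2 - 1) * X[, 2]^3 * (1 + X[, 3])
  }
  m <- lra_fit(X, g(X), rank = 2, degree = 4,
               bounds = cbind(rep(-1, 3), rep(1, 3)),
               tol = 1e-14, max_sweeps = 1000)
  Xh <- matrix(runif(200 * 3, -1, 1), 200, 3)
  expect_lt(rel_rms(lra_predict(m, Xh), g(Xh)), 1e-6)
})

test_that("the rank-5 surrogate approximates the SAR ground truth", {
  tr <- gen_indoor_training(n_designs = 500, seed = 7)
  te <- gen_indoor_training(n_designs = 200, seed = 99)
  errs <- vapply(1:5, function(r) {
    m <- lra_fit(tr$X0, tr$Y0, rank = r, degree = 4, bounds = tr$bounds)
    rel_rms(lra_predict(m, te$X0), te$Y0)
  }, numeric(1))
  expect_lt(errs[5], 0.10)
  # held-out error is non-increasing in rank up to least-squares noise
  expect_true(all(errs[-1] <= 1.5 * errs[-5]))
})

test_that("surrogate evaluation is linear in the normalizing constants", {
  tr <- gen_indoor_training(n_designs = 200, seed = 5)
  m <- lra_fit(tr$X0, tr$Y0, rank = 2, degree = 3, bounds = tr$bounds)
  X <- tr$X0[1:10, ]
  p <- lra_predict(m, X)
  m0 <- m; m0$b <- rep(0, m$rank)
  expect_equal(as.numeric(lra_predict(m0, X)), rep(0, 10))
  m3 <- m; m3$b <- 3 * m$b
  expect_equal(as.numeric(lra_predict(m3, X)), as.numeric(3 * p),
               tolerance = 1e-12)
  expect_error(lra_predict(m, matrix(1, 2, 3)), class = "invalid_input")
  # single-rank hand evaluation: sum over the product of basis expansions
  m1 <- m; m1$rank <- 1; m1$Z <- m$Z[1]; m1$b <- m$b[1]
  x <- tr$X0[3, , drop = FALSE]
  u <- 2 * (x - tr$bounds[, 1]) / (tr$bounds[, 2] - tr$bounds[, 1]) - 1
  manual <- m$b[1]
  for (i in 1:5) {
    leg <- cbind(1, u[i], (3 * u[i]^2 - 1) / 2, (5 * u[i]^3 - 3 * u[i]) / 2)
    leg <- leg * sqrt(2 * (0:3) + 1)
    manual <- manual * sum(leg * m$Z[[1]][, i])
  }
  expect_equal(as.numeric(lra_predict(m1, x)), as.numeric(manual),
               tolerance = 1e-10)
})

test_that("undersized experimental sets are rejected", {
  tr <- gen_indoor_training(n_designs = 60, seed = 1)
  expect_error(lra_fit(tr$X0, tr$Y0, rank = 5, degree = 4, bounds = tr$bounds),
               class = "underdetermined_design")
  expect_error(lra_fit(tr$X0, tr$Y0, rank = 0), class = "invalid_config")
})

test_that("surrogate serialization round-trips through JSON", {
  tr <- gen_indoor_training(n_designs = 200, seed = 5)
  m <- lra_fit(tr$X0, tr$Y0, rank = 2, degree = 3, bounds = tr$bounds)
  path <- withr::local_tempfile(fileext = ".json")
  lra_write(m, path)
  m2 <- lra_read(path)
  X <- tr$X0[1:20, ]
  expect_equal(as.numeric(lra_predict(m2, X)), as.numeric(lra_predict(m, X)),
               tolerance = 1e-12)
})

test_that("PCA + kriging reconstructs and interpolates indoor field maps", {
  pos <- as.matrix(expand.grid(x = seq(0.5, 2.5, length.out = 4),
                               y = seq(0.5, 3.5, length.out = 4)))
  maps <- t(apply(pos, 1, pathloss_map))
  m <- pca_kriging_fit(maps, pos, variance_threshold = 0.999)
  # exact reproduction of a training map (zero-nugget kriging + PCA)
  rec <- pca_kriging_predict(m, pos[6, ])
  expect_lt(rel_rms(as.numeric(rec), maps[6, ]), 1e-6)
  # unseen source position against the oracle map
  new <- c(1.7, 2.1)
  pred <- pca_kriging_predict(m, new)
  expect_lt(rel_rms(as.numeric(pred), pathloss_map(new)), 0.15)
  # continuity: nearby sources differ less than distant sources
  d_near <- sqrt(mean((pca_kriging_predict(m, c(1.0, 1.0)) -
                         pca_kriging_predict(m, c(1.1, 1.0)))^2))
  d_far <- sqrt(mean((pca_kriging_predict(m, c(1.0, 1.0)) -
                        pca_kriging_predict(m, c(2.4, 3.4)))^2))
  expect_lt(d_near, d_far)
})

test_that("degenerate map families are handled", {
  pos <- cbind(runif(5, 0, 3), runif(5, 0, 4))
  same <- matrix(rep(pathloss_map(c(1, 2)), each = 5), nrow = 5)
  m <- pca_kriging_fit(same, pos)
  expect_equal(m$d, 1L)
  expect_equal(as.numeric(pca_kriging_predict(m, c(0.4, 0.4))), same[1, ],
               tolerance = 1e-9)
  zero <- matrix(0, 5, 300)
  mz <- pca_kriging_fit(zero, pos)
  expect_true(all(pca_kriging_predict(mz, c(1, 1)) == 0))
  expect_error(pca_kriging_fit(same[1:2, ], pos[1:2, ]),
               class = "insufficient_training")
  # full-rank retention reconstructs every training map
  maps <- t(apply(pos, 1, pathloss_map))
  mf <- pca_kriging_fit(maps, pos, variance_threshold = 1)
  for (i in 1:5) {
    expect_lt(rel_rms(as.numeric(pca_kriging_predict(mf, pos[i, ])),
                      maps[i, ]), 1e-6)
  }
})

test_that("penetration loss follows the dB attenuation law", {
  expect_equal(penetrate(1, penetration_params(0)), 1)
  expect_equal(penetrate(1, penetration_params(20)), 0.1)
  expect_equal(penetrate(0.82), 0.82 * 10^(-0.475))
  expect_error(penetrate(-1), class = "invalid_input")
  expect_error(penetration_params(-3), class = "invalid_config")
  # group property: sequential losses compose additively in dB
  v <- c(0, 0.3, 0.82, 2.5)
  expect_identical(
    penetrate(penetrate(v, penetration_params(4.5)), penetration_params(5)),
    penetrate(v, penetration_params(9.5)))
})

test_that("calibrated building profiles reproduce the indoor source table", {
  prof <- indoor_profiles(one_building(), outdoor_field = 0, n = 20000,
                          seed = 4)
  wb <- prof$b1$whole_body$adult
  expect_equal(mean(wb$indoor), 2.4e-1, tolerance = 0.05)
  expect_equal(sd(wb$indoor), 1.7e-1, tolerance = 0.05)
  # zero sources and zero outdoor field give an all-zero ambient part
  expect_true(all(wb$outdoor == 0))
  # additivity: per-sample totals decompose exactly
  expect_identical(wb$total, wb$indoor + wb$outdoor)
  pen <- indoor_profiles(one_building(), outdoor_field = 0.82, n = 500,
                         seed = 4)$b1$whole_brain$child
  expect_identical(pen$total, pen$indoor + pen$outdoor)
  expect_equal(unique(pen$outdoor),
               field_to_sar(penetrate(0.82), tissue = "whole_brain",
                            age = "child"))
})

test_that("surrogate-driven building profiles track the trained model", {
  tr <- gen_indoor_training(n_designs = 200, seed = 5)
  m <- lra_fit(tr$X0, tr$Y0, rank = 2, degree = 3, bounds = tr$bounds)
  prof <- indoor_profiles(one_building(), outdoor_field = 0, n = 2000,
                          seed = 6, mode = "surrogate", surrogate = m,
                          room = tr$room)
  s <- prof$b1$whole_body$child$indoor
  # WLAN part dominated by the surrogate's range of SAR values
  expect_true(mean(s) > 0 && mean(s) < max(tr$Y0) * 1.3)
  expect_error(indoor_profiles(one_building(), 0, mode = "surrogate"),
               class = "configuration_error")
})
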