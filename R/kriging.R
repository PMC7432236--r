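# Ordinary kriging of the outdoor downlink field in natural-log space, with
# local neighborhoods and lognormal back-transform of the predictions.

#' Combine multi-band measurements into one total-field record per location
#'
#' Drive tests record several downlink bands per location. The default
#' analysis interpolates a single exposure surface, so per-location band
#' levels are combined by root-sum-of-squares (fields of incoherent sources
#' add in power).
#'
#' @param measurements data frame with `point_id`, `x`, `y`, `band`, `E_vpm`.
#' @return data frame with one row per location: `point_id`, `x`, `y`,
#'   `E_vpm` (RSS-combined).
#' @export
combine_bands <- function(measurements) {
  stopifnot(all(c("point_id", "x", "y", "E_vpm") %in% names(measurements)))
  sp <- split(measurements, measurements$point_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(point_id = d$point_id[1], x = d$x[1], y = d$y[1],
               E_vpm = sqrt(sum(d$E_vpm^2)))
  }))
  rownames(out) <- NULL
  out[order(out$point_id), , drop = FALSE]
}

# Semivariance of a fitted model. Classic convention: gamma(0) = 0 exactly,
# with the nugget as the right-limit at h -> 0+.
vg_gamma <- function(vg, h) {
  g <- switch(vg$model_family,
    exponential = vg$nugget + vg$partial_sill * (1 - exp(-h / vg$range_m)),
    spherical = vg$nugget + vg$partial_sill *
      ifelse(h >= vg$range_m, 1, 1.5 * h / vg$range_m - 0.5 * (h / vg$range_m)^3),
    gaussian = vg$nugget + vg$partial_sill * (1 - exp(-(h / vg$range_m)^2)),
    stop_rfemap("unknown variogram family", "invalid_config")
  )
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram of log-transformed field values
#'
#' Distances are binned into `n_bins` equal-width classes up to `max_dist`
#' (default: half the largest pairwise distance); within each class the
#' classical Matheron estimator `mean(diff^2) / 2` is computed on the
#' natural-log values.
#'
#' @param points data frame with `x`, `y` and `E_vpm` (or a precomputed `z`
#'   log-value column).
#' @param n_bins number of distance classes.
#' @param max_dist maximum pair distance used.
#' @return data frame `dist` (bin midpoint), `gamma`, `n` (pair count).
#' @export
empirical_variogram <- function(points, n_bins = 15, max_dist = NULL) {
  z <- if ("z" %in% names(points)) points$z else log(points$E_vpm)
  d <- stats::dist(cbind(points$x, points$y))
  dz2 <- stats::dist(z)^2
  dv <- as.vector(d)
  if (is.null(max_dist)) max_dist <- max(dv) / 2
  keep <- dv > 0 & dv <= max_dist
  dv <- dv[keep]
  g <- as.vector(dz2)[keep] / 2
  br <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- cut(dv, br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    dist = tapply(dv, bin, mean),
    gamma = tapply(g, bin, mean),
    n = as.integer(tapply(g, bin, length))
  )
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a variogram model to log-transformed field measurements
#'
#' The downlink field is lognormal, so the variogram is estimated on the
#' natural-log values. The empirical semivariogram is fitted by weighted
#' least squares; the default weights `N_k / h_k^2` (pair count over squared
#' lag) emphasize the structured short lags, where finite-domain
#' fluctuations of the long-lag semivariances would otherwise destabilize
#' the range estimate. Plain pair-count weights are available via
#' `weights = "npairs"`. Duplicate coordinates are averaged in log space
#' beforehand.
#'
#' @param points data frame with `x`, `y`, `E_vpm` (single band or
#'   RSS-combined; see [combine_bands()]).
#' @param model_family one of `"exponential"` (default), `"spherical"`,
#'   `"gaussian"`.
#' @param n_bins,max_dist passed to [empirical_variogram()].
#' @param weights `"nh2"` (default) or `"npairs"`.
#' @param min_points minimum number of locations required.
#' @return object of class `variogram_model`: `model_family`, `nugget`,
#'   `partial_sill`, `range_m`, plus the empirical variogram used.
#' @export
fit_variogram <- function(points, model_family = "exponential",
                          n_bins = 15, max_dist = NULL,
                          weights = c("nh2", "npairs"), min_points = 30) {
  weights <- match.arg(weights)
  pts <- dedup_points(points)
  if (nrow(pts) < min_points) {
    stop_rfemap(sprintf("variogram fit needs >= %d points", min_points),
                "insufficient_data")
  }
  if (stats::var(pts$z) == 0) {
    stop_rfemap("all field values identical; variogram undefined",
                "degenerate_field")
  }
  ev <- empirical_variogram(pts, n_bins = n_bins, max_dist = max_dist)
  s2 <- stats::var(pts$z)
  dmax <- max(ev$dist)

  w <- switch(weights, nh2 = ev$n / ev$dist^2, npairs = ev$n)
  obj <- function(p) {
    vg <- list(model_family = model_family, nugget = p[1],
               partial_sill = p[2], range_m = p[3])
    sum(w * (ev$gamma - vg_gamma(vg, ev$dist))^2)
  }
  # the range is only identifiable within the span of fitted lags
  start <- c(nugget = 0.1 * s2, partial_sill = 0.9 * s2, range_m = dmax / 4)
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0, dmax * 1e-3),
                      upper = c(4 * s2, 8 * s2, dmax))
  structure(list(
    model_family = model_family,
    nugget = unname(fit$par[1]),
    partial_sill = unname(fit$par[2]),
    range_m = unname(fit$par[3]),
    empirical = ev,
    n_points = nrow(pts)
  ), class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "Variogram model (%s): nugget %.4g, partial sill %.4g, range %.1f m\n",
    x$model_family, x$nugget, x$partial_sill, x$range_m))
  invisible(x)
}

# Average duplicate coordinates in log space; returns data frame x, y, z.
dedup_points <- function(points) {
  z <- if ("z" %in% names(points)) points$z else {
    if (any(points$E_vpm <= 0)) {
      stop_rfemap("field values must be > 0 for log transform",
                  "invalid_config")
    }
    log(points$E_vpm)
  }
  key <- paste(signif(points$x, 12), signif(points$y, 12))
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(
      list(z = z), by = list(key = key), FUN = mean)
    first <- !duplicated(key)
    map <- match(agg$key, key[first])
    xf <- points$x[first][map]
    yf <- points$y[first][map]
    data.frame(x = xf, y = yf, z = agg$z)
  } else {
    data.frame(x = points$x, y = points$y, z = z)
  }
}

# Solve the ordinary kriging system for one target given neighbor coords and
# log values. Returns prediction, kriging variance and the weights.
ok_solve <- function(nx, ny, nz, tx, ty, vg) {
  n <- length(nx)
  d0 <- sqrt((nx - tx)^2 + (ny - ty)^2)
  # coincident target: the exact-interpolator convention, which also avoids
  # a singular system when the variogram is degenerate
  hit <- which(d0 < 1e-9)
  if (length(hit) > 0) {
    w <- rep(0, n)
    w[hit] <- 1 / length(hit)
    return(list(z_log = mean(nz[hit]), s2_log = 0, weights = w))
  }
  D <- as.matrix(stats::dist(cbind(nx, ny)))
  G <- vg_gamma(vg, D)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  b <- c(vg_gamma(vg, d0), 1)
  sol <- tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-10, n + 1), b)
  })
  w <- unname(sol[seq_len(n)])
  mu <- unname(sol[n + 1])
  list(
    z_log = sum(w * nz),
    s2_log = max(0, sum(w * b[seq_len(n)]) + mu),
    weights = w
  )
}

#' Ordinary kriging prediction at one location
#'
#' Solves the ordinary kriging system in natural-log space over the
#' measurement points inside a local neighborhood of the target (default
#' radius four times the variogram range, giving a locally varying mean).
#'
#' @param points data frame with `x`, `y` and `E_vpm` or log values `z`.
#' @param target numeric `c(x, y)`.
#' @param vg a [fit_variogram()] model.
#' @param neighborhood_radius metres; default `4 * vg$range_m`.
#' @return list `z_log`, `s2_log`, `weights`, `n_neighbors`.
#' @export
krige_point <- function(points, target, vg, neighborhood_radius = NULL) {
  r <- neighborhood_radius %||% (4 * vg$range_m)
  pts <- dedup_points(points)
  d <- sqrt((pts$x - target[1])^2 + (pts$y - target[2])^2)
  nb <- which(d <= r)
  if (length(nb) == 0) {
    stop_rfemap("no measurement inside the kriging neighborhood",
                "no_neighbor")
  }
  sol <- ok_solve(pts$x[nb], pts$y[nb], pts$z[nb], target[1], target[2], vg)
  sol$n_neighbors <- length(nb)
  sol
}

#' Back-transform a log-scale prediction to linear scale
#'
#' Converts a log-domain Gaussian prediction and its kriging variance to the
#' mean and variance of the corresponding lognormal field:
#' `z_lin = exp(z_log + s2_log / 2)` and
#' `s2_lin = exp(2 * z_log + s2_log) * (exp(s2_log) - 1)`.
#'
#' @param z_log predicted natural-log value(s).
#' @param s2_log kriging variance(s) in log scale, `>= 0`.
#' @return list `z_lin` (V/m), `s2_lin` ((V/m)^2).
#' @export
backtransform <- function(z_log, s2_log) {
  if (any(s2_log < 0)) {
    stop_rfemap("kriging variance must be non-negative", "invalid_variance")
  }
  list(
    z_lin = exp(z_log + s2_log / 2),
    s2_lin = exp(2 * z_log + s2_log) * (exp(s2_log) - 1)
  )
}

#' Krige the full analysis grid
#'
#' Predicts the log field at every cell centre with local-neighborhood
#' ordinary kriging and back-transforms to linear scale. Cells with no
#' measurement inside the neighborhood fall back to the global log mean with
#' the total sill as variance and are flagged.
#'
#' @param points measurement data frame (`x`, `y`, `E_vpm`).
#' @param grid analysis grid from [make_grid()].
#' @param vg a [fit_variogram()] model.
#' @param neighborhood_radius metres; default `4 * vg$range_m`.
#' @return data frame per cell: `cell_id`, centre coordinates, `z_log`,
#'   `s2_log`, `z_lin`, `s2_lin`, `flagged`.
#' @export
krige_grid <- function(points, grid, vg, neighborhood_radius = NULL) {
  r <- neighborhood_radius %||% (4 * vg$range_m)
  pts <- dedup_points(points)
  gmean <- mean(pts$z)
  gvar <- vg$nugget + vg$partial_sill
  n_cells <- nrow(grid)
  z_log <- s2_log <- numeric(n_cells)
  flagged <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    tx <- grid$x_center[i]; ty <- grid$y_center[i]
    d <- sqrt((pts$x - tx)^2 + (pts$y - ty)^2)
    nb <- which(d <= r)
    if (length(nb) == 0) {
      z_log[i] <- gmean
      s2_log[i] <- gvar
      flagged[i] <- TRUE
    } else {
      sol <- ok_solve(pts$x[nb], pts$y[nb], pts$z[nb], tx, ty, vg)
      z_log[i] <- sol$z_log
      s2_log[i] <- sol$s2_log
    }
  }
  bt <- backtransform(z_log, s2_log)
  data.frame(
    cell_id = grid$cell_id,
    x_center = grid$x_center, y_center = grid$y_center,
    z_log = z_log, s2_log = s2_log,
    z_lin = bt$z_lin, s2_lin = bt$s2_lin,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Leave-one-out cross-validation with neighbor exclusion
#'
#' Predicts every measurement from the others, optionally excluding all
#' predictors within `exclusion_radius` of the held-out point to probe the
#' effect of increasingly larger unmeasured areas. `exclusion_radius = 0`
#' is plain leave-one-out.
#'
#' @param points measurement data frame (`x`, `y`, `E_vpm`).
#' @param vg a [fit_variogram()] model.
#' @param exclusion_radius metres.
#' @param neighborhood_radius metres; default `4 * vg$range_m`.
#' @return object of class `cv_report`: per-point table (`observed`,
#'   `predicted`, `s2_log`, `predictable`, log scale), `rmse`, `mean_error`,
#'   `n_unpredictable`, `exclusion_radius`.
#' @export
loo_cv <- function(points, vg, exclusion_radius = 0,
                   neighborhood_radius = NULL) {
  pts <- dedup_points(points)
  if (nrow(pts) < 2) stop_rfemap("LOO-CV needs >= 2 points", "insufficient_data")
  r <- neighborhood_radius %||% (4 * vg$range_m)
  n <- nrow(pts)
  pred <- s2 <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)
    cand <- which(d > exclusion_radius & d > 0 & d <= r)
    if (length(cand) == 0) next
    sol <- ok_solve(pts$x[cand], pts$y[cand], pts$z[cand],
                    pts$x[i], pts$y[i], vg)
    pred[i] <- sol$z_log
    s2[i] <- sol$s2_log
    ok[i] <- TRUE
  }
  err <- pred[ok] - pts$z[ok]
  structure(list(
    table = data.frame(observed = pts$z, predicted = pred, s2_log = s2,
                       predictable = ok),
    rmse = sqrt(mean(err^2)),
    mean_error = mean(err),
    n_unpredictable = sum(!ok),
    exclusion_radius = exclusion_radius
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "LOO-CV (exclusion %g m): log-RMSE %.4f, mean error %.4f, %d/%d unpredictable\n",
    x$exclusion_radius, x$rmse, x$mean_error, x$n_unpredictable,
    nrow(x$table)))
  invisible(x)
}
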