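# Diurnal exposure profiles from monitoring-node series, and time-varying
# per-cell exposure distributions.

#' Normalize one day of field samples
#'
#' Converts a day of electric-field samples from one node and band into
#' normalized squared-field values `eta_i = E_i^2 / Ebar_day^2`. Two readings
#' of the day normalizer are supported: `"literal"` (default) uses the
#' squared arithmetic mean of E; `"rms"` uses the mean of E^2, under which
#' the day-average of eta is exactly 1.
#'
#' eta is invariant to rescaling the whole day by a positive constant in
#' both modes, which removes long-term level changes of the network or
#' environment.
#'
#' @param E numeric field samples of one day (>= 2 values).
#' @param method `"literal"` or `"rms"`.
#' @return numeric eta values.
#' @export
normalize_day <- function(E, method = c("literal", "rms")) {
  method <- match.arg(method)
  if (length(E) < 2) stop_rfemap("need >= 2 samples in a day", "insufficient_data")
  if (all(E == 0)) stop_rfemap("all-zero day", "zero_day")
  denom <- switch(method, literal = mean(E)^2, rms = mean(E^2))
  E^2 / denom
}

#' Build the diurnal exposure profile of one band
#'
#' Normalizes every node-day of the series with [normalize_day()], pools the
#' eta values across nodes and days, and averages within each hour-of-day
#' bin. Hours without samples are filled by linear interpolation from
#' adjacent hours (circular) and flagged.
#'
#' Because each day is normalized by its own level, nodes with different
#' absolute levels contribute identically shaped information, and a single
#' network-wide profile results.
#'
#' @param sensors data frame `node_id`, `timestamp` (ISO 8601), `band`,
#'   `E_vpm`.
#' @param band band label to profile.
#' @param method normalization reading, see [normalize_day()].
#' @return object of class `time_profile`: `band`, `eta_hour` (24 values),
#'   `n_samples_hour`, `interpolated` (logical 24), `method`.
#' @export
build_profile <- function(sensors, band, method = c("literal", "rms")) {
  method <- match.arg(method)
  d <- sensors[sensors$band == band, , drop = FALSE]
  if (nrow(d) == 0) stop_rfemap("no samples for band", "insufficient_data")
  ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  day <- format(ts, "%Y-%m-%d")
  hour <- as.integer(format(ts, "%H"))

  eta <- rep(NA_real_, nrow(d))
  day_groups <- split(seq_len(nrow(d)), paste(d$node_id, day))
  for (idx in day_groups) {
    if (length(idx) < 2) next
    Ed <- d$E_vpm[idx]
    if (all(Ed == 0)) next  # zero-day skipped
    eta[idx] <- normalize_day(Ed, method = method)
  }
  keep <- !is.na(eta)
  eta <- eta[keep]; hour <- hour[keep]

  eta_hour <- rep(NA_real_, 24)
  n_hour <- integer(24)
  for (h in 0:23) {
    idx <- hour == h
    n_hour[h + 1] <- sum(idx)
    if (any(idx)) eta_hour[h + 1] <- mean(eta[idx])
  }
  interpolated <- is.na(eta_hour)
  if (all(interpolated)) stop_rfemap("no usable hours", "insufficient_data")
  if (any(interpolated)) {
    # circular linear interpolation over missing hours
    idx <- which(!interpolated)
    ext_x <- c(idx - 24, idx, idx + 24)
    ext_y <- rep(eta_hour[idx], 3)
    eta_hour[interpolated] <- stats::approx(ext_x, ext_y,
                                            xout = which(interpolated))$y
  }
  structure(list(band = band, eta_hour = eta_hour,
                 n_samples_hour = n_hour, interpolated = interpolated,
                 method = method),
            class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("Diurnal profile, band %s (%s normalization): eta range %.3f-%.3f\n",
              x$band, x$method, min(x$eta_hour), max(x$eta_hour)))
  invisible(x)
}

#' Build a time-varying exposure distribution for one grid cell
#'
#' Starting from the kriged cell estimate, draws `n` base field samples from
#' Normal(`z_lin`, `s2_lin`) truncated at zero (redrawn), assigns each
#' sample a uniform hour of day and a band by `band_weights`, scales the
#' squared sample by the band profile's eta for that hour, and returns the
#' square-rooted field samples.
#'
#' @param estimate one-row kriged estimate (list or data frame row with
#'   `z_lin`, `s2_lin`).
#' @param profiles named list of [build_profile()] objects, one per band.
#' @param band_weights named weights over `names(profiles)`, summing to 1;
#'   default equal.
#' @param n sample count (default 20000).
#' @param seed integer seed.
#' @return object of class `cell_exposure`: `samples` (V/m), `fitted_family`,
#'   `fit_params`, `ks_stats`, `seed`.
#' @param fit if `TRUE` (default), select a gamma or normal fit via
#'   [fit_best()].
#' @export
temporalize_cell <- function(estimate, profiles, band_weights = NULL,
                             n = 20000, seed = 1L, fit = TRUE) {
  if (estimate$s2_lin < 0) stop_rfemap("negative linear variance", "invalid_input")
  bands <- names(profiles)
  if (is.null(band_weights)) {
    band_weights <- stats::setNames(rep(1 / length(bands), length(bands)), bands)
  }
  if (abs(sum(band_weights) - 1) > 1e-8) {
    stop_rfemap("band weights must sum to 1", "invalid_config")
  }
  set.seed(as.integer(seed))
  mu <- estimate$z_lin
  sdv <- sqrt(estimate$s2_lin)

  base <- stats::rnorm(n, mu, sdv)
  bad <- base < 0
  while (any(bad)) {  # truncate at 0 by redraw: fields are nonnegative
    base[bad] <- stats::rnorm(sum(bad), mu, sdv)
    bad <- base < 0
  }
  hour <- sample.int(24, n, replace = TRUE) - 1L
  band <- sample(bands, n, replace = TRUE, prob = band_weights[bands])
  eta_mat <- vapply(profiles, function(p) p$eta_hour, numeric(24))
  eta <- eta_mat[cbind(hour + 1L, match(band, bands))]
  samples <- sqrt(base^2 * eta)

  out <- list(samples = samples, seed = as.integer(seed),
              band_weights = band_weights, n = n)
  if (fit) {
    f <- fit_best(samples)
    out$fitted_family <- f$family
    out$fit_params <- f$params
    out$ks_stats <- f$ks_stats
  }
  structure(out, class = "cell_exposure")
}

#' Select the better of gamma and normal fits by Kolmogorov-Smirnov distance
#'
#' Fits both families by maximum likelihood (closed form for the normal,
#' [MASS::fitdistr()] for the gamma), computes each fit's KS statistic, and
#' selects the family with the smaller statistic.
#'
#' @param samples numeric vector (>= 100 values, positive spread).
#' @return list `family` (`"gamma"` or `"normal"`), `params`, `ks_stats`
#'   (named numeric with both statistics).
#' @export
fit_best <- function(samples) {
  if (length(samples) < 100) stop_rfemap("need >= 100 samples", "insufficient_data")
  if (stats::sd(samples) == 0) {
    stop_rfemap("zero-variance sample", "degenerate_distribution")
  }
  norm_par <- c(mean = mean(samples),
                sd = stats::sd(samples) * sqrt((length(samples) - 1) / length(samples)))
  ks_norm <- suppressWarnings(stats::ks.test(
    samples, "pnorm", norm_par[["mean"]], norm_par[["sd"]]))$statistic

  gam_par <- tryCatch({
    if (any(samples <= 0)) stop("gamma needs positive data")
    m <- mean(samples); v <- stats::var(samples)
    start <- list(shape = m^2 / v, rate = m / v)
    fit <- suppressWarnings(MASS::fitdistr(samples, "gamma", start = start,
                                           lower = c(1e-8, 1e-8)))
    fit$estimate
  }, error = function(e) NULL)

  if (is.null(gam_par)) {
    return(list(family = "normal", params = norm_par,
                ks_stats = c(gamma = NA_real_, normal = unname(ks_norm))))
  }
  ks_gam <- suppressWarnings(stats::ks.test(
    samples, "pgamma", gam_par[["shape"]], gam_par[["rate"]]))$statistic

  ks <- c(gamma = unname(ks_gam), normal = unname(ks_norm))
  if (ks[["gamma"]] <= ks[["normal"]]) {
    list(family = "gamma", params = gam_par, ks_stats = ks)
  } else {
    list(family = "normal", params = norm_par, ks_stats = ks)
  }
}
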