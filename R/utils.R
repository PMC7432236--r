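#' @keywords internal
"_PACKAGE"

# Derive a reproducible sub-seed for a pipeline stage from the run seed.
# Keeps results invariant to how much RNG an earlier stage consumed.
# Result stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    scene = 101L, drive = 211L, sensors = 307L, indoor_design = 401L,
    kriging = 503L, temporal = 601L, indoor = 701L, uplink = 809L,
    aggregate = 907L
  )
  off <- offsets[[stage]]
  # headroom below 2^31 so callers can add small per-unit offsets
  as.integer((as.numeric(seed) * 7919 + off) %% 2000000000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rfemap <- function(msg, class) {
  stop(structure(
    class = c(class, "rfemap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Weighted quantiles of type-7 flavour (linear interpolation on the weighted
# empirical cdf). Used for district-wide person-hour-weighted summaries.
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}
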