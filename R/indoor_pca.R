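# 2D indoor field surrogate: linear-kernel PCA of training field maps plus
# one ordinary-kriging model per retained component score over the source
# position space.

#' Train a PCA + kriging surrogate of 2D indoor field maps
#'
#' Training maps (one per known source position) are centred and decomposed
#' by principal component analysis; the smallest number `d` of components
#' whose cumulative explained variance reaches `variance_threshold` is
#' retained, and each component score is interpolated over source-position
#' space by ordinary kriging (zero-nugget exponential model by default, so
#' training maps are reproduced exactly).
#'
#' @param maps numeric matrix, one row per training map (flattened field
#'   map), all on a common spatial grid.
#' @param positions matrix n x 2 of source positions matching the map rows.
#' @param variance_threshold cumulative explained-variance cutoff in (0, 1].
#' @param range_m kriging range over source-position space; default half the
#'   largest pairwise source distance.
#' @return object of class `pca2d_surrogate`.
#' @export
pca_kriging_fit <- function(maps, positions, variance_threshold = 0.995,
                            range_m = NULL) {
  maps <- as.matrix(maps)
  positions <- as.matrix(positions)
  n <- nrow(maps)
  if (n < 3) stop_rfemap("need >= 3 training maps", "insufficient_training")
  stopifnot(nrow(positions) == n, ncol(positions) == 2)

  mean_map <- colMeans(maps)
  Xc <- sweep(maps, 2, mean_map)
  sv <- svd(Xc)
  ev <- sv$d^2
  total <- sum(ev)
  if (total <= 1e-12 * n * max(1, mean(maps^2))) {
    # degenerate: all maps identical
    d <- 1L
    scores <- matrix(0, n, 1)
    comps <- matrix(0, ncol(maps), 1)
  } else {
    cum <- cumsum(ev) / total
    d <- which(cum >= variance_threshold)[1]
    d <- max(1L, min(d, n))
    scores <- sv$u[, seq_len(d), drop = FALSE] %*%
      diag(sv$d[seq_len(d)], d, d)
    comps <- sv$v[, seq_len(d), drop = FALSE]
  }

  if (is.null(range_m)) {
    range_m <- max(stats::dist(positions)) / 2
  }
  krig <- lapply(seq_len(d), function(j) {
    s2 <- stats::var(scores[, j])
    list(model_family = "exponential", nugget = 0,
         partial_sill = max(s2, 1e-12), range_m = range_m)
  })

  structure(list(
    d = d, mean_map = mean_map, components = comps, scores = scores,
    positions = positions, kriging = krig,
    explained_variance = ev / max(total, 1e-300)
  ), class = "pca2d_surrogate")
}

#' Predict a 2D indoor field map at a new source position
#'
#' Kriges each retained component score at the requested source position,
#' reconstructs the map by inverse PCA, and clips negative reconstructed
#' field values to zero (flagged). Source positions outside the training
#' hull's bounding box are flagged as extrapolated.
#'
#' @param model a [pca_kriging_fit()] surrogate.
#' @param source_position numeric `c(x, y)`.
#' @return numeric field map (same length as the training maps), with
#'   attributes `clipped` (count of negative pixels clipped) and
#'   `extrapolated` (logical).
#' @export
pca_kriging_predict <- function(model, source_position) {
  p <- model$positions
  extrap <- source_position[1] < min(p[, 1]) || source_position[1] > max(p[, 1]) ||
    source_position[2] < min(p[, 2]) || source_position[2] > max(p[, 2])
  sc <- vapply(seq_len(model$d), function(j) {
    vg <- model$kriging[[j]]
    sol <- ok_solve(p[, 1], p[, 2], model$scores[, j],
                    source_position[1], source_position[2], vg)
    sol$z_log  # kriged score (the machinery is scale-agnostic)
  }, numeric(1))
  map <- model$mean_map + as.vector(model$components %*% sc)
  clipped <- sum(map < 0)
  map[map < 0] <- 0
  attr(map, "clipped") <- clipped
  attr(map, "extrapolated") <- extrap
  map
}

#' @export
print.pca2d_surrogate <- function(x, ...) {
  cat(sprintf("PCA+kriging 2D surrogate: %d training maps, d = %d components\n",
              nrow(x$positions), x$d))
  invisible(x)
}
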