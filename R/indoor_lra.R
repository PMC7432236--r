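# Low-rank tensor-approximation (LRA) surrogate: the multivariate SAR
# response is expressed as a finite sum of rank-one products of univariate
# polynomial functions, trained by greedy rank-one corrections with
# alternating least squares.

# Orthonormal Legendre polynomials on [-1, 1] (orthonormal w.r.t. the
# uniform density): column k+1 is sqrt(2k+1) * P_k(x).
legendre_basis <- function(x, degree) {
  n <- length(x)
  B <- matrix(0, n, degree + 1)
  B[, 1] <- 1
  if (degree >= 1) B[, 2] <- x
  if (degree >= 2) {
    for (k in 1:(degree - 1)) {
      B[, k + 2] <- ((2 * k + 1) * x * B[, k + 1] - k * B[, k]) / (k + 1)
    }
  }
  sweep(B, 2, sqrt(2 * seq(0, degree) + 1), `*`)
}

# Affine map of inputs onto the canonical [-1, 1]^M cube.
scale_to_cube <- function(X, bounds) {
  X <- as.matrix(X)
  U <- sapply(seq_len(ncol(X)), function(i) {
    2 * (X[, i] - bounds[i, 1]) / (bounds[i, 2] - bounds[i, 1]) - 1
  })
  matrix(U, nrow = nrow(X))
}

#' Fit a low-rank tensor-approximation surrogate
#'
#' Approximates a response `Y0` on inputs `X0` as
#' `sum_l b_l * prod_i v_l_i(X_i)`, where each `v_l_i` is a univariate
#' polynomial in an orthonormal Legendre basis on inputs scaled to
#' `[-1, 1]`. Rank-one terms are built greedily on the current residual by
#' alternating least squares: holding all dimensions but one fixed, the
#' basis coefficients of that dimension solve a linear least-squares
#' problem; sweeps repeat until the relative change of the training RMSE
#' drops below `tol` or `max_sweeps` is hit. After each new rank the
#' normalizing constants `b` are re-estimated jointly on all accumulated
#' rank-one terms.
#'
#' @param X0 n x M input matrix (the experimental set).
#' @param Y0 numeric responses (e.g. whole-body SAR, mW/kg).
#' @param rank decomposition rank R (>= 1).
#' @param degree polynomial degree of each univariate function (default 4).
#' @param bounds M x 2 matrix of input-domain bounds; default data range.
#' @param tol ALS stopping tolerance on relative training-RMSE change.
#' @param max_sweeps ALS sweep cap per rank.
#' @return object of class `lra_surrogate`.
#' @export
lra_fit <- function(X0, Y0, rank = 5, degree = 4, bounds = NULL,
                    tol = 1e-8, max_sweeps = 100) {
  X0 <- as.matrix(X0)
  N <- nrow(X0); M <- ncol(X0); P <- degree + 1
  if (rank < 1) stop_rfemap("rank must be >= 1", "invalid_config")
  n_coef <- rank * M * P + rank
  if (N < n_coef) {
    stop_rfemap(sprintf(
      "experimental set too small: %d points for %d coefficients",
      N, n_coef), "underdetermined_design")
  }
  if (is.null(bounds)) {
    bounds <- t(apply(X0, 2, range))
  }
  U <- scale_to_cube(X0, bounds)
  Phi <- lapply(seq_len(M), function(i) legendre_basis(U[, i], degree))

  Z <- vector("list", rank)        # Z[[l]] is a P x M coefficient matrix
  W <- matrix(0, N, 0)             # rank-one term values on the training set
  b <- numeric(0)
  res <- Y0
  y_rms <- sqrt(mean(Y0^2))
  converged <- logical(rank)

  # ALS sweeps fitting one rank-one term to a target; z normalized per dim
  als_rank <- function(target, z) {
    w_dims <- sapply(seq_len(M), function(i) Phi[[i]] %*% z[, i])
    rmse_prev <- Inf
    conv <- FALSE
    for (sweep in seq_len(max_sweeps)) {
      for (i in seq_len(M)) {
        other <- apply(w_dims[, -i, drop = FALSE], 1, prod)
        A <- Phi[[i]] * other
        coef <- stats::lsfit(A, target, intercept = FALSE)$coefficients
        nrm <- sqrt(sum(coef^2))
        if (nrm == 0) { coef[1] <- 1; nrm <- 1 }
        z[, i] <- coef / nrm
        w_dims[, i] <- Phi[[i]] %*% z[, i]
      }
      w <- apply(w_dims, 1, prod)
      s <- sum(w * target) / max(sum(w * w), 1e-300)
      rmse <- sqrt(mean((target - s * w)^2))
      if (rmse < 1e-14 * max(y_rms, 1e-300) ||
          (is.finite(rmse_prev) &&
             abs(rmse_prev - rmse) <= tol * max(rmse_prev, 1e-300))) {
        conv <- TRUE
        break
      }
      rmse_prev <- rmse
    }
    list(z = z, w = apply(w_dims, 1, prod), converged = conv)
  }

  # greedy rank-by-rank construction on the running residual
  for (l in seq_len(rank)) {
    z0 <- matrix(0, P, M)
    z0[1, ] <- 1                   # start from the constant function
    fit_l <- als_rank(res, z0)
    converged[l] <- fit_l$converged
    Z[[l]] <- fit_l$z
    W <- cbind(W, fit_l$w)
    b <- stats::lsfit(W, Y0, intercept = FALSE)$coefficients
    res <- Y0 - W %*% b
  }

  # refinement: joint ALS across ranks (CP-style) — for each input
  # dimension the basis coefficients of every rank are re-solved in one
  # least-squares problem, until the training RMSE stabilizes
  if (rank > 1) {
    w_dims <- lapply(seq_len(rank), function(l) {
      sapply(seq_len(M), function(i) Phi[[i]] %*% Z[[l]][, i])
    })
    rmse_prev <- sqrt(mean(res^2))
    for (it in seq_len(max_sweeps)) {
      for (i in seq_len(M)) {
        A <- do.call(cbind, lapply(seq_len(rank), function(l) {
          other <- apply(w_dims[[l]][, -i, drop = FALSE], 1, prod)
          Phi[[i]] * other
        }))
        coef <- stats::lsfit(A, Y0, intercept = FALSE)$coefficients
        for (l in seq_len(rank)) {
          cl <- coef[((l - 1) * P + 1):(l * P)]
          nrm <- sqrt(sum(cl^2))
          if (nrm == 0) { cl[1] <- 1; nrm <- 1 }
          Z[[l]][, i] <- cl / nrm
          w_dims[[l]][, i] <- Phi[[i]] %*% Z[[l]][, i]
          b[l] <- nrm
        }
      }
      W <- sapply(seq_len(rank), function(l) apply(w_dims[[l]], 1, prod))
      b <- stats::lsfit(W, Y0, intercept = FALSE)$coefficients
      res <- Y0 - W %*% b
      rmse <- sqrt(mean(res^2))
      if (rmse < 1e-14 * max(y_rms, 1e-300) ||
          abs(rmse_prev - rmse) <= tol * max(rmse_prev, 1e-300)) break
      rmse_prev <- rmse
    }
  }

  structure(list(
    rank = rank, M = M, degree = degree, basis = "legendre_orthonormal",
    bounds = bounds, Z = Z, b = as.numeric(b),
    training_rmse = sqrt(mean(res^2)),
    converged = converged
  ), class = "lra_surrogate")
}

#' Evaluate a low-rank surrogate
#'
#' Computes the finite sum of rank-one products at new input points. Points
#' outside the training domain bounds are still evaluated but flagged via
#' the `"extrapolated"` attribute.
#'
#' @param model an [lra_fit()] surrogate.
#' @param X matrix (or vector for a single point) of inputs.
#' @return numeric predictions, with attribute `extrapolated` (logical per
#'   point).
#' @export
lra_predict <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$M) {
    stop_rfemap("input dimension mismatch", "invalid_input")
  }
  extrap <- rowSums(matrix(
    sapply(seq_len(model$M), function(i) {
      X[, i] < model$bounds[i, 1] | X[, i] > model$bounds[i, 2]
    }), nrow = nrow(X))) > 0
  U <- scale_to_cube(X, model$bounds)
  Phi <- lapply(seq_len(model$M), function(i) legendre_basis(U[, i], model$degree))
  pred <- rep(0, nrow(X))
  for (l in seq_len(model$rank)) {
    w <- rep(1, nrow(X))
    for (i in seq_len(model$M)) {
      w <- w * as.vector(Phi[[i]] %*% model$Z[[l]][, i])
    }
    pred <- pred + model$b[l] * w
  }
  attr(pred, "extrapolated") <- extrap
  pred
}

#' @export
print.lra_surrogate <- function(x, ...) {
  cat(sprintf(
    "LRA surrogate: rank %d, %d inputs, degree %d, training RMSE %.3g\n",
    x$rank, x$M, x$degree, x$training_rmse))
  invisible(x)
}

#' Serialize a low-rank surrogate to portable JSON
#'
#' Writes coefficients, bounds and the basis specification so trained models
#' can be exchanged between implementations.
#'
#' @param model an [lra_fit()] surrogate.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
lra_write <- function(model, path) {
  payload <- list(
    format = "rfemap-lra-1",
    rank = model$rank, M = model$M, degree = model$degree,
    basis = model$basis,
    bounds = unname(model$bounds),
    b = model$b,
    Z = model$Z,
    training_rmse = model$training_rmse
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized low-rank surrogate
#'
#' @param path file written by [lra_write()].
#' @return an `lra_surrogate` object.
#' @export
lra_read <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(p$format, "rfemap-lra-1"))
  bounds <- matrix(p$bounds, ncol = 2)
  Z <- if (is.array(p$Z) && length(dim(p$Z)) == 3) {
    lapply(seq_len(dim(p$Z)[1]), function(l) {
      matrix(p$Z[l, , ], dim(p$Z)[2], dim(p$Z)[3])
    })
  } else if (is.list(p$Z)) {
    lapply(p$Z, as.matrix)
  } else {
    list(as.matrix(p$Z))
  }
  structure(list(
    rank = p$rank, M = p$M, degree = p$degree, basis = p$basis,
    bounds = bounds, Z = Z, b = as.numeric(p$b),
    training_rmse = p$training_rmse,
    converged = NULL
  ), class = "lra_surrogate")
}
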