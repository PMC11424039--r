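#' Non-negative least-squares deconvolution
#'
#' Solves `argmin ||A x - y||^2  s.t.  x >= 0` for a built
#' [build_operator()] (or any matrix) and a measured signal, returning
#' per-streamline intra-axonal signal fractions. The solver is a
#' deterministic block principal pivoting method (Portugal-Judice-Vicente)
#' on the normal equations: whole blocks of infeasible primal/dual
#' variables are exchanged between the active and passive sets, falling
#' back to single-index (Murty) exchanges when cycling threatens, which
#' guarantees finite termination at the exact KKT point.
#'
#' @param operator a `streamline_operator` or a numeric matrix.
#' @param signal measured signal: a 4D array on the operator's grid, or a
#'   vector in the operator's row ordering.
#' @param prune_threshold weights at or below this value are marked not
#'   kept in the returned mask (numerical zero; default 1e-10).
#' @return A `streamline_weights` object: list with `x` (per-streamline
#'   weights), `x_full` (all columns, compartments included),
#'   `residual_norm`, `kept_mask`, and `col_type`.
#' @export
solve_nnls <- function(operator, signal, prune_threshold = 1e-10) {
  if (is.matrix(operator) || inherits(operator, "Matrix")) {
    A <- operator
    y <- as.numeric(signal)
    if (nrow(A) != length(y)) stop_invalid("operator rows must match signal length")
    n_sl <- ncol(A)
    col_type <- rep("stick", n_sl)
  } else {
    A <- operator$A
    y <- flatten_signal(operator, signal)
    n_sl <- operator$n_streamlines
    col_type <- operator$col_type
  }
  AtA <- as.matrix(Matrix::crossprod(A))
  Aty <- as.numeric(Matrix::crossprod(A, y))
  x <- nnls_bpp(AtA, Aty)
  r <- y - as.numeric(A %*% x)
  xs <- x[seq_len(n_sl)]
  structure(list(
    x = xs, x_full = x,
    residual_norm = sqrt(sum(r^2)),
    kept_mask = xs > prune_threshold,
    prune_threshold = prune_threshold,
    col_type = col_type
  ), class = "streamline_weights")
}

#' @export
print.streamline_weights <- function(x, ...) {
  cat("Streamline weights:", length(x$x), "streamlines,",
      sum(x$kept_mask), "kept\n")
  cat("  residual norm:", format(x$residual_norm), "\n")
  invisible(x)
}

# Block principal pivoting NNLS on the normal equations.
# Zero columns (AtA diagonal == 0) are pinned to the active set.
nnls_bpp <- function(AtA, Atb, tol = NULL, max_iter = 2000L) {
  n <- length(Atb)
  if (n == 0) return(numeric(0))
  dia <- diag(AtA)
  if (is.null(tol)) tol <- 1e-12 * max(dia, 1)
  solvable <- dia > 0
  x <- numeric(n)
  w <- -Atb                       # dual: grad = AtA x - Atb
  if (all(w >= -tol)) return(x)   # x = 0 already optimal
  FF <- rep(FALSE, n)             # passive (free) set
  p <- 3L
  n_inf_prev <- n + 1L
  for (it in seq_len(max_iter)) {
    infeas <- which((FF & x < -tol) | (!FF & solvable & w < -tol))
    if (length(infeas) == 0) {
      x[x < 0] <- 0
      return(x)
    }
    if (length(infeas) < n_inf_prev) {
      n_inf_prev <- length(infeas)
      p <- 3L
      FF[infeas] <- !FF[infeas]
    } else if (p > 0L) {
      p <- p - 1L
      FF[infeas] <- !FF[infeas]
    } else {
      k <- max(infeas)            # Murty's least-index style fallback
      FF[k] <- !FF[k]
    }
    x <- numeric(n)
    if (any(FF)) {
      x[FF] <- solve_psd(AtA[FF, FF, drop = FALSE], Atb[FF])
    }
    w <- as.numeric(AtA %*% x) - Atb
  }
  warning("NNLS did not converge in ", max_iter, " pivoting iterations")
  x[x < 0] <- 0
  x
}

# Cholesky solve with a tiny ridge fallback for (numerically) singular
# passive-set Gram matrices.
solve_psd <- function(M, b) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-10 * mean(diag(M))
    ch <- chol(M + diag(ridge, nrow(M)))
  }
  backsolve(ch, forwardsolve(t(ch), b))
}

#' Filter implausible streamlines by weight
#'
#' Marks streamlines as kept when their recovered intra-axonal signal
#' fraction exceeds `threshold`; filtered streamlines are excluded from
#' all downstream bundle and connectome computations.
#'
#' @param weights a `streamline_weights` object from [solve_nnls()].
#' @param threshold nonnegative weight threshold (default the weights'
#'   prune threshold).
#' @return The `streamline_weights` with an updated `kept_mask`.
#' @export
filter_streamlines <- function(weights, threshold = weights$prune_threshold) {
  if (threshold < 0) stop_invalid("threshold must be nonnegative")
  weights$kept_mask <- weights$x > threshold
  weights$prune_threshold <- threshold
  weights
}
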