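#' Multi-shell acquisition schemes
#'
#' An acquisition scheme is the gradient table every signal model in the
#' package evaluates against: one b-value (s/mm^2) and one unit gradient
#' direction per acquired volume, with b = 0 volumes carrying zero vectors.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs numeric matrix, `length(bvals)` x 3, unit rows (zero rows
#'   allowed where `bvals == 0`).
#' @return An object of class `acquisition_scheme`: a list with `bvals`,
#'   `bvecs` and `n_b0` (number of b = 0 volumes).
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3) {
    stop_invalid("bvecs must be a length(bvals) x 3 matrix")
  }
  if (any(bvals < 0)) stop_invalid("b-values must be nonnegative")
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- abs(nrm - 1) > 1e-6 & !(bvals == 0 & nrm < 1e-12)
  if (any(bad)) {
    stop_invalid("all b > 0 directions must have unit norm (offending volume ",
                 which(bad)[1], ")")
  }
  structure(
    list(bvals = bvals, bvecs = bvecs, n_b0 = sum(bvals == 0)),
    class = "acquisition_scheme"
  )
}

#' Build a multi-shell scheme with near-uniform directions
#'
#' Directions on each shell are placed on a deterministic Fibonacci spiral
#' (approximately uniform over the sphere) and the whole shell is given a
#' random rotation drawn from the seed, so different seeds give different
#' but equally uniform direction sets.
#'
#' @param shells list of `c(b, n_dirs)` pairs (or a 2-column matrix), one per
#'   shell: the b-value in s/mm^2 and the number of directions on that shell.
#' @param n_b0 number of interleaved b = 0 volumes (prepended).
#' @param seed integer seed controlling the per-shell rotations.
#' @return An [acquisition_scheme()].
#' @examples
#' sch <- make_scheme(list(c(500, 30), c(1200, 30), c(2400, 60),
#'                         c(4000, 60), c(6000, 60)), n_b0 = 14, seed = 1)
#' length(sch$bvals)  # 254 volumes
#' @export
make_scheme <- function(shells, n_b0 = 0, seed = 1) {
  if (is.matrix(shells)) shells <- asplit(shells, 1)
  if (length(shells) == 0) stop_invalid("shell list must be nonempty")
  shells <- lapply(shells, as.numeric)
  for (s in shells) {
    if (length(s) != 2 || s[1] < 0 || s[2] < 1) {
      stop_invalid("each shell must be (b >= 0, n_dirs >= 1)")
    }
  }
  if (n_b0 < 0) stop_invalid("n_b0 must be nonnegative")
  with_seed(seed, {
    bvals <- rep(0, n_b0)
    bvecs <- matrix(0, n_b0, 3)
    for (s in shells) {
      dirs <- fibonacci_sphere(as.integer(s[2]))
      dirs <- dirs %*% t(random_rotation())
      bvals <- c(bvals, rep(s[1], nrow(dirs)))
      bvecs <- rbind(bvecs, dirs)
    }
    acquisition_scheme(bvals, bvecs)
  })
}

# n approximately uniform points on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  shells <- table(x$bvals[x$bvals > 0])
  cat("Acquisition scheme:", length(x$bvals), "volumes (",
      x$n_b0, "b=0 )\n")
  for (b in names(shells)) {
    cat("  b =", format(as.numeric(b)), "s/mm^2 x", shells[[b]], "directions\n")
  }
  invisible(x)
}

#' Read and write FSL-style gradient tables
#'
#' `write_gradient_table()` writes `<prefix>.bval` (one row of b-values) and
#' `<prefix>.bvec` (three rows: x, y, z components). `read_gradient_table()`
#' reads them back, or a single 4-column whitespace/comma table
#' (bx, by, bz, b).
#'
#' @param scheme an [acquisition_scheme()].
#' @param prefix path prefix for the `.bval`/`.bvec` pair.
#' @return `read_gradient_table()` returns an [acquisition_scheme()].
#' @export
write_gradient_table <- function(scheme, prefix) {
  writeLines(paste(sprintf("%.17g", scheme$bvals), collapse = " "),
             paste0(prefix, ".bval"))
  con <- file(paste0(prefix, ".bvec"), "w")
  on.exit(close(con))
  for (k in 1:3) {
    writeLines(paste(sprintf("%.17g", scheme$bvecs[, k]), collapse = " "), con)
  }
  invisible(prefix)
}

#' @param path for `read_gradient_table()`: either a prefix with `.bval` and
#'   `.bvec` files, or a single delimited 4-column file.
#' @rdname write_gradient_table
#' @export
read_gradient_table <- function(path) {
  if (file.exists(paste0(path, ".bval")) && file.exists(paste0(path, ".bvec"))) {
    bvals <- scan(paste0(path, ".bval"), quiet = TRUE)
    bv <- do.call(rbind, lapply(readLines(paste0(path, ".bvec")), function(l) {
      scan(text = l, quiet = TRUE)
    }))
    return(acquisition_scheme(bvals, t(bv)))
  }
  tab <- utils::read.table(path, sep = "", header = FALSE,
                           blank.lines.skip = TRUE)
  if (ncol(tab) == 1) {
    tab <- utils::read.table(path, sep = ",", header = FALSE)
  }
  if (ncol(tab) != 4) stop_invalid("gradient table must have 4 columns")
  acquisition_scheme(tab[[4]], as.matrix(tab[, 1:3]))
}
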