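#' Build the streamline deconvolution operator
#'
#' Assembles the forward linear model `y = A x` of the miniature COMMIT
#' stage. Rows index (traversed voxel, acquisition volume) pairs; columns
#' are, in order: one stick column per streamline, one zeppelin column per
#' (voxel, local bundle orientation), and one ball column per
#' (voxel, isotropic diffusivity).
#'
#' A streamline column accumulates, over its fine segments in each voxel,
#' `(segment length / total in-grid length) * stick(b, g, u_segment)`, so a
#' unit weight contributes unit b = 0 signal spread along the streamline's
#' path and the recovered weight is a signal fraction. Zeppelin columns use
#' the length-weighted mean direction of each bundle's segments in the
#' voxel (at most 3 orientations per voxel, largest length shares kept).
#' Streamlines entirely outside the grid are excluded from the operator
#' with a warning (their recovered weight is defined as 0).
#'
#' @param tck a [tractogram()]; bundle labels are taken from `tck$bundle`,
#'   falling back to endpoint-ROI pairs, else a single bundle.
#' @param grid a [voxel_grid()].
#' @param scheme an [acquisition_scheme()].
#' @param params a [kernel_params()].
#' @return A `streamline_operator`: list with the sparse matrix `A`
#'   (rows = n_voxels * n_volumes, flattened voxel-major), `voxels` (linear
#'   voxel indices of the rows), `col_type` (`"stick"`, `"zeppelin"`,
#'   `"ball"`), `n_streamlines`, `n_vol` and `dropped` (indices of excluded
#'   streamlines).
#' @export
build_operator <- function(tck, grid, scheme, params = kernel_params()) {
  if (length(tck$streamlines) == 0) stop_invalid("tractogram must be nonempty")
  if (length(scheme$bvals) == 0) stop_invalid("scheme must be nonempty")
  B <- scheme$bvals; G <- scheme$bvecs
  n_vol <- length(B)
  n_sl <- length(tck$streamlines)

  seg <- segment_table(tck, grid)
  seg <- seg[!is.na(seg$vox), , drop = FALSE]
  present <- sort(unique(seg$sl))
  dropped <- setdiff(seq_len(n_sl), present)
  if (length(dropped) > 0) {
    warning(length(dropped), " streamline(s) entirely outside the grid; ",
            "excluded from the operator")
  }
  if (nrow(seg) == 0) stop_invalid("no streamline intersects the grid")

  voxels <- sort(unique(seg$vox))
  vox_pos <- match(seg$vox, voxels)
  n_vox <- length(voxels)

  L <- rep(NA_real_, n_sl)
  Lt <- tapply(seg$len, seg$sl, sum)
  L[as.integer(names(Lt))] <- Lt

  # --- stick columns -------------------------------------------------------
  Ks <- stick_kernel_matrix(B, G, as.matrix(seg[, c("ux", "uy", "uz")]),
                            params$d_par)                 # n_vol x n_seg
  w_seg <- seg$len / L[seg$sl]
  n_seg <- nrow(seg)
  trip_i <- rep((vox_pos - 1L) * n_vol, each = n_vol) + seq_len(n_vol)
  trip_j <- rep(seg$sl, each = n_vol)
  trip_x <- as.numeric(Ks) * rep(w_seg, each = n_vol)

  # --- zeppelin columns ----------------------------------------------------
  bnd <- tck$bundle
  if (is.null(bnd)) {
    bnd <- if (!is.null(tck$endpoint_rois)) {
      as.integer(factor(paste(pmin(tck$endpoint_rois[, 1], tck$endpoint_rois[, 2]),
                              pmax(tck$endpoint_rois[, 1], tck$endpoint_rois[, 2]))))
    } else rep(1L, n_sl)
  }
  seg$bnd <- bnd[seg$sl]
  agg <- aggregate(cbind(len = seg$len, lux = seg$len * seg$ux,
                         luy = seg$len * seg$uy, luz = seg$len * seg$uz),
                   by = list(vox = seg$vox, bnd = seg$bnd), FUN = sum)
  # keep at most 3 orientations per voxel (largest in-voxel length)
  agg <- agg[order(agg$vox, -agg$len), , drop = FALSE]
  keep <- unlist(tapply(seq_len(nrow(agg)), agg$vox,
                        function(ii) ii[seq_len(min(3L, length(ii)))]),
                 use.names = FALSE)
  agg <- agg[sort(keep), , drop = FALSE]
  u <- cbind(agg$lux, agg$luy, agg$luz)
  u <- u / sqrt(rowSums(u^2))
  n_zep <- nrow(agg)
  Kz <- zeppelin_kernel_matrix(B, G, u, params$d_par_zep, params$d_perp)
  zep_pos <- match(agg$vox, voxels)
  trip_i <- c(trip_i, rep((zep_pos - 1L) * n_vol, each = n_vol) + seq_len(n_vol))
  trip_j <- c(trip_j, rep(n_sl + seq_len(n_zep), each = n_vol))
  trip_x <- c(trip_x, as.numeric(Kz))

  # --- ball columns --------------------------------------------------------
  n_iso <- length(params$d_iso_list)
  for (m in seq_len(n_iso)) {
    kb <- exp(-B * params$d_iso_list[m])
    trip_i <- c(trip_i, rep((seq_len(n_vox) - 1L) * n_vol, each = n_vol) + seq_len(n_vol))
    trip_j <- c(trip_j, rep(n_sl + n_zep + (m - 1L) * n_vox + seq_len(n_vox),
                            each = n_vol))
    trip_x <- c(trip_x, rep(kb, n_vox))
  }

  n_col <- n_sl + n_zep + n_iso * n_vox
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_vox * n_vol, n_col))
  structure(list(
    A = A, voxels = voxels, grid = grid, n_vol = n_vol,
    n_streamlines = n_sl, dropped = dropped,
    col_type = c(rep("stick", n_sl), rep("zeppelin", n_zep),
                 rep("ball", n_iso * n_vox)),
    zep_meta = agg[, c("vox", "bnd")]
  ), class = "streamline_operator")
}

#' @export
print.streamline_operator <- function(x, ...) {
  cat("Streamline operator:", nrow(x$A), "rows (", length(x$voxels),
      "voxels x", x$n_vol, "volumes ),", ncol(x$A), "columns\n")
  cat("  columns:", x$n_streamlines, "stick,",
      sum(x$col_type == "zeppelin"), "zeppelin,",
      sum(x$col_type == "ball"), "ball\n")
  invisible(x)
}

# Flatten a 4D signal array (or pass through a vector) to the operator's
# row ordering: voxel-major, volumes fastest.
flatten_signal <- function(op, signal) {
  if (is.numeric(signal) && is.null(dim(signal))) {
    if (length(signal) != nrow(op$A)) {
      stop_invalid("signal length must match operator rows")
    }
    return(as.numeric(signal))
  }
  d <- dim(signal)
  if (length(d) != 4 || prod(d[1:3]) < max(op$voxels) || d[4] != op$n_vol) {
    stop_invalid("signal array incompatible with operator grid/scheme")
  }
  flat <- matrix(signal, prod(d[1:3]), d[4])
  as.numeric(t(flat[op$voxels, , drop = FALSE]))
}

#' Apply the operator to a full coefficient vector
#'
#' @param op a `streamline_operator`.
#' @param x coefficient vector (streamlines, then zeppelin, then ball).
#' @return predicted signal vector in the operator's row ordering.
#' @export
operator_predict <- function(op, x) {
  if (length(x) != ncol(op$A)) stop_invalid("x length must match operator columns")
  as.numeric(op$A %*% x)
}

#' Ground-truth coefficient vector in operator column order
#'
#' Maps a phantom's `ground_truth` onto the operator's columns so the
#' forward models can be compared and recovery measured per column block.
#'
#' @param op a `streamline_operator`.
#' @param ground_truth the `ground_truth` from [make_crossing_phantom()].
#' @param params the [kernel_params()] used to build the operator.
#' @return numeric vector of length `ncol(op$A)`.
#' @export
ground_truth_vector <- function(op, ground_truth, params = kernel_params()) {
  x <- numeric(ncol(op$A))
  x[seq_len(op$n_streamlines)] <- ground_truth$x_true
  zf <- ground_truth$zep_fracs
  if (!is.null(zf) && nrow(zf) > 0) {
    key_op <- paste(op$zep_meta$vox, op$zep_meta$bnd)
    m <- match(paste(zf$vox, zf$bundle), key_op)
    ok <- !is.na(m)
    x[op$n_streamlines + m[ok]] <- zf$frac[ok]
  }
  iso <- ground_truth$iso_fracs
  if (!is.null(iso) && nrow(iso) > 0) {
    n_zep <- sum(op$col_type == "zeppelin")
    n_vox <- length(op$voxels)
    n_iso <- length(params$d_iso_list)
    pos <- match(iso$vox, op$voxels)
    ok <- !is.na(pos)
    for (m in seq_len(n_iso)) {
      x[op$n_streamlines + n_zep + (m - 1L) * n_vox + pos[ok]] <-
        iso$frac[ok] / n_iso
    }
  }
  x
}
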