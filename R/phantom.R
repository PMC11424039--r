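#' Voxel grids, streamlines and tractograms
#'
#' The package works in continuous millimetre coordinates: voxel
#' `(i, j, k)` (1-based indices) spans the half-open box
#' `[(i-1)*vox, i*vox) x ...`. A streamline is an ordered matrix of 3D
#' points in mm; a tractogram is a list of streamlines with optional
#' endpoint-ROI assignments and bundle labels.
#'
#' @param shape integer 3-vector of grid dimensions (voxels per axis).
#' @param voxel_size isotropic voxel edge length in mm (default 2, the
#'   acquisition resolution the package emulates).
#' @return `voxel_grid()` returns a `voxel_grid` list with `shape` and
#'   `voxel_size`.
#' @export
voxel_grid <- function(shape, voxel_size = 2.0) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop_invalid("shape must be three positive integers")
  }
  if (voxel_size <= 0) stop_invalid("voxel_size must be positive")
  structure(list(shape = shape, voxel_size = voxel_size), class = "voxel_grid")
}

#' @param streamlines list of n x 3 point matrices (mm), each with >= 2
#'   distinct consecutive points.
#' @param endpoint_rois optional n_streamlines x 2 integer matrix of ROI
#'   labels for the two endpoints (NA = unassigned).
#' @param bundle optional integer bundle label per streamline.
#' @rdname voxel_grid
#' @export
tractogram <- function(streamlines, endpoint_rois = NULL, bundle = NULL) {
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3 || nrow(s) < 2) {
      stop_invalid("each streamline must be an n x 3 matrix with n >= 2")
    }
    if (any(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2) == 0)) {
      stop_invalid("consecutive streamline points must be distinct")
    }
  }
  n <- length(streamlines)
  if (!is.null(endpoint_rois)) {
    endpoint_rois <- matrix(as.integer(endpoint_rois), ncol = 2)
    if (nrow(endpoint_rois) != n) stop_invalid("endpoint_rois must have one row per streamline")
  }
  if (!is.null(bundle) && length(bundle) != n) {
    stop_invalid("bundle must have one label per streamline")
  }
  structure(list(streamlines = streamlines, endpoint_rois = endpoint_rois,
                 bundle = bundle),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("Tractogram:", length(x$streamlines), "streamlines")
  if (!is.null(x$bundle)) cat(",", length(unique(x$bundle)), "bundles")
  cat("\n")
  invisible(x)
}

#' Streamline lengths in mm
#' @param tck a [tractogram()].
#' @return numeric vector of polyline lengths (mm).
#' @export
streamline_lengths <- function(tck) {
  vapply(tck$streamlines, function(s) {
    sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
  }, numeric(1))
}

# Resample a polyline at (approximately) equal arc-length steps.
resample_polyline <- function(pts, step) {
  seg <- pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  n_out <- max(2L, ceiling(total / step) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  cum <- c(0, cumsum(lens))
  idx <- findInterval(s_out, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(pts) - 1L)
  frac <- (s_out - cum[idx]) / lens[idx]
  pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

# Segment table: one row per fine segment of every streamline, with the
# containing voxel (by segment midpoint, 0-based half-open convention),
# segment length and unit direction. Segments outside the grid get vox = NA.
# This is the single geometry contract shared by the analytic phantom
# synthesis and the deconvolution operator.
segment_table <- function(tck, grid, step = grid$voxel_size / 10) {
  out <- vector("list", length(tck$streamlines))
  vox <- grid$voxel_size
  shp <- grid$shape
  for (k in seq_along(tck$streamlines)) {
    p <- resample_polyline(tck$streamlines[[k]], step)
    d <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    keep <- len > 0
    d <- d[keep, , drop = FALSE]; len <- len[keep]
    mid <- (p[-1, , drop = FALSE] + p[-nrow(p), , drop = FALSE])[keep, , drop = FALSE] / 2
    ijk <- floor(mid / vox)
    inside <- ijk[, 1] >= 0 & ijk[, 1] < shp[1] &
      ijk[, 2] >= 0 & ijk[, 2] < shp[2] &
      ijk[, 3] >= 0 & ijk[, 3] < shp[3]
    lin <- ifelse(inside, 1 + ijk[, 1] + shp[1] * (ijk[, 2] + shp[2] * ijk[, 3]), NA)
    out[[k]] <- data.frame(sl = k, vox = lin, len = len,
                           ux = d[, 1] / len, uy = d[, 2] / len, uz = d[, 3] / len)
  }
  do.call(rbind, out)
}

#' Generate a crossing-fibre phantom with known signal fractions
#'
#' Lays out up to three orthogonal bundles (along x, y and z) of gently
#' curved streamlines, one streamline per discrete "lane" of voxels, so the
#' bundles cross in shared voxels while every streamline keeps an
#' identifiable voxel footprint. Each streamline receives a ground-truth
#' intra-axonal signal fraction drawn uniformly from \[0.2, 0.7\]; the
#' remaining per-voxel signal budget is filled with isotropic (ball,
#' default total fraction 0.2) and hindered extra-axonal (zeppelin)
#' compartments oriented along the local bundle directions. A face-slab
#' parcellation is attached so each bundle connects a distinct ROI pair.
#'
#' @param grid a [voxel_grid()] (each dimension must be >= 4).
#' @param n_bundles number of orthogonal bundles (1-3).
#' @param streamlines_per_bundle streamlines per bundle; limited by the
#'   number of interior lanes, `(shape-2)^2`.
#' @param seed integer seed (signal-fraction draws and lane jitter).
#' @param curvature lateral sinusoidal deflection amplitude as a fraction
#'   of the voxel size (default 0.25; keeps each streamline in its lane).
#' @param ball_fraction total isotropic signal fraction per traversed voxel.
#' @param add_decoy add one streamline through otherwise empty voxels with
#'   true weight 0 (for testing implausible-streamline filtering).
#' @return list with `tractogram`, `ground_truth` (fields `x_true`,
#'   `iso_fracs`, `zep_fracs`), and `parcellation`.
#' @export
make_crossing_phantom <- function(grid, n_bundles = 2, streamlines_per_bundle = 20,
                                  seed = 1, curvature = 0.25,
                                  ball_fraction = 0.2, add_decoy = FALSE) {
  if (n_bundles < 1 || n_bundles > 3) stop_invalid("n_bundles must be 1, 2 or 3")
  shp <- grid$shape
  if (any(shp < 4)) stop_invalid("grid too small: each dimension must be >= 4")
  vox <- grid$voxel_size
  inner <- lapply(shp, function(n) seq_len(n - 2L))  # interior 1-based idx
  # lanes for a bundle along `axis`: pairs of interior indices on the two
  # transverse axes, enumerated deterministically
  lane_grid <- function(axis) {
    tr <- setdiff(1:3, axis)
    # reserve decoy lane: skip the lexicographically last transverse plane
    g <- expand.grid(a = inner[[tr[1]]], b = inner[[tr[2]]])
    g$axis <- axis; g$tr1 <- tr[1]; g$tr2 <- tr[2]
    g
  }
  with_seed(seed, {
    streamlines <- list(); bundle <- integer(0); ep <- NULL
    for (bnd in seq_len(n_bundles)) {
      lanes <- lane_grid(bnd)
      # with a decoy, the last transverse plane of every bundle is kept
      # free so the decoy's voxels stay signal-free
      n_a <- length(inner[[setdiff(1:3, bnd)[1]]])
      n_b <- length(inner[[setdiff(1:3, bnd)[2]]])
      max_lanes <- if (add_decoy) n_a * (n_b - 1L) else nrow(lanes)
      if (streamlines_per_bundle > max_lanes) {
        stop_invalid("grid too small for ", streamlines_per_bundle,
                     " streamlines per bundle (", max_lanes, " lanes available)")
      }
      for (i in seq_len(streamlines_per_bundle)) {
        streamlines[[length(streamlines) + 1L]] <-
          lane_streamline(lanes[i, ], shp, vox, curvature,
                          jitter = runif(2, -0.1, 0.1))
        bundle <- c(bundle, bnd)
        ep <- rbind(ep, c(2L * bnd - 1L, 2L * bnd))
      }
    }
    x_true <- runif(length(streamlines), 0.2, 0.7)
    if (add_decoy) {
      lanes <- lane_grid(1L)
      streamlines[[length(streamlines) + 1L]] <-
        lane_streamline(lanes[nrow(lanes), ], shp, vox, curvature,
                        jitter = c(0, 0))
      bundle <- c(bundle, 1L)
      ep <- rbind(ep, c(1L, 2L))
      x_true <- c(x_true, 0)
    }
    tck <- tractogram(streamlines, endpoint_rois = ep, bundle = bundle)
    gt <- phantom_ground_truth(tck, grid, x_true, ball_fraction)
    parc <- face_slab_parcellation(grid, n_bundles)
    list(tractogram = tck, ground_truth = gt, parcellation = parc)
  })
}

# One streamline running face to face along `lane$axis`, centred in lane
# (lane$a, lane$b) with a small sinusoidal lateral bow.
lane_streamline <- function(lane, shp, vox, curvature, jitter = c(0, 0)) {
  axis <- lane$axis
  n_pts <- 4L * shp[axis]
  t <- seq(0, 1, length.out = n_pts)
  along <- (0.5 + t * (shp[axis] - 1)) * vox
  p <- matrix(0, n_pts, 3)
  p[, axis] <- along
  p[, lane$tr1] <- (lane$a - 0.5 + jitter[1]) * vox +
    curvature * vox * sin(pi * t)
  p[, lane$tr2] <- (lane$b - 0.5 + jitter[2]) * vox
  p
}

# Fill each traversed voxel's remaining signal budget with ball + zeppelin
# compartments. zep_fracs rows: (vox, bundle, frac, ux, uy, uz).
phantom_ground_truth <- function(tck, grid, x_true, ball_fraction) {
  seg <- segment_table(tck, grid)
  seg <- seg[!is.na(seg$vox) & x_true[seg$sl] > 0, , drop = FALSE]
  L <- tapply(seg$len, seg$sl, sum)             # total in-grid length per sl
  w <- x_true[seg$sl] * seg$len / L[as.character(seg$sl)]
  f_intra <- tapply(w, seg$vox, sum)            # per-voxel intra fraction
  voxels <- as.integer(names(f_intra))
  iso_total <- pmin(ball_fraction, pmax(0, 1 - f_intra))
  zep_total <- 0.8 * pmax(0, 1 - f_intra - iso_total)
  # split the zeppelin budget across bundles in the voxel, in proportion to
  # each bundle's intra-axonal length contribution, along mean directions
  seg$bnd <- if (is.null(tck$bundle)) 1L else tck$bundle[seg$sl]
  agg <- aggregate(cbind(len = seg$len, lux = seg$len * seg$ux,
                         luy = seg$len * seg$uy, luz = seg$len * seg$uz),
                   by = list(vox = seg$vox, bnd = seg$bnd), FUN = sum)
  len_vox <- tapply(agg$len, agg$vox, sum)
  agg$share <- agg$len / len_vox[as.character(agg$vox)]
  u <- cbind(agg$lux, agg$luy, agg$luz)
  u <- u / sqrt(rowSums(u^2))
  zt <- zep_total[match(agg$vox, voxels)]
  zep_fracs <- data.frame(vox = agg$vox, bundle = agg$bnd,
                          frac = zt * agg$share,
                          ux = u[, 1], uy = u[, 2], uz = u[, 3])
  structure(list(
    x_true = x_true,
    iso_fracs = data.frame(vox = voxels, frac = as.numeric(iso_total)),
    zep_fracs = zep_fracs
  ), class = "ground_truth")
}

# Face-slab parcellation: ROI (2b-1, 2b) at the low/high face of bundle
# axis b; earlier axes take precedence at shared edge voxels.
face_slab_parcellation <- function(grid, n_bundles) {
  shp <- grid$shape
  lab <- array(0L, dim = shp)
  for (bnd in seq_len(n_bundles)) {
    lo <- slice_index(shp, bnd, 1L)
    hi <- slice_index(shp, bnd, shp[bnd])
    lab[lo][lab[lo] == 0L] <- 2L * bnd - 1L
    lab[hi][lab[hi] == 0L] <- 2L * bnd
  }
  labels <- sort(unique(as.integer(lab[lab > 0])))
  parcellation(lab, grid,
               roi_names = setNames(paste0("roi_", labels), labels))
}

slice_index <- function(shp, axis, i) {
  idx <- array(FALSE, dim = shp)
  if (axis == 1) idx[i, , ] <- TRUE
  if (axis == 2) idx[, i, ] <- TRUE
  if (axis == 3) idx[, , i] <- TRUE
  idx
}

#' Synthesize multi-shell signals from a phantom
#'
#' Analytic per-voxel signal accumulation: every fine streamline segment
#' contributes `x * (segment length / streamline in-grid length)` times the
#' stick attenuation along its own direction; each voxel's zeppelin and
#' ball fractions contribute their kernels. At b = 0 every kernel is 1, so
#' the b = 0 signal equals the voxel's total compartment fraction. This
#' path is independent of the deconvolution operator assembly.
#'
#' @param tck a [tractogram()].
#' @param ground_truth the `ground_truth` from [make_crossing_phantom()].
#' @param grid a [voxel_grid()].
#' @param scheme an [acquisition_scheme()].
#' @param params a [kernel_params()].
#' @return 4D array `shape x n_volumes` of normalized signals.
#' @export
simulate_signal <- function(tck, ground_truth, grid, scheme,
                            params = kernel_params()) {
  x_true <- ground_truth$x_true
  if (length(x_true) != length(tck$streamlines)) {
    stop_invalid("x_true length must match the number of streamlines")
  }
  B <- scheme$bvals; G <- scheme$bvecs
  n_vol <- length(B)
  n_xyz <- prod(grid$shape)
  flat <- matrix(0, n_xyz, n_vol)

  seg <- segment_table(tck, grid)
  seg <- seg[!is.na(seg$vox) & x_true[seg$sl] > 0, , drop = FALSE]
  if (nrow(seg) > 0) {
    L <- tapply(seg$len, seg$sl, sum)
    w <- as.numeric(x_true[seg$sl] * seg$len / L[as.character(seg$sl)])
    K <- stick_kernel_matrix(B, G, as.matrix(seg[, c("ux", "uy", "uz")]),
                             params$d_par)   # n_vol x n_seg
    M <- Matrix::sparseMatrix(i = seq_len(nrow(seg)), j = seg$vox,
                              x = w, dims = c(nrow(seg), n_xyz))
    flat <- flat + t(as.matrix(K %*% M))
  }
  zf <- ground_truth$zep_fracs
  if (!is.null(zf) && nrow(zf) > 0) {
    Kz <- zeppelin_kernel_matrix(B, G, as.matrix(zf[, c("ux", "uy", "uz")]),
                                 params$d_par_zep, params$d_perp)
    Mz <- Matrix::sparseMatrix(i = seq_len(nrow(zf)), j = zf$vox,
                               x = zf$frac, dims = c(nrow(zf), n_xyz))
    flat <- flat + t(as.matrix(Kz %*% Mz))
  }
  iso <- ground_truth$iso_fracs
  if (!is.null(iso) && nrow(iso) > 0) {
    n_iso <- length(params$d_iso_list)
    for (d in params$d_iso_list) {
      flat[iso$vox, ] <- flat[iso$vox, ] +
        outer(iso$frac / n_iso, exp(-B * d))
    }
  }
  array(flat, dim = c(grid$shape, n_vol))
}

#' Add measurement noise to a signal volume
#'
#' Gaussian noise adds independent N(0, sigma) to every sample; Rician noise
#' takes the magnitude of the signal perturbed by complex Gaussian noise,
#' `sqrt((s + n1)^2 + n2^2)`, the standard model for magnitude MR images.
#'
#' @param signal numeric array.
#' @param sigma noise standard deviation (same units as the signal).
#' @param model `"gaussian"` or `"rician"`.
#' @param seed integer seed.
#' @return array of the same shape.
#' @export
add_noise <- function(signal, sigma, model = c("gaussian", "rician"), seed = 1) {
  model <- match.arg(model)
  if (sigma < 0) stop_invalid("sigma must be nonnegative")
  if (sigma == 0) return(signal)
  with_seed(seed, {
    n <- length(signal)
    out <- if (model == "gaussian") {
      signal + rnorm(n, 0, sigma)
    } else {
      sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    }
    array(out, dim = dim(signal) %||% n)
  })
}
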