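#' Parcellations
#'
#' A parcellation labels every voxel of a grid with a positive integer ROI
#' label (0 = background), with optional ROI names and a homologous-ROI
#' (contralateral) map used by the atlas-merging rule.
#'
#' @param labels integer 3D array of ROI labels (0 = background).
#' @param grid the [voxel_grid()] the labels live on.
#' @param roi_names optional named character vector, names = labels.
#' @param homolog_map optional named integer vector mapping each label to
#'   its contralateral label; must be symmetric where defined.
#' @return A `parcellation` object.
#' @export
parcellation <- function(labels, grid, roi_names = NULL, homolog_map = NULL) {
  if (!all(dim(labels) == grid$shape)) {
    stop_invalid("label array must match the grid shape")
  }
  if (any(labels < 0)) stop_invalid("labels must be nonnegative")
  if (!is.null(homolog_map)) {
    for (l in names(homolog_map)) {
      m <- as.character(homolog_map[[l]])
      if (!is.null(homolog_map[[m]]) && homolog_map[[m]] != as.integer(l)) {
        stop_invalid("homolog_map must be symmetric")
      }
    }
  }
  structure(list(labels = labels, grid = grid, roi_names = roi_names,
                 homolog_map = homolog_map),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  labs <- setdiff(sort(unique(as.integer(x$labels))), 0L)
  cat("Parcellation:", length(labs), "ROIs on",
      paste(x$grid$shape, collapse = "x"), "grid\n")
  invisible(x)
}

#' Assign streamline endpoints to ROIs
#'
#' Each endpoint takes the label of its containing voxel; endpoints in
#' background take the label of the nearest labelled voxel within
#' `radius_mm`, else stay unassigned (NA). Streamlines with any unassigned
#' endpoint are dropped from bundle formation downstream.
#'
#' @param tck a [tractogram()].
#' @param parc a [parcellation()].
#' @param radius_mm search radius for background endpoints (default 2 mm,
#'   one voxel at the emulated resolution).
#' @return The tractogram with `endpoint_rois` filled in.
#' @export
assign_endpoints <- function(tck, parc, radius_mm = 2) {
  lab <- parc$labels
  vox <- parc$grid$voxel_size
  shp <- parc$grid$shape
  labelled <- which(lab > 0, arr.ind = TRUE)
  centers <- (labelled - 0.5) * vox
  lab_vals <- lab[labelled]
  one <- function(pt) {
    ijk <- floor(pt / vox) + 1
    if (all(ijk >= 1) && all(ijk <= shp)) {
      l <- lab[ijk[1], ijk[2], ijk[3]]
      if (l > 0) return(l)
    }
    d2 <- colSums((t(centers) - pt)^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= radius_mm) lab_vals[j] else NA_integer_
  }
  ep <- t(vapply(tck$streamlines, function(s) {
    c(one(s[1, ]), one(s[nrow(s), ]))
  }, integer(2)))
  tck$endpoint_rois <- ep
  tck
}

#' Bundle edge weight: total bundle IASF
#'
#' The connectome entry for the bundle between ROIs i and j is the
#' length-weighted total of its streamlines' intra-axonal signal
#' fractions, normalized by the bundle's mean length:
#' `a_ij = sum_k(x_k * l_k) / (sum_k(l_k) / N_ij)`.
#' When every `x_k = c` this reduces to `c * N_ij`, and a single-streamline
#' bundle returns its own `x`.
#'
#' @param x weights (IASF) of the bundle's streamlines.
#' @param lengths streamline lengths in mm (same order).
#' @return scalar edge weight.
#' @export
edge_weight <- function(x, lengths) {
  n <- length(x)
  if (n == 0) stop_invalid("edge_weight is undefined for an empty bundle")
  if (length(lengths) != n) stop_invalid("x and lengths must have equal length")
  if (any(lengths <= 0)) stop_invalid("lengths must be positive")
  if (any(x < 0)) stop_invalid("weights must be nonnegative")
  sum(x * lengths) / (sum(lengths) / n)
}

#' Build a weighted connectome from kept streamlines
#'
#' Groups kept streamlines into bundles by unordered endpoint ROI pair and
#' fills a symmetric, zero-diagonal matrix: `"IASF"` weighting applies the
#' bundle [edge_weight()] equation; `"NOS"` uses the plain streamline
#' count. Intra-ROI streamlines and streamlines with unassigned endpoints
#' are excluded. ROIs present in the parcellation but touched by no kept
#' bundle appear as isolated nodes.
#'
#' @param tck a [tractogram()] with `endpoint_rois` (see
#'   [assign_endpoints()]).
#' @param weights a `streamline_weights` object from [solve_nnls()], or a
#'   plain numeric vector of per-streamline weights (all kept). Ignored
#'   for `"NOS"` except for its `kept_mask`.
#' @param parc a [parcellation()] (defines the node set).
#' @param weighting `"IASF"` or `"NOS"`.
#' @return A `connectome` object: list with the symmetric `matrix`
#'   (dimnames = ROI labels) and `nodes` data.frame (label, name).
#' @export
build_connectome <- function(tck, weights, parc, weighting = c("IASF", "NOS")) {
  weighting <- match.arg(weighting)
  if (inherits(weights, "streamline_weights")) {
    x <- weights$x
    kept <- weights$kept_mask
  } else {
    x <- as.numeric(weights)
    kept <- rep(TRUE, length(x))
  }
  if (length(x) != length(tck$streamlines)) {
    stop_invalid("weights must align with the tractogram")
  }
  if (is.null(tck$endpoint_rois)) stop_invalid("tractogram has no endpoint ROIs")
  labels <- setdiff(sort(unique(as.integer(parc$labels))), 0L)
  n <- length(labels)
  mat <- matrix(0, n, n, dimnames = list(labels, labels))
  ep <- tck$endpoint_rois
  lens <- streamline_lengths(tck)
  use <- kept & !is.na(ep[, 1]) & !is.na(ep[, 2]) & ep[, 1] != ep[, 2]
  if (any(use)) {
    i <- pmin(ep[use, 1], ep[use, 2])
    j <- pmax(ep[use, 1], ep[use, 2])
    key <- paste(i, j)
    for (k in unique(key)) {
      members <- which(use)[key == k]
      ij <- c(i[key == k][1], j[key == k][1])
      a <- if (weighting == "IASF") {
        edge_weight(x[members], lens[members])
      } else {
        length(members)
      }
      pi_ <- match(ij[1], labels); pj <- match(ij[2], labels)
      mat[pi_, pj] <- mat[pj, pi_] <- a
    }
  }
  connectome(mat, weighting = weighting,
             node_names = parc$roi_names[as.character(labels)])
}

#' Connectome container
#'
#' @param mat symmetric nonnegative matrix with zero diagonal; dimnames
#'   are node (ROI) labels.
#' @param weighting `"IASF"`, `"NOS"` or other descriptive string.
#' @param node_names optional display names per node.
#' @param groups optional named vector: node label -> group (canonical
#'   network) name.
#' @return A `connectome` object.
#' @export
connectome <- function(mat, weighting = "IASF", node_names = NULL,
                       groups = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop_invalid("connectome matrix must be square")
  if (max(abs(mat - t(mat))) > 1e-8) stop_invalid("connectome must be symmetric")
  if (any(mat < 0)) stop_invalid("connectome must be nonnegative")
  if (any(diag(mat) != 0)) stop_invalid("connectome diagonal must be zero")
  if (is.null(dimnames(mat))) {
    dimnames(mat) <- list(seq_len(nrow(mat)), seq_len(nrow(mat)))
  }
  nodes <- data.frame(label = rownames(mat),
                      name = node_names %||% rownames(mat),
                      row.names = NULL)
  if (!is.null(groups)) nodes$group <- unname(groups[nodes$label])
  structure(list(matrix = mat, weighting = weighting, nodes = nodes),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome (", x$weighting, "-weighted): ", nrow(x$matrix),
      " nodes, ", sum(x$matrix[upper.tri(x$matrix)] > 0), " edges\n", sep = "")
  invisible(x)
}

#' Extract the subgraph of one canonical network
#'
#' Keeps only the nodes assigned to `group` and the edges among them;
#' between-group edges are discarded.
#'
#' @param conn a [connectome()].
#' @param assignment a `network_assignment` (see [merge_atlas()]) or a
#'   named vector node label -> group.
#' @param group group (network) name.
#' @return A [connectome()] over the group's nodes.
#' @export
subnetwork_extract <- function(conn, assignment, group) {
  map <- assignment_map(assignment)
  if (!group %in% map) stop_invalid("unknown group: ", group)
  keep <- rownames(conn$matrix)[rownames(conn$matrix) %in%
                                  names(map)[map == group]]
  if (length(keep) == 0) stop_invalid("group ", group, " has no nodes in this connectome")
  sub <- conn$matrix[keep, keep, drop = FALSE]
  connectome(sub, weighting = conn$weighting,
             groups = map[keep])
}

assignment_map <- function(assignment) {
  if (inherits(assignment, "network_assignment")) {
    setNames(assignment$assignment$group, assignment$assignment$roi)
  } else if (!is.null(names(assignment))) {
    assignment
  } else {
    stop_invalid("assignment must be a network_assignment or a named vector")
  }
}

#' Connection density
#'
#' Fraction of possible (unordered, off-diagonal) node pairs connected by
#' a nonzero edge.
#'
#' @param conn a [connectome()] or square symmetric matrix.
#' @return density in \[0, 1\].
#' @export
connection_density <- function(conn) {
  m <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  n <- nrow(m)
  if (n < 2) stop_invalid("density needs at least 2 nodes")
  sum(m[upper.tri(m)] > 0) / (n * (n - 1) / 2)
}

#' Read and write connectome CSV matrices
#'
#' The matrix is written as a labelled CSV; node metadata (label, name,
#' group) goes to a sidecar TSV at `<path>.nodes.tsv`.
#'
#' @param conn a [connectome()].
#' @param path CSV path.
#' @export
write_connectome <- function(conn, path) {
  write.csv(as.data.frame(conn$matrix), path, row.names = TRUE)
  utils::write.table(conn$nodes, paste0(path, ".nodes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param weighting weighting tag for the read connectome.
#' @rdname write_connectome
#' @export
read_connectome <- function(path, weighting = "IASF") {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- rownames(m)
  groups <- NULL
  nt <- paste0(path, ".nodes.tsv")
  if (file.exists(nt)) {
    nodes <- utils::read.table(nt, sep = "\t", header = TRUE,
                               colClasses = "character")
    if ("group" %in% names(nodes)) groups <- setNames(nodes$group, nodes$label)
  }
  connectome(m, weighting = weighting, groups = groups)
}
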