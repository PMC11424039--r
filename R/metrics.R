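#' Metric configuration
#'
#' @param gamma modularity resolution parameter (default 1).
#' @param length_transform rule converting edge weights to path lengths for
#'   efficiency metrics; only `"reciprocal"` (length = 1/weight) is
#'   provided, matching the reference toolbox convention.
#' @return A `metric_config` list.
#' @export
metric_config <- function(gamma = 1.0, length_transform = "reciprocal") {
  if (gamma <= 0) stop_invalid("gamma must be positive")
  length_transform <- match.arg(length_transform, "reciprocal")
  structure(list(gamma = gamma, length_transform = length_transform),
            class = "metric_config")
}

metric_matrix <- function(conn) {
  m <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  if (nrow(m) != ncol(m)) stop_invalid("need a square matrix")
  m
}

#' Node strength
#'
#' Strength of node i is the sum of the weights of its links,
#' `s_i = sum_j w_ij`; `mean_strength()` averages over nodes.
#'
#' @param conn a [connectome()] or symmetric weight matrix.
#' @return `strength()`: named numeric per node; `mean_strength()`: scalar.
#' @export
strength <- function(conn) {
  rowSums(metric_matrix(conn))
}

#' @rdname strength
#' @export
mean_strength <- function(conn) {
  mean(strength(conn))
}

#' Global efficiency
#'
#' Average inverse weighted shortest-path length over ordered node pairs.
#' Weights are converted to lengths by the reciprocal rule (1/w for w > 0,
#' infinite otherwise); disconnected pairs contribute 0 (1/infinity) to
#' the average rather than being excluded.
#'
#' @param conn a [connectome()] or symmetric weight matrix.
#' @param config a [metric_config()].
#' @return scalar efficiency (in \[0, 1\] for weights in \[0, 1\]).
#' @export
global_efficiency <- function(conn, config = metric_config()) {
  m <- metric_matrix(conn)
  n <- nrow(m)
  if (n < 2) stop_invalid("global efficiency needs at least 2 nodes")
  d <- shortest_path_lengths(m)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

# All-pairs weighted shortest path lengths under the reciprocal transform
# (Dijkstra via igraph; Inf for disconnected pairs).
shortest_path_lengths <- function(m) {
  n <- nrow(m)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  }
  igraph::distances(g, algorithm = "dijkstra")
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours (the
#' node itself excluded); 0 when the node has fewer than 2 neighbours.
#'
#' @param conn a [connectome()] or symmetric weight matrix.
#' @param node node label (dimname) or index; omit for all nodes.
#' @param config a [metric_config()].
#' @return scalar for one node, or named vector for all nodes.
#' @export
local_efficiency <- function(conn, node = NULL, config = metric_config()) {
  m <- metric_matrix(conn)
  one <- function(i) {
    nb <- which(m[i, ] > 0)
    nb <- setdiff(nb, i)
    if (length(nb) < 2) return(0)
    global_efficiency(m[nb, nb, drop = FALSE], config)
  }
  if (is.null(node)) {
    out <- vapply(seq_len(nrow(m)), one, numeric(1))
    names(out) <- rownames(m)
    return(out)
  }
  i <- if (is.character(node)) match(node, rownames(m)) else as.integer(node)
  if (is.na(i) || i < 1 || i > nrow(m)) stop_invalid("unknown node: ", node)
  one(i)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Average intensity of triangles around each node. Weights are first
#' normalized by the largest weight in the graph; node i's coefficient is
#' `C_i = sum_{j,h} (w'_ij w'_ih w'_jh)^{1/3} / (k_i (k_i - 1))` over its
#' neighbour pairs (k_i = degree), 0 when k_i < 2.
#'
#' @param conn a [connectome()] or symmetric weight matrix.
#' @return named numeric vector per node; `mean_clustering()`: scalar mean.
#' @export
clustering_coefficient <- function(conn) {
  m <- metric_matrix(conn)
  mx <- max(m)
  if (mx == 0) return(setNames(rep(0, nrow(m)), rownames(m)))
  w3 <- (m / mx)^(1 / 3)
  cyc <- diag(w3 %*% w3 %*% w3)          # 2 * sum of triangle intensities
  k <- rowSums(m > 0)
  ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  setNames(ci, rownames(m))
}

#' @rdname clustering_coefficient
#' @export
mean_clustering <- function(conn) {
  mean(clustering_coefficient(conn))
}

#' Modularity by Newman spectral community detection
#'
#' Maximizes `Q = (1/v) sum_ij (w_ij - gamma s_i s_j / v) delta(c_i, c_j)`
#' (v = total weight `sum_ij w_ij`) by recursive leading-eigenvector
#' bisection of the generalized modularity matrix, each split refined by
#' Kernighan-Lin-style single-node sweeps, recursing while a split
#' increases Q. Deterministic: eigenvector sign is fixed and zero entries
#' join the positive block.
#'
#' @param conn a [connectome()] or symmetric weight matrix with positive
#'   total weight.
#' @param config a [metric_config()] (resolution `gamma`).
#' @return list with `Q` (modularity of the final partition) and
#'   `partition` (integer community id per node).
#' @export
modularity <- function(conn, config = metric_config()) {
  m <- metric_matrix(conn)
  v <- sum(m)
  if (v <= 0) stop_invalid("modularity needs positive total weight")
  n <- nrow(m)
  s <- rowSums(m)
  gamma <- config$gamma
  Bmod <- m - gamma * outer(s, s) / v    # full modularity matrix

  partition <- rep(1L, n)
  next_id <- 2L
  queue <- list(seq_len(n))
  while (length(queue) > 0) {
    grp <- queue[[1]]; queue <- queue[-1]
    if (length(grp) < 2) next
    Bg <- Bmod[grp, grp, drop = FALSE]
    # generalized modularity matrix for subdivision: remove row sums
    diag(Bg) <- diag(Bg) - rowSums(Bmod[grp, grp, drop = FALSE])
    ev <- eigen(Bg, symmetric = TRUE)
    lead <- ev$vectors[, 1]
    if (ev$values[1] <= 1e-12) next      # indivisible
    # deterministic sign: make the largest-magnitude entry positive
    if (lead[which.max(abs(lead))] < 0) lead <- -lead
    side <- lead >= 0
    side <- kl_refine(Bg, side)
    dQ <- split_gain(Bg, side) / v
    if (dQ <= 1e-12 || all(side) || !any(side)) next
    g2 <- grp[!side]
    partition[g2] <- next_id
    next_id <- next_id + 1L
    queue <- c(queue, list(grp[side]), list(g2))
  }
  Q <- modularity_value(m, partition, gamma)
  list(Q = Q, partition = partition)
}

# Q contribution of a two-way split encoded by logical `side`, given the
# subdivision matrix Bg (rows already adjusted): (1/4... ) here plain
# s' Bg s with s = +/-1, Q gain = s' Bg s / (2 v) * (1/2) — we only need
# the sign and relative magnitude, so return s' Bg s.
split_gain <- function(Bg, side) {
  sv <- ifelse(side, 1, -1)
  as.numeric(t(sv) %*% Bg %*% sv)
}

# Kernighan-Lin-style refinement: sweep single-node moves, accept the best
# improving move, repeat until no move improves the split gain.
kl_refine <- function(Bg, side) {
  repeat {
    sv <- ifelse(side, 1, -1)
    base <- as.numeric(t(sv) %*% Bg %*% sv)
    # gain of flipping node i: -4 s_i (Bg s)_i + 4 Bg_ii
    bs <- as.numeric(Bg %*% sv)
    gains <- -4 * sv * bs + 4 * diag(Bg)
    # flipping must not empty a side
    if (sum(side) == 1) gains[side] <- -Inf
    if (sum(!side) == 1) gains[!side] <- -Inf
    best <- which.max(gains)
    if (gains[best] <= 1e-12) return(side)
    side[best] <- !side[best]
  }
}

#' Modularity of a given partition
#'
#' @param m symmetric weight matrix.
#' @param partition integer community id per node.
#' @param gamma resolution parameter.
#' @return scalar Q.
#' @export
modularity_value <- function(m, partition, gamma = 1.0) {
  v <- sum(m)
  s <- rowSums(m)
  same <- outer(partition, partition, "==")
  sum((m - gamma * outer(s, s) / v) * same) / v
}

#' Per-subject, per-network metric table
#'
#' Computes the weighted network measures for each subject's whole
#' connectome and for each canonical-network subgraph: modularity Q,
#' global efficiency, mean clustering coefficient, mean strength, mean
#' local efficiency, and connection density. Subnetworks with fewer than
#' 2 nodes (or zero total weight, for modularity) get NA metrics with a
#' warning.
#'
#' @param cohort list of subject records (see [simulate_cohort()]), or a
#'   list of [connectome()]s.
#' @param assignment a `network_assignment` mapping node labels to groups.
#' @param config a [metric_config()].
#' @param metrics character subset of
#'   `c("modularity", "global_efficiency", "clustering", "mean_strength",
#'   "local_efficiency", "density")` to compute (all by default).
#' @return data.frame with one row per (subject, group), group
#'   `"whole_brain"` included, plus subject covariates when present.
#' @export
compute_metric_table <- function(cohort, assignment, config = metric_config(),
                                 metrics = c("modularity", "global_efficiency",
                                             "clustering", "mean_strength",
                                             "local_efficiency", "density")) {
  if (length(cohort) == 0) stop_invalid("cohort must be nonempty")
  metrics <- match.arg(metrics, several.ok = TRUE)
  map <- assignment_map(assignment)
  groups <- unique(unname(map))
  rows <- list()
  for (subj in cohort) {
    conn <- if (inherits(subj, "connectome")) subj else subj$connectome
    id <- if (inherits(subj, "connectome")) length(rows) + 1L else subj$id
    for (g in c("whole_brain", groups)) {
      sub <- if (g == "whole_brain") conn else {
        tryCatch(subnetwork_extract(conn, assignment, g),
                 micoconn_invalid_argument = function(e) NULL)
      }
      row <- data.frame(subject = id, group = g)
      if (!inherits(subj, "connectome")) {
        row$age <- subj$age; row$sex <- subj$sex; row$icv <- subj$icv
      }
      ok <- !is.null(sub) && nrow(sub$matrix) >= 2
      if (!ok) {
        warning("subject ", id, ", group ", g,
                ": fewer than 2 nodes; metrics recorded as missing")
      }
      for (met in metrics) {
        row[[met]] <- if (!ok) NA_real_ else switch(
          met,
          modularity = if (sum(sub$matrix) > 0) {
            modularity(sub, config)$Q
          } else NA_real_,
          global_efficiency = global_efficiency(sub, config),
          clustering = mean_clustering(sub),
          mean_strength = mean_strength(sub),
          local_efficiency = mean(local_efficiency(sub, config = config)),
          density = connection_density(sub)
        )
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-node local efficiency features for one network
#'
#' Feature matrix for the elastic-net stage: one row per subject, one
#' column per node of the requested network, entries the node's local
#' efficiency within the network subgraph.
#'
#' @inheritParams compute_metric_table
#' @param group network name.
#' @return numeric matrix, subjects x nodes.
#' @export
node_local_efficiency <- function(cohort, assignment, group,
                                  config = metric_config()) {
  rows <- lapply(cohort, function(subj) {
    conn <- if (inherits(subj, "connectome")) subj else subj$connectome
    sub <- subnetwork_extract(conn, assignment, group)
    local_efficiency(sub, config = config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (inherits(s, "connectome")) as.character(i) else as.character(s$id)
  }, character(1))
  out
}

#' Write a metric table as tidy CSV
#'
#' Long format: subject, group, metric, value (covariate columns kept).
#'
#' @param tab output of [compute_metric_table()].
#' @param path CSV path.
#' @export
write_metric_table <- function(tab, path) {
  meta <- intersect(c("subject", "group", "age", "sex", "icv"), names(tab))
  mets <- setdiff(names(tab), meta)
  long <- do.call(rbind, lapply(mets, function(m) {
    cbind(tab[meta], metric = m, value = tab[[m]])
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
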