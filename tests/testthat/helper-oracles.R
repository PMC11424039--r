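# Independent brute-force oracles used to cross-check the package's graph
# metrics and NNLS solver. These deliberately use naive algorithms
# (Floyd-Warshall, explicit triangle/partition/subset enumeration) and
# share no code with the implementation.

# All-pairs shortest path lengths by Floyd-Warshall on reciprocal lengths.
fw_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  d <- fw_distances(w)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

oracle_local_efficiency <- function(w, i) {
  nb <- setdiff(which(w[i, ] > 0), i)
  if (length(nb) < 2) return(0)
  oracle_global_efficiency(w[nb, nb, drop = FALSE])
}

# Onnela clustering by explicit neighbour-pair triangle enumeration.
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  sapply(seq_len(n), function(i) {
    nb <- setdiff(which(w[i, ] > 0), i)
    k <- length(nb)
    if (k < 2) return(0)
    tot <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        j <- nb[a]; h <- nb[b]
        tot <- tot + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    2 * tot / (k * (k - 1))
  })
}

# All set partitions of 1..n via restricted growth strings.
all_partitions <- function(n) {
  parts <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      parts[[length(parts) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  parts
}

oracle_best_modularity <- function(w, gamma = 1) {
  best <- -Inf
  for (p in all_partitions(nrow(w))) {
    q <- modularity_value(w, p, gamma)
    if (q > best) best <- q
  }
  best
}

# NNLS by exhaustive enumeration of passive sets: the optimum is the best
# feasible unconstrained LS solution over all column subsets.
oracle_nnls <- function(A, y) {
  n <- ncol(A)
  best_obj <- sum(y^2)
  best_x <- numeric(n)
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) == 0) next
    As <- A[, sel, drop = FALSE]
    xs <- tryCatch(qr.solve(As, y), error = function(e) NULL)
    if (is.null(xs) || any(xs < 0)) next
    obj <- sum((A[, sel, drop = FALSE] %*% xs - y)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_x <- numeric(n)
      best_x[sel] <- xs
    }
  }
  list(x = best_x, objective = best_obj)
}

# Random connected-ish weighted graph on n nodes (symmetric, zero diagonal).
random_graph <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  m <- sum(ut)
  vals <- ifelse(runif(m) < p_edge, runif(m, 0.1, 1), 0)
  w[ut] <- vals
  w + t(w)
}
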