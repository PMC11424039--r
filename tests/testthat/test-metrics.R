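triangle6 <- function() {
  m <- matrix(0, 6, 6)
  m[1, 2] <- m[2, 3] <- m[1, 3] <- 1
  m[4, 5] <- m[5, 6] <- m[4, 6] <- 1
  m + t(m)
}

test_that("strength sums edge weights per node", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(unname(strength(full)), rep(3, 4))
  expect_equal(unname(strength(matrix(0, 3, 3))), rep(0, 3))
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.6; m[1, 3] <- m[3, 1] <- 0.4
  expect_equal(unname(strength(m)), c(1.0, 0.6, 0.4))
  expect_equal(mean_strength(m), 2 / 3, tolerance = 1e-12)
})

test_that("global efficiency handles complete, path and empty graphs", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(global_efficiency(full), 1)
  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 3] <- 1; p3 <- p3 + t(p3)
  expect_equal(global_efficiency(p3), 5 / 6, tolerance = 1e-12)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
})

test_that("local efficiency is the neighbourhood's global efficiency", {
  # node 1 joined to a unit triangle of neighbours
  m <- matrix(0, 4, 4)
  m[1, 2:4] <- 1
  m[2, 3] <- m[3, 4] <- m[2, 4] <- 1
  m <- pmax(m, t(m))
  expect_equal(local_efficiency(m, 1), 1)
  # neighbours forming a path
  m2 <- matrix(0, 4, 4)
  m2[1, 2:4] <- 1
  m2[2, 3] <- m2[3, 4] <- 1
  m2 <- pmax(m2, t(m2))
  expect_equal(local_efficiency(m2, 1), 5 / 6, tolerance = 1e-12)
  # degree < 2
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- pmax(star, t(star))
  expect_equal(local_efficiency(star, 2), 0)
  expect_error(local_efficiency(m, 9), class = "micoconn_invalid_argument")
})

test_that("clustering coefficient matches closed forms on canonical graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- pmax(star, t(star))
  expect_equal(unname(clustering_coefficient(star)), rep(0, 5))
  wtri <- rbind(c(0, 1, 0.5), c(1, 0, 0.5), c(0.5, 0.5, 0))
  expect_equal(unname(clustering_coefficient(wtri)),
               rep((1 * 0.5 * 0.5)^(1 / 3), 3), tolerance = 1e-12)
})

test_that("graph metrics match brute-force oracles on random graphs", {
  set.seed(123)
  for (r in 1:30) {
    w <- random_graph(sample(3:6, 1))
    expect_equal(global_efficiency(w), oracle_global_efficiency(w),
                 tolerance = 1e-10)
    expect_equal(unname(clustering_coefficient(w)), oracle_clustering(w),
                 tolerance = 1e-10)
    i <- sample(nrow(w), 1)
    expect_equal(local_efficiency(w, i), oracle_local_efficiency(w, i),
                 tolerance = 1e-10)
  }
})

test_that("modularity recovers planted structure and respects identities", {
  md <- modularity(triangle6())
  expect_equal(md$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(md$partition)), 2)
  expect_equal(md$Q, oracle_best_modularity(triangle6()), tolerance = 1e-12)
  # single community has Q = 0 at gamma = 1
  expect_equal(modularity_value(triangle6(), rep(1, 6)), 0, tolerance = 1e-12)
  # complete graph: no split improves Q; trivial partition returned
  full <- matrix(1, 4, 4); diag(full) <- 0
  mf <- modularity(full)
  expect_equal(length(unique(mf$partition)), 1)
  expect_equal(mf$Q, 0, tolerance = 1e-12)
  expect_equal(oracle_best_modularity(full), 0, tolerance = 1e-12)
  expect_error(modularity(matrix(0, 3, 3)), class = "micoconn_invalid_argument")
})

test_that("modularity equals the exhaustive optimum on a ring of cliques", {
  # three unit triangles joined in a ring by weak edges
  m <- matrix(0, 9, 9)
  for (blk in 0:2) {
    id <- blk * 3 + 1:3
    m[id, id] <- 1
  }
  diag(m) <- 0
  m[3, 4] <- m[6, 7] <- m[9, 1] <- 0.1
  m <- pmax(m, t(m))
  md <- modularity(m)
  expect_equal(md$Q, oracle_best_modularity(m), tolerance = 1e-9)
})

test_that("metric scale behaviour and permutation invariance hold", {
  set.seed(55)
  w <- random_graph(6)
  c_mult <- 3.7
  expect_equal(global_efficiency(c_mult * w), c_mult * global_efficiency(w),
               tolerance = 1e-10)
  expect_equal(clustering_coefficient(c_mult * w), clustering_coefficient(w),
               tolerance = 1e-12, ignore_attr = TRUE)
  p <- sample(6)
  wp <- w[p, p]
  expect_equal(global_efficiency(wp), global_efficiency(w), tolerance = 1e-12)
  expect_equal(mean_clustering(wp), mean_clustering(w), tolerance = 1e-12)
  expect_equal(mean_strength(wp), mean_strength(w), tolerance = 1e-12)
  expect_equal(modularity(wp)$Q, modularity(w)$Q, tolerance = 1e-10)
})

test_that("metric tables have one row per subject and group", {
  assign <- default_assignment(c("a", "b"), nodes_per_group = 3)
  eff <- effect_spec(c("a", "b"))
  coh <- simulate_cohort(3, assign, eff, n_female = 1, seed = 2)
  tab <- compute_metric_table(coh, assign)
  expect_equal(nrow(tab), 3 * (2 + 1))
  expect_setequal(unique(tab$group), c("whole_brain", "a", "b"))
  expect_true(all(is.finite(tab$mean_strength)))
  # identical connectomes give identical rows
  tab2 <- compute_metric_table(list(coh[[1]], coh[[1]]), assign)
  r <- tab2[tab2$group == "a", ]
  expect_equal(r$mean_strength[1], r$mean_strength[2])
  expect_equal(r$modularity[1], r$modularity[2])
})

test_that("undersized subnetworks are recorded as missing with a warning", {
  map <- setNames(c("big", "big", "big", "tiny"), c("n1", "n2", "n3", "n4"))
  m <- matrix(0.5, 4, 4); diag(m) <- 0
  dimnames(m) <- list(names(map), names(map))
  conn <- connectome(m, groups = map)
  expect_warning(
    tab <- compute_metric_table(list(conn), network_assignment(map),
                                metrics = "mean_strength"),
    "fewer than 2 nodes")
  expect_true(is.na(tab$mean_strength[tab$group == "tiny"]))
  expect_false(is.na(tab$mean_strength[tab$group == "big"]))
})
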