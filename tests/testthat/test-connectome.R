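test_that("edge weight equation matches hand-computed values", {
  expect_equal(edge_weight(c(0.5, 0.3), c(10, 20)), 11 / 15, tolerance = 1e-12)
  # single streamline reduces to its own weight for any length
  expect_equal(edge_weight(0.4, 37), 0.4, tolerance = 1e-12)
  expect_error(edge_weight(numeric(0), numeric(0)),
               class = "micoconn_invalid_argument")
  expect_error(edge_weight(c(0.1), c(-2)), class = "micoconn_invalid_argument")
})

test_that("equal weights give a_ij = c * N_ij for any lengths", {
  set.seed(31)
  for (r in 1:20) {
    n <- sample(1:12, 1)
    cst <- runif(1, 0.05, 0.9)
    lens <- runif(n, 5, 120)
    expect_equal(edge_weight(rep(cst, n), lens), cst * n, tolerance = 1e-12)
  }
})

test_that("edge weight is invariant to streamline order and linear in x", {
  set.seed(8)
  x <- runif(6); l <- runif(6, 10, 50)
  p <- sample(6)
  expect_equal(edge_weight(x, l), edge_weight(x[p], l[p]), tolerance = 1e-12)
  expect_equal(edge_weight(3 * x, l), 3 * edge_weight(x, l), tolerance = 1e-12)
})

make_two_roi_setup <- function() {
  grid <- voxel_grid(c(4, 4, 4), 2)
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1, , ] <- 1L; lab[4, , ] <- 2L
  parc <- parcellation(lab, grid)
  sl <- function(y) cbind(seq(1, 7, length.out = 10), y, 3)
  tck <- tractogram(list(sl(3), sl(3.4), sl(4.4)))
  list(grid = grid, parc = parc, tck = tck)
}

test_that("connectome assembly follows both weighting rules", {
  s <- make_two_roi_setup()
  tck <- assign_endpoints(s$tck, s$parc)
  expect_true(all(tck$endpoint_rois[, 1] == 1 & tck$endpoint_rois[, 2] == 2))
  ci <- build_connectome(tck, rep(0.2, 3), s$parc, "IASF")
  cn <- build_connectome(tck, rep(0.2, 3), s$parc, "NOS")
  expect_equal(ci$matrix["1", "2"], 0.6, tolerance = 1e-12)
  expect_equal(cn$matrix["1", "2"], 3)
  expect_equal(max(abs(ci$matrix - t(ci$matrix))), 0)
  expect_equal(diag(ci$matrix), c(`1` = 0, `2` = 0))
})

test_that("filtered streamlines contribute to neither weighting", {
  s <- make_two_roi_setup()
  tck <- assign_endpoints(s$tck, s$parc)
  w <- structure(list(x = c(0.2, 0.2, 0.2), kept_mask = c(TRUE, TRUE, FALSE)),
                 class = "streamline_weights")
  expect_equal(build_connectome(tck, w, s$parc, "IASF")$matrix["1", "2"], 0.4)
  expect_equal(build_connectome(tck, w, s$parc, "NOS")$matrix["1", "2"], 2)
})

test_that("endpoint assignment applies the containment/radius/drop rules", {
  grid <- voxel_grid(c(5, 5, 5), 2)
  lab <- array(0L, dim = c(5, 5, 5))
  lab[1, 1, 1] <- 3L        # voxel [0,2)^3
  lab[5, 5, 5] <- 5L        # voxel [8,10)^3
  parc <- parcellation(lab, grid)
  inside <- cbind(c(1, 9), c(1, 9), c(1, 9))          # both endpoints inside ROIs
  near <- cbind(c(1, 9.5), c(1, 9.5), c(2.8, 9.5))    # start 1mm below ROI 3's voxel? no:
  # start point (1,1,2.8) lies just outside ROI 3's voxel, within 2mm of its centre
  far <- cbind(c(5, 9), c(5, 9), c(5, 9))             # start 10+ mm from any ROI
  tck <- tractogram(list(inside, near, far))
  tck <- assign_endpoints(tck, parc, radius_mm = 2)
  expect_equal(tck$endpoint_rois[1, ], c(3L, 5L))
  expect_equal(tck$endpoint_rois[2, ], c(3L, 5L))
  expect_true(is.na(tck$endpoint_rois[3, 1]))
  # dropped from bundles: the far streamline contributes no edge
  conn <- build_connectome(tck, rep(0.5, 3), parc, "NOS")
  expect_equal(conn$matrix["3", "5"], 2)
})

test_that("subnetwork extraction partitions the node set", {
  m <- matrix(runif(36), 6, 6); m <- m + t(m); diag(m) <- 0
  dimnames(m) <- list(letters[1:6], letters[1:6])
  conn <- connectome(m)
  map <- setNames(c("A", "A", "B", "B", "B", "C"), letters[1:6])
  subA <- subnetwork_extract(conn, map, "A")
  expect_equal(rownames(subA$matrix), c("a", "b"))
  expect_equal(subA$matrix["a", "b"], m["a", "b"])
  all_nodes <- unlist(lapply(c("A", "B", "C"), function(g) {
    rownames(subnetwork_extract(conn, map, g)$matrix)
  }))
  expect_setequal(all_nodes, letters[1:6])
  expect_error(subnetwork_extract(conn, map, "Z"),
               class = "micoconn_invalid_argument")
  # single all-nodes group returns the identical matrix
  whole <- subnetwork_extract(conn, setNames(rep("all", 6), letters[1:6]), "all")
  expect_equal(whole$matrix, m)
})

test_that("connection density counts nonzero off-diagonal pairs", {
  full <- matrix(1, 4, 4); diag(full) <- 0
  expect_equal(connection_density(full), 1)
  expect_equal(connection_density(matrix(0, 4, 4)), 0)
  m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 1; m[3, 4] <- m[4, 3] <- 1
  expect_equal(connection_density(m), 1 / 3)
  expect_error(connection_density(matrix(0, 1, 1)),
               class = "micoconn_invalid_argument")
})

test_that("connectome CSVs round-trip with node metadata", {
  m <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("7", "9"), c("7", "9")))
  conn <- connectome(m, groups = c(`7` = "visual", `9` = "limbic"))
  path <- file.path(withr::local_tempdir(), "conn.csv")
  write_connectome(conn, path)
  back <- read_connectome(path)
  expect_equal(back$matrix, conn$matrix)
  expect_equal(back$nodes$group, c("visual", "limbic"))
})
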