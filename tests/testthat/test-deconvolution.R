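test_that("identity operator returns the data as weights", {
  A <- diag(2)
  w <- solve_nnls(A, c(0.3, 0.5))
  expect_equal(w$x, c(0.3, 0.5), tolerance = 1e-12)
  expect_equal(w$residual_norm, 0, tolerance = 1e-12)
})

test_that("nonnegativity binds on negative data", {
  set.seed(2)
  A <- matrix(abs(rnorm(12)), 6, 2)
  y <- -as.numeric(A %*% c(1, 1))
  w <- solve_nnls(A, y)
  expect_equal(w$x, c(0, 0))
  # all-zero signal is not an error and gives zero weights
  expect_equal(solve_nnls(A, rep(0, 6))$x, c(0, 0))
})

test_that("solver matches the exhaustive active-set oracle on small instances", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:10, 1)
    m <- n + sample(0:6, 1)
    A <- matrix(runif(m * n), m, n)
    y <- as.numeric(A %*% runif(n, -0.5, 1)) + rnorm(m, 0, 0.05)
    w <- solve_nnls(A, y)
    orc <- oracle_nnls(A, y)
    expect_true(all(w$x >= 0))
    expect_equal(w$residual_norm^2, orc$objective, tolerance = 1e-8)
  }
})

test_that("solver agrees with an independent reference NNLS implementation", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (rep in 1:10) {
    A <- matrix(runif(60), 12, 5)
    y <- rnorm(12)
    ours <- solve_nnls(A, y)
    ref <- pracma::lsqnonneg(A, y)
    expect_equal(ours$x, as.numeric(ref$x), tolerance = 1e-6)
  }
})

test_that("adding a compartment column never increases the optimal residual", {
  set.seed(13)
  A <- matrix(runif(40), 10, 4)
  y <- rnorm(10)
  r1 <- solve_nnls(A, y)$residual_norm
  r2 <- solve_nnls(cbind(A, runif(10)), y)$residual_norm
  expect_lte(r2, r1 + 1e-12)
})

test_that("operator geometry: single streamline in a single b=0 voxel", {
  ph <- single_voxel_phantom()
  sch <- acquisition_scheme(0, rbind(c(0, 0, 0)))
  op <- build_operator(ph$tck, ph$grid, sch)
  # streamline column carries unit b=0 contribution after normalization
  expect_equal(sum(op$A[, 1]), 1, tolerance = 1e-12)
  expect_equal(op$n_streamlines, 1)
  expect_equal(length(op$voxels), 1)
})

test_that("parallel streamlines in disjoint voxels have disjoint row support", {
  grid <- voxel_grid(c(6, 6, 6), 2)
  s1 <- cbind(seq(1, 11, length.out = 20), 3, 3)
  s2 <- cbind(seq(1, 11, length.out = 20), 7, 7)
  tck <- tractogram(list(s1, s2), bundle = c(1L, 2L))
  op <- build_operator(tck, grid, study_scheme())
  sup1 <- which(op$A[, 1] != 0)
  sup2 <- which(op$A[, 2] != 0)
  expect_length(intersect(sup1, sup2), 0)
})

test_that("operator applied to ground truth reproduces the phantom signal", {
  grid <- voxel_grid(c(8, 8, 8), 2)
  sch <- study_scheme()
  ph <- make_crossing_phantom(grid, 2, 6, seed = 5)
  sig <- simulate_signal(ph$tractogram, ph$ground_truth, grid, sch)
  op <- build_operator(ph$tractogram, grid, sch)
  xt <- ground_truth_vector(op, ph$ground_truth)
  pred <- operator_predict(op, xt)
  y <- micoconn:::flatten_signal(op, sig)
  expect_lt(max(abs(pred - y)) / max(y), 1e-2)
})

test_that("streamlines outside the grid are excluded with a warning", {
  grid <- voxel_grid(c(4, 4, 4), 2)
  inside <- cbind(seq(1, 7, length.out = 10), 3, 3)
  outside <- cbind(seq(20, 30, length.out = 10), 25, 25)
  tck <- tractogram(list(inside, outside), bundle = c(1L, 1L))
  expect_warning(op <- build_operator(tck, grid, study_scheme()),
                 "outside the grid")
  expect_equal(op$dropped, 2L)
  # its column is all zero, so its weight solves to 0
  expect_equal(sum(op$A[, 2] != 0), 0)
})

test_that("noise-robust recovery stays accurate at moderate Rician noise", {
  grid <- voxel_grid(c(8, 8, 8), 2)
  sch <- study_scheme()
  errs <- sapply(1:3, function(s) {
    ph <- make_crossing_phantom(grid, 2, 6, seed = s)
    sig <- simulate_signal(ph$tractogram, ph$ground_truth, grid, sch)
    noisy <- add_noise(sig, 0.02, "rician", seed = 100 + s)
    op <- build_operator(ph$tractogram, grid, sch)
    w <- solve_nnls(op, noisy)
    median(abs(w$x - ph$ground_truth$x_true) / ph$ground_truth$x_true)
  })
  expect_lt(median(errs), 0.15)
})

test_that("filtering thresholds behave at the extremes", {
  w <- structure(list(x = c(0.5, 1e-12, 0.2), prune_threshold = 1e-10,
                      kept_mask = c(TRUE, TRUE, TRUE)),
                 class = "streamline_weights")
  expect_equal(filter_streamlines(w, 0)$kept_mask, c(TRUE, TRUE, TRUE))
  expect_equal(filter_streamlines(w, Inf)$kept_mask, rep(FALSE, 3))
  expect_equal(filter_streamlines(w)$kept_mask, c(TRUE, FALSE, TRUE))
  expect_error(filter_streamlines(w, -1), class = "micoconn_invalid_argument")
})
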