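test_that("single-voxel stick signal matches the closed form", {
  ph <- single_voxel_phantom(x = 0.5)
  sig <- simulate_signal(ph$tck, ph$gt, ph$grid, zx_scheme())
  expect_equal(sig[1, 1, 1, 1], 0.5, tolerance = 1e-9)               # b = 0
  expect_equal(sig[1, 1, 1, 2], 0.5 * exp(-1000 * 1.7e-3),           # g || u
               tolerance = 1e-9)
  expect_equal(sig[1, 1, 1, 3], 0.5, tolerance = 1e-9)               # g perp u
})

test_that("b=0 signal equals the total per-voxel compartment fraction", {
  grid <- voxel_grid(c(8, 8, 8), 2)
  ph <- make_crossing_phantom(grid, n_bundles = 2, streamlines_per_bundle = 6,
                              seed = 3)
  sch <- acquisition_scheme(0, rbind(c(0, 0, 0)))
  sig <- simulate_signal(ph$tractogram, ph$ground_truth, grid, sch)
  flat <- as.numeric(sig)
  # reconstruct the fraction budget independently of the synthesis path
  gt <- ph$ground_truth
  seg <- micoconn:::segment_table(ph$tractogram, grid)
  seg <- seg[!is.na(seg$vox), ]
  L <- tapply(seg$len, seg$sl, sum)
  w <- gt$x_true[seg$sl] * seg$len / L[as.character(seg$sl)]
  frac <- rep(0, prod(grid$shape))
  for (r in seq_len(nrow(seg))) frac[seg$vox[r]] <- frac[seg$vox[r]] + w[r]
  for (r in seq_len(nrow(gt$iso_fracs))) {
    frac[gt$iso_fracs$vox[r]] <- frac[gt$iso_fracs$vox[r]] + gt$iso_fracs$frac[r]
  }
  for (r in seq_len(nrow(gt$zep_fracs))) {
    frac[gt$zep_fracs$vox[r]] <- frac[gt$zep_fracs$vox[r]] + gt$zep_fracs$frac[r]
  }
  expect_equal(flat, frac, tolerance = 1e-9)
  expect_true(all(frac <= 1 + 1e-9))
})

test_that("voxel signal is invariant under joint rotation of fibres and gradients", {
  sch0 <- acquisition_scheme(c(1000, 2400), rbind(c(0, 0, 1), c(1, 0, 0)))
  ph <- single_voxel_phantom(0.6)
  base <- simulate_signal(ph$tck, ph$gt, ph$grid, sch0)
  set.seed(11)
  for (r in 1:5) {
    R <- micoconn:::random_rotation()
    ctr <- c(1, 1, 1)
    sl_rot <- t(R %*% (t(ph$tck$streamlines[[1]]) - ctr) + ctr)
    # keep only rotations that stay inside the single voxel
    if (any(sl_rot < 0.01) || any(sl_rot > 1.99)) next
    tck_rot <- tractogram(list(sl_rot), bundle = 1L)
    sch_rot <- acquisition_scheme(sch0$bvals, sch0$bvecs %*% t(R))
    rot <- simulate_signal(tck_rot, ph$gt, ph$grid, sch_rot)
    expect_equal(as.numeric(rot), as.numeric(base), tolerance = 1e-9)
  }
})

test_that("phantoms are deterministic given the seed", {
  grid <- voxel_grid(c(8, 8, 8), 2)
  p1 <- make_crossing_phantom(grid, 2, 5, seed = 77)
  p2 <- make_crossing_phantom(grid, 2, 5, seed = 77)
  expect_identical(p1$tractogram$streamlines, p2$tractogram$streamlines)
  expect_identical(p1$ground_truth$x_true, p2$ground_truth$x_true)
  p3 <- make_crossing_phantom(grid, 2, 5, seed = 78)
  expect_false(identical(p1$ground_truth$x_true, p3$ground_truth$x_true))
})

test_that("crossing bundles share voxels and land in distinct ROIs", {
  grid <- voxel_grid(c(10, 10, 10), 2)
  ph <- make_crossing_phantom(grid, n_bundles = 2, streamlines_per_bundle = 8,
                              seed = 1)
  seg <- micoconn:::segment_table(ph$tractogram, grid)
  seg <- seg[!is.na(seg$vox), ]
  vox_by_bundle <- split(seg$vox, ph$tractogram$bundle[seg$sl])
  expect_gt(length(intersect(vox_by_bundle[[1]], vox_by_bundle[[2]])), 0)
  ep <- ph$tractogram$endpoint_rois
  expect_true(all(ep[ph$tractogram$bundle == 1, ] == rep(c(1, 2), each = 8)))
  expect_true(all(ep[ph$tractogram$bundle == 2, ] == rep(c(3, 4), each = 8)))
  # ground-truth fractions live in the stated range
  expect_true(all(ph$ground_truth$x_true >= 0.2 & ph$ground_truth$x_true <= 0.7))
})

test_that("degenerate phantom requests fail cleanly", {
  expect_error(make_crossing_phantom(voxel_grid(c(3, 3, 3)), 2, 2),
               class = "micoconn_invalid_argument")
  expect_error(make_crossing_phantom(voxel_grid(c(8, 8, 8)), 2, 1000),
               class = "micoconn_invalid_argument")
  ph <- make_crossing_phantom(voxel_grid(c(8, 8, 8)), 1, 1, seed = 2)
  expect_length(ph$tractogram$streamlines, 1)
})

test_that("noise models behave as specified", {
  sig <- array(0.5, dim = c(4, 4, 4, 3))
  expect_identical(add_noise(sig, 0, "gaussian"), sig)
  big <- array(0.5, dim = c(50, 50, 40, 1))
  noisy <- add_noise(big, 0.01, "gaussian", seed = 4)
  expect_equal(sd(noisy - big), 0.01, tolerance = 0.05)
  # Rician floor on zero signal: Rayleigh mean sigma * sqrt(pi/2)
  zero <- array(0, dim = c(50, 50, 40, 1))
  ric <- add_noise(zero, 0.02, "rician", seed = 5)
  expect_equal(mean(ric), 0.02 * sqrt(pi / 2), tolerance = 0.02)
  expect_error(add_noise(sig, -1), class = "micoconn_invalid_argument")
  # reproducibility
  expect_identical(add_noise(sig, 0.1, "rician", seed = 9),
                   add_noise(sig, 0.1, "rician", seed = 9))
})
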