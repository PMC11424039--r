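# Small shared fixtures built in code.

tiny_scheme <- function(bvals, bvecs) {
  acquisition_scheme(bvals, bvecs)
}

# Scheme with one b=0 volume plus b=1000 along z and along x.
zx_scheme <- function() {
  acquisition_scheme(c(0, 1000, 1000),
                     rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)))
}

# One straight streamline along z through the centre of a single-voxel
# grid, with a hand-assembled ground truth (no zeppelin/ball).
single_voxel_phantom <- function(x = 0.5) {
  grid <- voxel_grid(c(1, 1, 1), 2)
  sl <- cbind(1, 1, seq(0.1, 1.9, length.out = 9))
  tck <- tractogram(list(sl), bundle = 1L)
  gt <- structure(list(
    x_true = x,
    iso_fracs = data.frame(vox = integer(0), frac = numeric(0)),
    zep_fracs = data.frame(vox = integer(0), bundle = integer(0),
                           frac = numeric(0), ux = numeric(0),
                           uy = numeric(0), uz = numeric(0))
  ), class = "ground_truth")
  list(grid = grid, tck = tck, gt = gt)
}

# The full 254-volume multi-shell scheme.
study_scheme <- function(seed = 1) {
  make_scheme(list(c(500, 30), c(1200, 30), c(2400, 60), c(4000, 60),
                   c(6000, 60)), n_b0 = 14, seed = seed)
}
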