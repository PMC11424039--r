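#' Compartment model parameters
#'
#' Fixed diffusivities of the stick-zeppelin-ball compartment model used both
#' to synthesize phantom signals and to build the deconvolution operator:
#' the stick (fully restricted intra-axonal compartment) has a single
#' parallel diffusivity, the zeppelin (hindered extra-axonal compartment) an
#' axially symmetric tensor, and each ball an isotropic diffusivity.
#'
#' Defaults are the white-matter values used throughout the package:
#' `d_par = d_par_zep = 1.7e-3` mm^2/s, `d_perp = 0.61e-3` mm^2/s and two
#' isotropic compartments at `1.7e-3` (hindered-isotropic) and `3.0e-3`
#' (CSF-like) mm^2/s.
#'
#' @param d_par stick parallel diffusivity, mm^2/s.
#' @param d_par_zep zeppelin parallel diffusivity, mm^2/s.
#' @param d_perp zeppelin perpendicular diffusivity, mm^2/s (must not exceed
#'   `d_par_zep`).
#' @param d_iso_list numeric vector of ball diffusivities, mm^2/s.
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(d_par = 1.7e-3, d_par_zep = 1.7e-3,
                          d_perp = 0.61e-3, d_iso_list = c(1.7e-3, 3.0e-3)) {
  if (any(c(d_par, d_par_zep, d_perp, d_iso_list) <= 0)) {
    stop_invalid("all diffusivities must be positive")
  }
  if (d_perp > d_par_zep) {
    stop_invalid("d_perp must not exceed d_par_zep")
  }
  structure(list(d_par = d_par, d_par_zep = d_par_zep, d_perp = d_perp,
                 d_iso_list = as.numeric(d_iso_list)),
            class = "kernel_params")
}

#' Stick, zeppelin and ball signal kernels
#'
#' Normalized (S/S0) diffusion signal of each compartment for b-value `b`
#' (s/mm^2), gradient direction `g` and fibre orientation `u` (both unit
#' 3-vectors):
#' * stick: `exp(-b * d_par * (g.u)^2)`
#' * zeppelin: `exp(-b * (d_perp + (d_par_zep - d_perp) * (g.u)^2))`
#' * ball: `exp(-b * d_iso)` (direction-independent)
#'
#' @param b b-value(s), s/mm^2.
#' @param g gradient direction, unit 3-vector.
#' @param u fibre orientation, unit 3-vector.
#' @param d_par,d_par_zep,d_perp,d_iso diffusivities in mm^2/s.
#' @return Signal attenuation in (0, 1].
#' @export
stick_signal <- function(b, g, u, d_par = 1.7e-3) {
  if (any(b < 0)) stop_invalid("b must be nonnegative")
  check_unit(g, "g"); check_unit(u, "u")
  exp(-b * d_par * sum(g * u)^2)
}

#' @rdname stick_signal
#' @export
zeppelin_signal <- function(b, g, u, d_par_zep = 1.7e-3, d_perp = 0.61e-3) {
  if (any(b < 0)) stop_invalid("b must be nonnegative")
  if (d_perp > d_par_zep) stop_invalid("d_perp must not exceed d_par_zep")
  check_unit(g, "g"); check_unit(u, "u")
  exp(-b * (d_perp + (d_par_zep - d_perp) * sum(g * u)^2))
}

#' @rdname stick_signal
#' @export
ball_signal <- function(b, d_iso = 3.0e-3) {
  if (any(b < 0)) stop_invalid("b must be nonnegative")
  if (d_iso <= 0) stop_invalid("d_iso must be positive")
  exp(-b * d_iso)
}

# Vectorized stick kernel: B (n_vol b-values), G (n_vol x 3), U (m x 3 unit
# rows). Returns n_vol x m matrix of attenuations. No per-call validation:
# internal hot path for operator assembly and phantom synthesis.
stick_kernel_matrix <- function(B, G, U, d_par) {
  ct2 <- (G %*% t(U))^2
  exp(-B * d_par * ct2)
}

zeppelin_kernel_matrix <- function(B, G, U, d_par_zep, d_perp) {
  ct2 <- (G %*% t(U))^2
  exp(-B * (d_perp + (d_par_zep - d_perp) * ct2))
}
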