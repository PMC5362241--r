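#' Active contractile stress of the myosin field
#'
#' The active stress generated by cortical NMIIA is an increasing, saturating
#' function of its concentration, `m / (K + m)`: linear at small `m` and
#' approaching the maximal stress (1 in non-dimensional units) when `m >> K`.
#' The saturation prevents runaway self-contraction.
#'
#' @param m NMIIA concentration (scalar or field); non-negative.
#' @param K Half-saturation constant of the stress.
#' @return The stress, same shape as `m`, in `[0, 1)`.
#' @examples
#' active_stress(c(0, 1, 100), K = 1)
#' @export
active_stress <- function(m, K) {
  if (any(m < 0)) stop("myosin concentration must be non-negative", call. = FALSE)
  stopifnot(K > 0)
  m / (K + m)
}

#' Cortical flow from a prescribed stress field
#'
#' Solves the quasi-static force balance `v - v'' = d(stress)/dx` on the
#' grid: friction balances the divergence of viscous plus active stress, so
#' the flow is screened over one non-dimensional length unit.  Discretised
#' with second-order central differences and solved directly (tridiagonal,
#' or cyclic-tridiagonal on a periodic domain).
#'
#' @param stress Stress field sampled at the cell centres.
#' @param grid A [grid_1d()] object.
#' @return The velocity field at the cell centres.
#' @export
velocity_from_stress <- function(stress, grid) {
  stopifnot(inherits(grid, "grid_1d"), length(stress) == grid$n_cells)
  velocity_from_stress_cpp(as.numeric(stress), grid$dx, grid$bc == "periodic")
}

#' Cortical flow field generated by the myosin distribution
#'
#' Computes the active stress of the NMIIA field and solves the force
#' balance `v - v'' = d/dx (m / (K + m))` for the flow.  A localized myosin
#' peak drives convergent flow directed toward the peak from both sides;
#' a spatially uniform field generates no flow.
#'
#' @param m NMIIA concentration field at the cell centres; non-negative.
#' @param grid A [grid_1d()] object.
#' @param K Half-saturation of the active stress (see [mech_params()]).
#' @return The velocity field at the cell centres.
#' @examples
#' g <- grid_1d(20, 200)
#' m <- exp(-(g$x - 10)^2)
#' v <- solve_velocity(m, g, K = 1)
#' @export
solve_velocity <- function(m, grid, K = 1) {
  stopifnot(inherits(grid, "grid_1d"), length(m) == grid$n_cells)
  velocity_from_stress(active_stress(m, K), grid)
}
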