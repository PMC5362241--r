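#' Kinetic parameters of the RhoA-NMIIA feedback circuit
#'
#' Non-dimensional parameters of the mutual-recruitment kinetics: RhoA and
#' NMIIA each recruit the other to the cortex through a Hill-type adsorption
#' term and dissociate linearly.  Concentrations are measured in units of the
#' saturation level `s/k`, so the recruitment terms saturate at 1.
#'
#' @param alpha Reaction-rate prefactor, the ratio of the diffusion timescale
#'   to the reaction timescale.  Larger `alpha` means faster kinetics relative
#'   to diffusion.  Must be positive.
#' @param kappa1 Half-saturation concentration of NMIIA in its activation of
#'   RhoA (non-dimensional).  Must be positive.
#' @param kappa2 Half-saturation concentration of RhoA in its activation of
#'   NMIIA.  Must be positive.
#' @param n Hill coefficient, a positive integer.  Default 4.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(alpha = 1, kappa1 = 0.2, kappa2 = 0.2)
#' reaction_rates(0.5, 0.5, kp)
#' @export
kinetic_params <- function(alpha = 1, kappa1 = 0.2, kappa2 = kappa1, n = 4L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  stopifnot(is.numeric(kappa1), length(kappa1) == 1, kappa1 > 0)
  stopifnot(is.numeric(kappa2), length(kappa2) == 1, kappa2 > 0)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  structure(
    list(alpha = alpha, kappa1 = kappa1, kappa2 = kappa2, n = as.integer(n)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> alpha = %g, kappa1 = %g, kappa2 = %g, n = %d\n",
    x$alpha, x$kappa1, x$kappa2, x$n
  ))
  invisible(x)
}

#' Mechanical parameters of the contractile cortex
#'
#' @param pe Peclet number, the strength of advection by the contractile flow
#'   relative to diffusion (`Pe = sigma_max / (gamma * D)` in dimensional
#'   terms).  Must be non-negative; `pe = 0` is a passive medium.
#' @param K Non-dimensional half-saturation of the active stress in the NMIIA
#'   concentration.  Active stress is `m / (K + m)`, saturating at 1.
#' @param advection_mode Which species the flow transports: `"both"`
#'   (default) or `"myosin_only"` (only the force-generating NMIIA is
#'   advected, RhoA stays membrane-bound).
#'
#' @return An object of class `mech_params`.
#' @examples
#' mech_params(pe = 12)
#' mech_params(pe = 35, advection_mode = "myosin_only")
#' @export
mech_params <- function(pe, K = 1, advection_mode = c("both", "myosin_only")) {
  stopifnot(is.numeric(pe), length(pe) == 1, pe >= 0)
  stopifnot(is.numeric(K), length(K) == 1, K > 0)
  advection_mode <- match.arg(advection_mode)
  structure(
    list(pe = pe, K = K, advection_mode = advection_mode),
    class = "mech_params"
  )
}

#' @export
print.mech_params <- function(x, ...) {
  cat(sprintf(
    "<mech_params> Pe = %g, K = %g, advection: %s\n",
    x$pe, x$K, x$advection_mode
  ))
  invisible(x)
}

#' One-dimensional cortical grid
#'
#' Cell-centred uniform grid for the junctional cortex.  All lengths are in
#' non-dimensional units of the hydrodynamic screening length
#' `l = sqrt(eta / gamma)`.
#'
#' @param length Domain size in non-dimensional length units.
#' @param n_cells Number of grid cells (at least 50).
#' @param bc Boundary conditions: `"noflux_rigid"` (rigid walls, `v = 0` at
#'   both ends, no-flux for the concentrations; the default, conserving total
#'   protein) or `"periodic"`.
#'
#' @return An object of class `grid_1d` with fields `length`, `n_cells`,
#'   `dx` and the cell-centre coordinates `x`.
#' @examples
#' g <- grid_1d(length = 40, n_cells = 400)
#' g$dx
#' @export
grid_1d <- function(length = 40, n_cells = 400,
                    bc = c("noflux_rigid", "periodic")) {
  stopifnot(is.numeric(length), length > 0)
  if (!is.numeric(n_cells) || n_cells < 50 || n_cells != round(n_cells)) {
    stop("`n_cells` must be an integer >= 50", call. = FALSE)
  }
  bc <- match.arg(bc)
  n_cells <- as.integer(n_cells)
  dx <- length / n_cells
  structure(
    list(
      length = length, n_cells = n_cells, dx = dx, bc = bc,
      x = (seq_len(n_cells) - 0.5) * dx
    ),
    class = "grid_1d"
  )
}

#' @export
print.grid_1d <- function(x, ...) {
  cat(sprintf(
    "<grid_1d> length = %g, n_cells = %d (dx = %g), bc = %s\n",
    x$length, x$n_cells, x$dx, x$bc
  ))
  invisible(x)
}

#' Time-triggered perturbation protocol
#'
#' Describes an inhibition/washout-style experiment: at `t_switch` the Peclet
#' number changes to `pe_after` and the linear dissociation terms of the two
#' species are multiplied by the given factors.  The factors multiply only
#' the decay term `-alpha * c` inside the kinetics, not the recruitment term.
#'
#' @param t_switch Time of the perturbation (non-negative).
#' @param pe_after Peclet number after the switch.
#' @param nmiia_decay_factor Multiplier on the NMIIA dissociation term after
#'   the switch (default 1).
#' @param rho_decay_factor Multiplier on the RhoA dissociation term after the
#'   switch (default 1).
#'
#' @return An object of class `perturbation_protocol`.
#' @examples
#' # contractility inhibition: advection off, both species destabilized 2-fold
#' perturbation_protocol(t_switch = 40, pe_after = 0,
#'                       nmiia_decay_factor = 2, rho_decay_factor = 2)
#' @export
perturbation_protocol <- function(t_switch, pe_after,
                                  nmiia_decay_factor = 1,
                                  rho_decay_factor = 1) {
  stopifnot(is.numeric(t_switch), length(t_switch) == 1, t_switch >= 0)
  stopifnot(is.numeric(pe_after), length(pe_after) == 1, pe_after >= 0)
  stopifnot(nmiia_decay_factor > 0, rho_decay_factor > 0)
  structure(
    list(
      t_switch = t_switch, pe_after = pe_after,
      nmiia_decay_factor = nmiia_decay_factor,
      rho_decay_factor = rho_decay_factor
    ),
    class = "perturbation_protocol"
  )
}

#' @export
print.perturbation_protocol <- function(x, ...) {
  cat(sprintf(
    "<perturbation_protocol> at t = %g: Pe -> %g, NMIIA decay x%g, RhoA decay x%g\n",
    x$t_switch, x$pe_after, x$nmiia_decay_factor, x$rho_decay_factor
  ))
  invisible(x)
}
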