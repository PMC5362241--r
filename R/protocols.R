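#' Localized activation pulse initial condition
#'
#' A centred pulse of cortical activation on an otherwise empty cortex.  To
#' ignite the contractile state the amplitude must exceed the threshold set
#' by the saddle point of the well-mixed kinetics; sub-threshold pulses decay
#' back to the low state.
#'
#' @param grid A [grid_1d()] object.
#' @param amplitude Pulse amplitude (concentration); conventionally the
#'   high-state concentration (see [high_state()]).
#' @param half_width Half-width of the pulse in length units; must be less
#'   than half the domain.
#' @param species `"rho"` (default: RhoA activation only) or `"both"` (both
#'   species, emulating an established zone).
#' @param shape `"tophat"` (default) or `"gaussian"` (with standard
#'   deviation `half_width`).
#' @return A [cortex_state()] at `t = 0`.
#' @examples
#' g <- grid_1d(40, 400)
#' s <- make_pulse(g, amplitude = 1, half_width = 1)
#' @export
make_pulse <- function(grid, amplitude, half_width = 1,
                       species = c("rho", "both"),
                       shape = c("tophat", "gaussian")) {
  stopifnot(inherits(grid, "grid_1d"))
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0)
  species <- match.arg(species)
  shape <- match.arg(shape)
  if (half_width >= grid$length / 2) {
    stop("`half_width` must be less than half the domain length", call. = FALSE)
  }
  x0 <- grid$length / 2
  pulse <- switch(shape,
    tophat = amplitude * (abs(grid$x - x0) <= half_width),
    gaussian = amplitude * exp(-(grid$x - x0)^2 / (2 * half_width^2))
  )
  m <- if (species == "both") pulse else numeric(grid$n_cells)
  cortex_state(pulse, m, grid)
}

#' Run a time-triggered perturbation experiment
#'
#' Simulates with the base parameters up to the protocol's switch time, then
#' continues with `pe_after` and the decay-term multipliers applied, and
#' returns the stitched record spanning the switch.  With identity factors
#' and `pe_after` equal to the base Peclet number the result is identical to
#' a plain [simulate_cortex()] run.
#'
#' @inheritParams simulate_cortex
#' @param protocol A [perturbation_protocol()].  `t_switch` must be a
#'   multiple of `record_every` and less than `t_end`.
#' @return A `spacetime_record` spanning `[0, t_end]`.
#' @examples
#' \donttest{
#' g <- grid_1d(40, 400)
#' kp <- kinetic_params(alpha = 0.02)
#' mp <- mech_params(pe = 8)
#' pr <- perturbation_protocol(40, pe_after = 0,
#'                             nmiia_decay_factor = 2, rho_decay_factor = 2)
#' rec <- run_protocol(make_pulse(g, 1, species = "both"),
#'                     kp, mp, g, pr, t_end = 200)
#' }
#' @export
run_protocol <- function(init, kp, mp, grid, protocol, t_end,
                         record_every = 1, scheme = "muscl") {
  stopifnot(inherits(protocol, "perturbation_protocol"))
  if (protocol$t_switch >= t_end) {
    stop("`t_switch` must be less than `t_end`", call. = FALSE)
  }
  r <- protocol$t_switch / record_every
  if (abs(r - round(r)) > 1e-9) {
    stop("`t_switch` must be a multiple of `record_every` so the record spans the switch",
      call. = FALSE
    )
  }
  if (protocol$t_switch > init$t) {
    seg1 <- simulate_cortex(init, kp, mp, grid,
      t_end = protocol$t_switch,
      record_every = record_every, scheme = scheme
    )
    if (seg1$aborted) {
      return(seg1)
    }
    start2 <- state_at(seg1)
  } else {
    seg1 <- NULL
    start2 <- init
  }
  mp2 <- mech_params(protocol$pe_after, mp$K, mp$advection_mode)
  decay2 <- c(protocol$rho_decay_factor, protocol$nmiia_decay_factor)
  seg2 <- simulate_cortex(start2, kp, mp2, grid,
    t_end = t_end,
    record_every = record_every, scheme = scheme, decay = decay2
  )
  if (is.null(seg1)) {
    return(seg2)
  }
  # stitch, dropping seg2's duplicate first frame
  core <- list(
    times = c(seg1$times, seg2$times[-1]),
    rho_xt = rbind(seg1$rho_xt, seg2$rho_xt[-1, , drop = FALSE]),
    m_xt = rbind(seg1$m_xt, seg2$m_xt[-1, , drop = FALSE]),
    v_xt = rbind(seg1$v_xt, seg2$v_xt[-1, , drop = FALSE]),
    aborted = as.integer(seg2$aborted)
  )
  rec <- new_spacetime_record(core, grid, kp, mp, record_every, scheme,
    decay = c(1, 1)
  )
  rec$protocol <- protocol
  rec
}

#' Canonical contractility-inhibition protocol
#'
#' The inhibition experiment: after the zone is established, advection is
#' switched off (`Pe = 0`) and the cortical stability of the components is
#' reduced by a 2-fold increase of the dissociation rate, emulating ROCK
#' inhibition.  The destabilization is applied to both species: applying it
#' to NMIIA alone leaves the system bistable with the contractile state
#' dominant, so the zone would expand rather than inactivate (see the
#' methods vignette).
#'
#' @param t_switch Time of inhibitor addition.
#' @param decay_factor Fold-increase of the dissociation rates (default 2).
#' @return A [perturbation_protocol()].
#' @export
inhibition_protocol <- function(t_switch = 40, decay_factor = 2) {
  perturbation_protocol(t_switch,
    pe_after = 0,
    nmiia_decay_factor = decay_factor,
    rho_decay_factor = decay_factor
  )
}
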