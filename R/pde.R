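#' Instantaneous state of the cortical fields
#'
#' Bundles the RhoA and NMIIA concentration fields, the flow field and the
#' current time on a grid.
#'
#' @param rho,m Concentration fields at the cell centres (non-negative).
#' @param grid A [grid_1d()] object.
#' @param v Velocity field; if `NULL`, left as zero (it is recomputed from
#'   `m` at every step of the integrator anyway).
#' @param t Time stamp.
#' @return An object of class `cortex_state`.
#' @export
cortex_state <- function(rho, m, grid, v = NULL, t = 0) {
  stopifnot(inherits(grid, "grid_1d"))
  stopifnot(length(rho) == grid$n_cells, length(m) == grid$n_cells)
  if (any(rho < 0) || any(m < 0)) {
    stop("concentration fields must be non-negative", call. = FALSE)
  }
  if (is.null(v)) v <- numeric(grid$n_cells)
  structure(
    list(rho = as.numeric(rho), m = as.numeric(m), v = as.numeric(v), t = t),
    class = "cortex_state"
  )
}

#' @export
print.cortex_state <- function(x, ...) {
  cat(sprintf(
    "<cortex_state> t = %g, %d cells, max rho = %.4g, max m = %.4g\n",
    x$t, length(x$rho), max(x$rho), max(x$m)
  ))
  invisible(x)
}

scheme_code <- function(scheme) {
  switch(match.arg(scheme, c("muscl", "upwind")), muscl = 0L, upwind = 1L)
}

advect_flags <- function(mp) {
  list(
    rho = mp$advection_mode == "both",
    m = TRUE
  )
}

#' Admissible time step of the explicit scheme
#'
#' The step is limited by diffusive stability (`cfl_diff * dx^2`) and by the
#' advective CFL condition (`cfl_adv * dx / max|Pe v|` at the cell faces).
#'
#' @param s A [cortex_state()] whose velocity is current.
#' @param mp A [mech_params()] object.
#' @param grid A [grid_1d()] object.
#' @param cfl_diff,cfl_adv Safety factors.
#' @return The largest admissible `dt`.
#' @export
stable_dt <- function(s, mp, grid, cfl_diff = 0.2, cfl_adv = 0.4) {
  dt <- cfl_diff * grid$dx^2
  u <- mp$pe * (s$v[-1] + s$v[-length(s$v)]) / 2
  umax <- if (length(u)) max(abs(u)) else 0
  if (umax > 0) dt <- min(dt, cfl_adv * grid$dx / umax)
  dt
}

#' Advance the coupled fields by one time step
#'
#' One step of the operator-split scheme: (1) the flow is solved from the
#' current NMIIA field; (2) the advected species are transported by a
#' conservative limited-upwind step; (3) explicit diffusion (unit
#' coefficient for both species); (4) explicit reaction update.
#' Concentrations remain non-negative; values within round-off below zero
#' are clipped, larger negatives abort.
#'
#' @param s A [cortex_state()].
#' @param dt Time step; must satisfy [stable_dt()], otherwise an error
#'   reporting the admissible step is raised.
#' @param kp,mp,grid Kinetic parameters, mechanical parameters and grid.
#' @param scheme Advection reconstruction: `"muscl"` (second-order,
#'   minmod-limited; default) or `"upwind"` (first-order donor cell).
#' @param decay Length-2 multipliers of the RhoA and NMIIA dissociation
#'   terms (protocol support).
#' @return The advanced `cortex_state`.
#' @export
step_state <- function(s, dt, kp, mp, grid, scheme = "muscl",
                       decay = c(1, 1)) {
  stopifnot(
    inherits(s, "cortex_state"), inherits(kp, "kinetic_params"),
    inherits(mp, "mech_params"), inherits(grid, "grid_1d")
  )
  sv <- s
  sv$v <- solve_velocity(s$m, grid, mp$K)
  dt_ok <- stable_dt(sv, mp, grid)
  if (dt > dt_ok * (1 + 1e-12)) {
    stop(sprintf(
      "dt = %g violates the stability bound; admissible dt <= %g",
      dt, dt_ok
    ), call. = FALSE)
  }
  fl <- advect_flags(mp)
  out <- rad_step_cpp(
    s$rho, s$m, dt, kp$alpha, kp$kappa1, kp$kappa2, kp$n,
    mp$pe, mp$K, fl$rho, fl$m, grid$dx, grid$bc == "periodic",
    decay[1], decay[2], scheme_code(scheme)
  )
  if (out$status == 1) {
    stop("negative concentration beyond round-off: scheme failure", call. = FALSE)
  }
  if (out$status == 2) {
    stop("non-finite concentration: numerical blow-up", call. = FALSE)
  }
  cortex_state(out$rho, out$m, grid, v = out$v, t = s$t + dt)
}

new_spacetime_record <- function(core, grid, kp, mp, record_every,
                                 scheme, decay) {
  structure(
    list(
      times = as.numeric(core$times),
      rho_xt = core$rho_xt, m_xt = core$m_xt, v_xt = core$v_xt,
      x = grid$x, grid = grid, kp = kp, mp = mp,
      record_every = record_every, scheme = scheme, decay = decay,
      aborted = core$aborted != 0
    ),
    class = "spacetime_record"
  )
}

#' Simulate the reaction-advection-diffusion system
#'
#' Integrates the coupled RhoA/NMIIA fields with the cortical flow
#' recomputed quasi-statically at every step, recording frames at a fixed
#' cadence (the simulated kymograph).  The time step is chosen adaptively
#' from the diffusive and advective stability bounds.  On numerical blow-up
#' the integration aborts with a warning and the record up to the last valid
#' frame is returned (flagged `aborted`).
#'
#' @param init A [cortex_state()] initial condition (see [make_pulse()]).
#' @param kp,mp,grid Kinetic parameters, mechanical parameters and grid.
#' @param t_end Final time (the record extends to the first recorded time
#'   at or beyond `t_end`).
#' @param record_every Recording cadence in time units.
#' @param cfl_diff,cfl_adv Stability safety factors for the diffusive and
#'   advective step-size bounds (see [stable_dt()]); lower them to refine
#'   the time step.
#' @inheritParams step_state
#' @return A `spacetime_record` with fields `times`, `rho_xt`, `m_xt`,
#'   `v_xt` (frames in rows), `x`, and a full parameter echo.
#' @examples
#' \donttest{
#' g <- grid_1d(40, 400)
#' kp <- kinetic_params()
#' mp <- mech_params(pe = 12)
#' rec <- simulate_cortex(make_pulse(g, 1), kp, mp, g, t_end = 60)
#' }
#' @export
simulate_cortex <- function(init, kp, mp, grid, t_end, record_every = 1,
                            scheme = "muscl", decay = c(1, 1),
                            cfl_diff = 0.2, cfl_adv = 0.4) {
  stopifnot(
    inherits(init, "cortex_state"), inherits(kp, "kinetic_params"),
    inherits(mp, "mech_params"), inherits(grid, "grid_1d"),
    t_end > init$t, record_every > 0
  )
  fl <- advect_flags(mp)
  core <- rad_simulate_cpp(
    init$rho, init$m, init$t, kp$alpha, kp$kappa1, kp$kappa2, kp$n,
    mp$pe, mp$K, fl$rho, fl$m, grid$dx, grid$bc == "periodic",
    t_end, record_every, decay[1], decay[2], cfl_diff, cfl_adv,
    scheme_code(scheme)
  )
  rec <- new_spacetime_record(core, grid, kp, mp, record_every, scheme, decay)
  if (rec$aborted) {
    warning(sprintf(
      "numerical blow-up at t > %g; returning the last valid records",
      max(rec$times)
    ), call. = FALSE)
  }
  rec
}

#' @export
print.spacetime_record <- function(x, ...) {
  cat(sprintf(
    "<spacetime_record> %d frames, t in [%g, %g], %d cells, Pe = %g, alpha = %g%s\n",
    length(x$times), min(x$times), max(x$times), length(x$x),
    x$mp$pe, x$kp$alpha, if (x$aborted) " [ABORTED]" else ""
  ))
  invisible(x)
}

#' Extract one frame of a record as a state
#'
#' @param rec A `spacetime_record`.
#' @param frame Frame index (default: the last frame).
#' @return A [cortex_state()].
#' @export
state_at <- function(rec, frame = length(rec$times)) {
  stopifnot(inherits(rec, "spacetime_record"))
  stopifnot(frame >= 1, frame <= length(rec$times))
  cortex_state(rec$rho_xt[frame, ], rec$m_xt[frame, ], rec$grid,
    v = rec$v_xt[frame, ], t = rec$times[frame]
  )
}

#' @export
tidy.spacetime_record <- function(x, ...) {
  nf <- length(x$times)
  nx <- length(x$x)
  rho <- as.vector(t(x$rho_xt))
  m <- as.vector(t(x$m_xt))
  v <- as.vector(t(x$v_xt))
  tibble::tibble(
    time = rep(x$times, each = nx),
    x = rep(x$x, times = nf),
    rho = rho, m = m, v = v
  )
}

#' @export
glance.spacetime_record <- function(x, ...) {
  tibble::tibble(
    n_frames = length(x$times),
    t_end = max(x$times),
    n_cells = length(x$x),
    pe = x$mp$pe,
    alpha = x$kp$alpha,
    advection_mode = x$mp$advection_mode,
    scheme = x$scheme,
    aborted = x$aborted
  )
}
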