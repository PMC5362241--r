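run_and_classify <- function(kp, mp, grid, init, t_end, record_every,
                             rel_tol, window, margin, scheme) {
  rec <- simulate_cortex(init, kp, mp, grid,
    t_end = t_end,
    record_every = record_every, scheme = scheme
  )
  trace <- zone_width_series(rec)
  verdict <- detect_stationary(trace,
    rel_tol = rel_tol, window = window,
    margin = margin
  )
  speed <- if (!verdict$is_stationary) {
    tryCatch(front_speed(trace, high_state(kp), margin = margin),
      error = function(e) NA_real_
    )
  } else {
    NA_real_
  }
  list(rec = rec, trace = trace, verdict = verdict, speed = speed)
}

#' Scan the Peclet number
#'
#' Runs one full simulation plus diagnostics per Peclet value, from a
#' localized super-threshold pulse, and classifies each run as propagating,
#' stationary or censored (front reached the boundary margin).  Fully
#' deterministic given the configuration.
#'
#' @param kp A [kinetic_params()] object.
#' @param mp_template A [mech_params()] object whose `pe` is replaced by
#'   each scan value (carries `K` and the advection mode).
#' @param grid A [grid_1d()] object.
#' @param pe_values Peclet numbers to scan (non-empty).
#' @param init Initial condition; default is a centred top-hat RhoA pulse of
#'   amplitude `high_state(kp)` and half-width 1.
#' @param t_end,record_every Simulation horizon and cadence.
#' @param rel_tol,window,margin Stationarity criterion (see
#'   [detect_stationary()]).
#' @param scheme Advection scheme (see [step_state()]).
#' @return A tibble with one row per `pe`: `pe`, `verdict`,
#'   `is_stationary`, `speed`, `stationary_width`, `error` (failure message
#'   or `NA`; individual failures do not stop the scan).
#' @examples
#' \donttest{
#' tab <- pe_scan(kinetic_params(), mech_params(pe = 0), grid_1d(),
#'                pe_values = c(10, 12))
#' }
#' @export
pe_scan <- function(kp, mp_template, grid, pe_values, init = NULL,
                    t_end = 200, record_every = 1, rel_tol = 1e-3,
                    window = 20, margin = 2, scheme = "muscl") {
  stopifnot(length(pe_values) > 0)
  if (is.null(init)) {
    init <- make_pulse(grid, amplitude = high_state(kp), half_width = 1)
  }
  purrr::map_dfr(pe_values, function(pe) {
    mp <- mech_params(pe, mp_template$K, mp_template$advection_mode)
    res <- tryCatch(
      run_and_classify(
        kp, mp, grid, init, t_end, record_every,
        rel_tol, window, margin, scheme
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(
        pe = pe, verdict = NA_character_, is_stationary = NA,
        speed = NA_real_, stationary_width = NA_real_,
        error = conditionMessage(res)
      ))
    }
    tibble::tibble(
      pe = pe,
      verdict = res$verdict$verdict,
      is_stationary = res$verdict$is_stationary,
      speed = res$speed,
      stationary_width = res$verdict$stationary_width,
      error = NA_character_
    )
  })
}

classify_pe <- function(pe, kp, mp_template, grid, init, t_end, record_every,
                        rel_tol, window, margin, scheme) {
  mp <- mech_params(pe, mp_template$K, mp_template$advection_mode)
  res <- run_and_classify(
    kp, mp, grid, init, t_end, record_every,
    rel_tol, window, margin, scheme
  )
  if (res$verdict$verdict == "censored") {
    # boundary contact must not masquerade as a verdict: retry, 2x domain
    grid2 <- grid_1d(grid$length * 2, grid$n_cells * 2, grid$bc)
    init2 <- make_pulse(grid2,
      amplitude = max(init$rho), half_width = 1,
      species = if (max(init$m) > 0) "both" else "rho"
    )
    res <- run_and_classify(
      kp, mp, grid2, init2, t_end, record_every,
      rel_tol, window, margin, scheme
    )
    if (res$verdict$verdict == "censored") {
      # reached the margin of the doubled domain too: decisively propagating
      res$verdict$verdict <- "propagating"
      res$verdict$is_stationary <- FALSE
    }
  }
  res$verdict
}

#' Critical Peclet number by bisection
#'
#' Estimates the Peclet number separating the propagating-front and
#' stationary-zone regimes by bisection on the stationarity verdict.  Both
#' bracket endpoints are verified first; censored runs are re-run on a
#' doubled domain so boundary contact never decides the verdict.
#'
#' @inheritParams pe_scan
#' @param pe_lo Lower bracket (must classify as propagating).
#' @param pe_hi Upper bracket (must classify as stationary).
#' @param tol Bracket width at which bisection stops.
#' @return The critical Peclet estimate (midpoint of the final bracket),
#'   with the final bracket as attribute `bracket`.
#' @export
critical_pe <- function(kp, mp_template, grid, pe_lo, pe_hi, tol = 0.25,
                        init = NULL, t_end = 200, record_every = 1,
                        rel_tol = 1e-3, window = 20, margin = 2,
                        scheme = "muscl") {
  stopifnot(pe_lo < pe_hi, tol > 0)
  if (is.null(init)) {
    init <- make_pulse(grid, amplitude = high_state(kp), half_width = 1)
  }
  cls <- function(pe) {
    classify_pe(
      pe, kp, mp_template, grid, init, t_end, record_every,
      rel_tol, window, margin, scheme
    )
  }
  v_lo <- cls(pe_lo)
  if (v_lo$is_stationary) {
    stop(sprintf("invalid bracket: pe_lo = %g is already stationary", pe_lo),
      call. = FALSE
    )
  }
  v_hi <- cls(pe_hi)
  if (!v_hi$is_stationary) {
    stop(sprintf("invalid bracket: pe_hi = %g is not stationary", pe_hi),
      call. = FALSE
    )
  }
  while (pe_hi - pe_lo > tol) {
    mid <- (pe_lo + pe_hi) / 2
    if (cls(mid)$is_stationary) pe_hi <- mid else pe_lo <- mid
  }
  structure((pe_lo + pe_hi) / 2, bracket = c(pe_lo, pe_hi))
}

#' Stationary zone width as a function of the Peclet number
#'
#' Stationary widths where the zone pins; runs below the critical Peclet
#' number propagate indefinitely and are marked `"unbounded"`.
#'
#' @inheritParams pe_scan
#' @return A tibble with columns `pe`, `width` (`NA` where unbounded),
#'   `bounded` (`"stationary"` / `"unbounded"` / `"failed"`).
#' @export
width_vs_pe <- function(kp, mp_template, grid, pe_values, ...) {
  tab <- pe_scan(kp, mp_template, grid, pe_values, ...)
  tibble::tibble(
    pe = tab$pe,
    width = tab$stationary_width,
    bounded = dplyr::case_when(
      !is.na(tab$error) ~ "failed",
      tab$is_stationary ~ "stationary",
      .default = "unbounded"
    )
  )
}
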