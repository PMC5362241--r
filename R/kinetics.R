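#' @keywords internal
hill_term <- function(c, kappa, n) c^n / (kappa^n + c^n)

#' @keywords internal
hill_deriv <- function(c, kappa, n) {
  n * kappa^n * c^(n - 1) / (kappa^n + c^n)^2
}

#' Reaction rates of the well-mixed bistable system
#'
#' Rates of change of the cortical RhoA and NMIIA concentrations under the
#' mutual-recruitment kinetics: each species is recruited through a Hill
#' function of the other and dissociates linearly,
#' `d rho/dt = alpha * (m^n / (kappa1^n + m^n) - rho)` and symmetrically for
#' `m`.  Vectorised over `rho` and `m`.
#'
#' @param rho Cortical RhoA concentration(s), non-negative.
#' @param m Cortical NMIIA concentration(s), non-negative.
#' @param p A [kinetic_params()] object.
#' @param decay Optional length-2 numeric `c(rho, m)` multiplying the two
#'   dissociation terms (used by perturbation protocols; default `c(1, 1)`).
#'
#' @return A tibble with columns `d_rho` and `d_m`.
#' @examples
#' kp <- kinetic_params(alpha = 1, kappa1 = 0.2)
#' reaction_rates(0, 0.2, kp)  # Hill term at half-saturation: d_rho = 0.5
#' @export
reaction_rates <- function(rho, m, p, decay = c(1, 1)) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(rho < 0) || any(m < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  tibble::tibble(
    d_rho = p$alpha * (hill_term(m, p$kappa1, p$n) - decay[1] * rho),
    d_m = p$alpha * (hill_term(rho, p$kappa2, p$n) - decay[2] * m)
  )
}

#' Nullclines of the well-mixed system
#'
#' The RhoA nullcline is `rho = m^n / (kappa1^n + m^n)` and the NMIIA
#' nullcline is `m = rho^n / (kappa2^n + rho^n)`; fixed points sit at their
#' intersections.
#'
#' @inheritParams reaction_rates
#' @param max_c Upper end of the sampled concentration range.
#' @param n_points Number of samples per curve.
#' @return A tibble with columns `curve` (`"rho"` or `"m"`), `rho`, `m`.
#' @export
nullclines <- function(p, max_c = 1.5, n_points = 400) {
  stopifnot(inherits(p, "kinetic_params"))
  s <- seq(0, max_c, length.out = n_points)
  dplyr::bind_rows(
    tibble::tibble(curve = "rho", rho = hill_term(s, p$kappa1, p$n), m = s),
    tibble::tibble(curve = "m", rho = s, m = hill_term(s, p$kappa2, p$n))
  )
}

jacobian_at <- function(rho, m, p, decay = c(1, 1)) {
  matrix(
    c(
      -p$alpha * decay[1], p$alpha * hill_deriv(m, p$kappa1, p$n),
      p$alpha * hill_deriv(rho, p$kappa2, p$n), -p$alpha * decay[2]
    ),
    nrow = 2, byrow = TRUE
  )
}

classify_stability <- function(J, tol = 1e-9) {
  re <- Re(eigen(J, only.values = TRUE)$values)
  if (any(abs(re) < tol)) {
    stop("non-hyperbolic fixed point: eigenvalue real part below tolerance",
      call. = FALSE
    )
  }
  if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
}

#' Fixed points of the well-mixed system
#'
#' Locates all intersections of the two nullclines by scanning
#' `rho = H1(H2(rho))` on a dense sampling and polishing each sign change
#' with a root finder, then classifies stability from the Jacobian
#' eigenvalues.  In the bistable regime there are three fixed points: the
#' low state at the origin, a high contractile state, and a saddle whose
#' stable manifold separates the two basins.
#'
#' @inheritParams reaction_rates
#' @param max_c Upper end of the search interval for `rho`.
#' @param n_scan Number of scan points (>= 400 for robustness near the
#'   bistability boundary).
#' @param tol Root deduplication tolerance.
#'
#' @return A `fixed_point_set`: a tibble with columns `rho`, `m`,
#'   `stability`, carrying an `is_bistable` attribute.
#' @examples
#' fp <- find_fixed_points(kinetic_params(kappa1 = 0.4))
#' fp
#' attr(fp, "is_bistable")
#' @export
find_fixed_points <- function(p, max_c = 1.5, n_scan = 600,
                              tol = 1e-6, decay = c(1, 1)) {
  stopifnot(inherits(p, "kinetic_params"))
  f <- function(rho) {
    m <- hill_term(rho, p$kappa2, p$n) / decay[2]
    hill_term(m, p$kappa1, p$n) / decay[1] - rho
  }
  s <- seq(0, max_c, length.out = n_scan)
  fs <- vapply(s, f, numeric(1))
  roots <- 0 # the origin is always a fixed point
  for (i in seq_len(n_scan - 1)) {
    if (is.na(fs[i]) || is.na(fs[i + 1])) next
    if (fs[i] == 0 && s[i] > 0) {
      roots <- c(roots, s[i])
    } else if (fs[i] * fs[i + 1] < 0) {
      r <- tryCatch(
        stats::uniroot(f, c(s[i], s[i + 1]), tol = 1e-12)$root,
        error = function(e) {
          stop("fixed-point root finding failed in [", s[i], ", ", s[i + 1],
            "]: ", conditionMessage(e),
            call. = FALSE
          )
        }
      )
      roots <- c(roots, r)
    }
  }
  roots <- sort(roots)
  roots <- roots[!duplicated(round(roots / tol))]
  # deduplicate near-coincident roots
  keep <- c(TRUE, diff(roots) > tol)
  roots <- roots[keep]
  m <- hill_term(roots, p$kappa2, p$n) / decay[2]
  stability <- vapply(
    seq_along(roots),
    function(i) classify_stability(jacobian_at(roots[i], m[i], p, decay)),
    character(1)
  )
  out <- tibble::tibble(rho = roots, m = m, stability = stability)
  is_bi <- nrow(out) == 3 &&
    sum(out$stability == "stable") == 2 &&
    sum(out$stability == "saddle") == 1
  structure(out,
    is_bistable = is_bi,
    params = p, decay = decay,
    class = c("fixed_point_set", class(out))
  )
}

#' Is the well-mixed system bistable?
#'
#' `TRUE` iff the nullclines intersect three times (two stable states
#' separated by a saddle), i.e. a high contractile state coexists with the
#' low state at the origin.
#'
#' @inheritParams find_fixed_points
#' @return A logical flag.
#' @examples
#' bistability_check(kinetic_params(kappa1 = 0.4)) # TRUE
#' bistability_check(kinetic_params(kappa1 = 1.0)) # FALSE
#' @export
bistability_check <- function(p, decay = c(1, 1)) {
  attr(find_fixed_points(p, decay = decay), "is_bistable")
}

#' High-state concentration of the well-mixed system
#'
#' Convenience accessor: the RhoA concentration of the stable contractile
#' state (the largest stable fixed point).  Errors outside the bistable
#' regime.
#'
#' @inheritParams find_fixed_points
#' @return A scalar concentration.
#' @export
high_state <- function(p) {
  fp <- find_fixed_points(p)
  if (!attr(fp, "is_bistable")) {
    stop("parameters are not in the bistable regime", call. = FALSE)
  }
  max(fp$rho[fp$stability == "stable"])
}

kinetics_rhs <- function(t, y, parms) {
  p <- parms$p
  decay <- parms$decay
  list(c(
    p$alpha * (hill_term(y[2], p$kappa1, p$n) - decay[1] * y[1]),
    p$alpha * (hill_term(y[1], p$kappa2, p$n) - decay[2] * y[2])
  ))
}

#' Integrate the well-mixed kinetics
#'
#' Forward-integrates the two-variable ODE system from an initial condition,
#' using an adaptive stiff-capable solver.  Mainly used for basin-of-
#' attraction checks and phase-portrait trajectories.
#'
#' @param rho0,m0 Initial concentrations.
#' @inheritParams reaction_rates
#' @param t_end Final time.
#' @param n_out Number of output times.
#' @return A tibble with columns `time`, `rho`, `m`.
#' @export
integrate_kinetics <- function(rho0, m0, p, t_end = 50, n_out = 201,
                               decay = c(1, 1)) {
  stopifnot(inherits(p, "kinetic_params"))
  out <- deSolve::ode(
    y = c(rho0, m0), times = seq(0, t_end, length.out = n_out),
    func = kinetics_rhs, parms = list(p = p, decay = decay)
  )
  tibble::tibble(time = out[, 1], rho = out[, 2], m = out[, 3])
}

#' Separatrix of the bistable system
#'
#' Traces the stable manifold of the saddle point — the curve dividing the
#' basins of attraction of the low and high states — by integrating the
#' vector field backward in time from small displacements along the saddle's
#' stable eigenvector (offset 1e-6, both signs), with an adaptive stepper
#' that terminates when the trajectory leaves the box `[-0.1, 2]^2`.
#'
#' @inheritParams reaction_rates
#' @param arc_points Number of points returned per branch.
#' @return A tibble with columns `branch` (`"minus"`/`"plus"`), `rho`, `m`,
#'   carrying the saddle location as attribute `saddle`.
#' @examples
#' sep <- separatrix(kinetic_params(kappa1 = 0.4))
#' @export
separatrix <- function(p, arc_points = 200) {
  stopifnot(inherits(p, "kinetic_params"))
  fp <- find_fixed_points(p)
  if (!attr(fp, "is_bistable")) {
    stop("separatrix requires the bistable regime (3 fixed points)",
      call. = FALSE
    )
  }
  sad <- fp[fp$stability == "saddle", ]
  J <- jacobian_at(sad$rho, sad$m, p)
  eg <- eigen(J)
  i_stable <- which(Re(eg$values) < 0)
  ev <- Re(eg$vectors[, i_stable])
  ev <- ev / sqrt(sum(ev^2))

  back_rhs <- function(t, y, parms) {
    r <- kinetics_rhs(t, y, parms)
    list(-r[[1]])
  }
  leave_box <- function(t, y, parms) {
    c(y[1] + 0.1, 2 - y[1], y[2] + 0.1, 2 - y[2])
  }
  trace_branch <- function(sign) {
    y0 <- c(sad$rho, sad$m) + sign * 1e-6 * ev
    t_max <- 60 / p$alpha
    out <- deSolve::lsodar(
      y = y0, times = seq(0, t_max, length.out = 8 * arc_points),
      func = back_rhs, parms = list(p = p, decay = c(1, 1)),
      rootfunc = leave_box
    )
    k <- nrow(out)
    idx <- unique(round(seq(1, k, length.out = min(arc_points, k))))
    tibble::tibble(
      branch = if (sign > 0) "plus" else "minus",
      rho = out[idx, 2], m = out[idx, 3]
    )
  }
  res <- dplyr::bind_rows(trace_branch(-1), trace_branch(1))
  structure(res,
    saddle = c(rho = sad$rho, m = sad$m),
    class = c("separatrix", class(res))
  )
}

#' @export
#' @importFrom generics tidy
tidy.fixed_point_set <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rho", "m", "stability")])
}

#' @export
#' @importFrom generics glance
glance.fixed_point_set <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x),
    is_bistable = attr(x, "is_bistable"),
    rho_high = if (any(x$stability == "stable" & x$rho > 0)) {
      max(x$rho[x$stability == "stable"])
    } else {
      NA_real_
    },
    rho_saddle = if (any(x$stability == "saddle")) {
      x$rho[x$stability == "saddle"][1]
    } else {
      NA_real_
    }
  )
}

#' Export phase-portrait tables as CSV
#'
#' Writes plain CSV tables of the nullclines, the separatrix (stable
#' manifold) and the fixed points, suitable for external plotting.
#'
#' @inheritParams reaction_rates
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_phase_portrait <- function(p, dir) {
  stopifnot(inherits(p, "kinetic_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("nullclines.csv", "fixed_points.csv", "separatrix.csv"))
  utils::write.csv(nullclines(p), paths[1], row.names = FALSE)
  utils::write.csv(tidy(find_fixed_points(p)), paths[2], row.names = FALSE)
  sep <- tryCatch(separatrix(p), error = function(e) NULL)
  if (!is.null(sep)) {
    utils::write.csv(tibble::as_tibble(sep), paths[3], row.names = FALSE)
  } else {
    paths <- paths[1:2]
  }
  invisible(paths)
}
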