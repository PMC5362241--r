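# Shared fixtures: the standard parameter set used throughout the paper's
# simulations (alpha = 1, kappa = 0.2, K = 1) and small helpers.

std_kp <- function(alpha = 1) kinetic_params(alpha = alpha, kappa1 = 0.2)
std_grid <- function(length = 40, n_cells = 400) grid_1d(length, n_cells)

trapz_ref <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# diagonal fixed points of the symmetric system: positive roots of
# c^(n+1) - c^n + kappa^n * c = 0, i.e. of c^n - c^(n-1) + kappa^n = 0,
# located with the polynomial-root oracle (n = 4).
diagonal_roots <- function(kappa) {
  r <- polyroot(c(kappa^4, 0, 0, -1, 1))
  sort(Re(r[abs(Im(r)) < 1e-8 & Re(r) > 1e-12]))
}

# a zone_trace built from raw series, for diagnostics unit tests
make_trace <- function(time, width, grid = std_grid(),
                       edge_lo = NA_real_, edge_hi = NA_real_) {
  out <- tibble::tibble(
    time = time, width = width,
    edge_lo = rep_len(edge_lo, length(time)),
    edge_hi = rep_len(edge_hi, length(time))
  )
  structure(out,
    grid = grid, aborted = FALSE,
    class = c("zone_trace", class(out))
  )
}

# reference reaction-diffusion integrator (method of lines + deSolve),
# independent of the package's stepper; Pe = 0 only.
rd_reference <- function(rho0, m0, kp, grid, times) {
  n <- grid$n_cells
  rhs <- function(t, y, parms) {
    rho <- y[1:n]
    m <- y[(n + 1):(2 * n)]
    lap <- function(c) {
      cp <- c(c[-1], c[n])
      cm <- c(c[1], c[-n])
      (cp - 2 * c + cm) / grid$dx^2
    }
    h <- function(c, kap) c^kp$n / (kap^kp$n + c^kp$n)
    list(c(
      kp$alpha * (h(m, kp$kappa1) - rho) + lap(rho),
      kp$alpha * (h(rho, kp$kappa2) - m) + lap(m)
    ))
  }
  out <- deSolve::ode(
    y = c(rho0, m0), times = times, func = rhs, parms = NULL,
    method = "lsoda", rtol = 1e-8, atol = 1e-10
  )
  list(
    rho = out[nrow(out), 2:(n + 1)],
    m = out[nrow(out), (n + 2):(2 * n + 1)]
  )
}
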