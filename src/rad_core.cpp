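#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Tridiagonal (Thomas) solve for  b[i]*x[i-1] + d[i]*x[i] + a[i]*x[i+1] = r[i].
// d is overwritten; r is overwritten with the solution.
static void thomas(std::vector<double>& b, std::vector<double>& d,
                   std::vector<double>& a, std::vector<double>& r) {
  const int n = (int)d.size();
  for (int i = 1; i < n; ++i) {
    double w = b[i] / d[i - 1];
    d[i] -= w * a[i - 1];
    r[i] -= w * r[i - 1];
  }
  r[n - 1] /= d[n - 1];
  for (int i = n - 2; i >= 0; --i)
    r[i] = (r[i] - a[i] * r[i + 1]) / d[i];
}

// Solve (I - d2/dx2) v = g on n points.
// periodic: cyclic system via Sherman-Morrison.
// rigid (Dirichlet v = 0 at the walls): ghost v_0 = -v_1, v_{n+1} = -v_n
// so the wall-face value (midpoint) vanishes on the cell-centred grid.
static std::vector<double> solve_screened(const std::vector<double>& g,
                                          double dx, bool periodic) {
  const int n = (int)g.size();
  const double a = 1.0 / (dx * dx);
  std::vector<double> lo(n, -a), di(n, 1.0 + 2.0 * a), up(n, -a), r(g);
  if (!periodic) {
    di[0] = 1.0 + 3.0 * a;
    di[n - 1] = 1.0 + 3.0 * a;
    thomas(lo, di, up, r);
    return r;
  }
  // cyclic: A + u v^T with corner entries -a coupling first/last rows
  const double gamma = -di[0];
  std::vector<double> d2(di), r2(r), u(n, 0.0);
  d2[0] -= gamma;
  d2[n - 1] -= (a * a) / gamma;
  u[0] = gamma;
  u[n - 1] = -a;
  std::vector<double> lo1(lo), up1(up), d3(d2), u2(u);
  thomas(lo1, d3, up1, r2);            // y = A'^{-1} r
  std::vector<double> lo2(lo), up2(up);
  thomas(lo2, d2, up2, u2);            // z = A'^{-1} u
  double num = r2[0] - (a / gamma) * r2[n - 1];
  double den = 1.0 + u2[0] - (a / gamma) * u2[n - 1];
  double fact = num / den;
  for (int i = 0; i < n; ++i) r2[i] -= fact * u2[i];
  return r2;
}

static std::vector<double> stress_gradient(const std::vector<double>& s,
                                           double dx, bool periodic) {
  const int n = (int)s.size();
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    double sp = (i + 1 < n) ? s[i + 1] : (periodic ? s[0] : s[n - 1]);
    double sm = (i - 1 >= 0) ? s[i - 1] : (periodic ? s[n - 1] : s[0]);
    g[i] = (sp - sm) / (2.0 * dx);
  }
  return g;
}

// [[Rcpp::export]]
NumericVector velocity_from_stress_cpp(NumericVector stress, double dx,
                                       bool periodic) {
  const int n = stress.size();
  std::vector<double> s(stress.begin(), stress.end());
  std::vector<double> g = stress_gradient(s, dx, periodic);
  std::vector<double> v = solve_screened(g, dx, periodic);
  return NumericVector(v.begin(), v.end());
}

struct Pars {
  double alpha, kappa1, kappa2, pe, K, dx;
  int nhill;
  bool advect_rho, advect_m, periodic;
  double rho_decay, m_decay;
  int scheme;  // 0 = minmod-limited second-order upwind, 1 = first-order upwind
};

static inline double minmod(double a, double b) {
  if (a * b <= 0) return 0.0;
  return (std::fabs(a) < std::fabs(b)) ? a : b;
}

static inline double hill(double c, double kap, int n) {
  double cn = std::pow(c, n), kn = std::pow(kap, n);
  return cn / (kn + cn);
}

static std::vector<double> velocity(const std::vector<double>& m, const Pars& p) {
  const int n = (int)m.size();
  std::vector<double> s(n);
  for (int i = 0; i < n; ++i) s[i] = m[i] / (p.K + m[i]);
  std::vector<double> g = stress_gradient(s, p.dx, p.periodic);
  return solve_screened(g, p.dx, p.periodic);
}

// conservative upwind advection with face velocities Pe*v; the default
// reconstruction is second-order with minmod slope limiting (reduces the
// numerical diffusion that inflates near-critical zone widths), falling
// back to donor-cell values where the limiter returns zero slope.
static void advect(std::vector<double>& c, const std::vector<double>& v,
                   double dt, const Pars& p) {
  const int n = (int)c.size();
  std::vector<double> flux(n + 1, 0.0);      // flux[i] = face between i-1 and i
  auto at = [&](int i) -> double {
    if (i < 0) return p.periodic ? c[(i + n) % n] : c[0];
    if (i >= n) return p.periodic ? c[i % n] : c[n - 1];
    return c[i];
  };
  auto face_flux = [&](int il, int ir, double u) -> double {
    if (u == 0.0) return 0.0;
    int up = (u > 0) ? il : ir;
    double cu = at(up);
    if (p.scheme == 1) return u * cu;
    double sl = minmod(cu - at(up - 1), at(up + 1) - cu);
    return u * (cu + ((u > 0) ? 0.5 : -0.5) * sl);
  };
  for (int i = 1; i < n; ++i)
    flux[i] = face_flux(i - 1, i, p.pe * 0.5 * (v[i - 1] + v[i]));
  if (p.periodic) {
    flux[0] = face_flux(-1, 0, p.pe * 0.5 * (v[n - 1] + v[0]));
    flux[n] = flux[0];
  }                                           // rigid walls: zero flux
  for (int i = 0; i < n; ++i)
    c[i] -= dt / p.dx * (flux[i + 1] - flux[i]);
}

static void diffuse(std::vector<double>& c, double dt, const Pars& p) {
  const int n = (int)c.size();
  const double a = dt / (p.dx * p.dx);
  std::vector<double> old(c);
  for (int i = 0; i < n; ++i) {
    double cp = (i + 1 < n) ? old[i + 1] : (p.periodic ? old[0] : old[n - 1]);
    double cm = (i - 1 >= 0) ? old[i - 1] : (p.periodic ? old[n - 1] : old[0]);
    c[i] += a * (cp - 2.0 * old[i] + cm);
  }
}

static void react(std::vector<double>& rho, std::vector<double>& m,
                  double dt, const Pars& p) {
  const int n = (int)rho.size();
  for (int i = 0; i < n; ++i) {
    double r0 = rho[i], m0 = m[i];
    rho[i] += dt * p.alpha * (hill(m0, p.kappa1, p.nhill) - p.rho_decay * r0);
    m[i]   += dt * p.alpha * (hill(r0, p.kappa2, p.nhill) - p.m_decay * m0);
  }
}

// returns 0 ok, 1 negative beyond round-off, 2 non-finite
static int clip_check(std::vector<double>& c) {
  for (size_t i = 0; i < c.size(); ++i) {
    if (!std::isfinite(c[i])) return 2;
    if (c[i] < 0) {
      if (c[i] > -1e-12) c[i] = 0.0; else return 1;
    }
  }
  return 0;
}

static int one_step(std::vector<double>& rho, std::vector<double>& m,
                    std::vector<double>& v, double dt, const Pars& p) {
  v = velocity(m, p);
  if (p.pe > 0.0) {
    if (p.advect_rho) advect(rho, v, dt, p);
    if (p.advect_m) advect(m, v, dt, p);
  }
  diffuse(rho, dt, p);
  diffuse(m, dt, p);
  react(rho, m, dt, p);
  int cr = clip_check(rho), cm = clip_check(m);
  return cr > cm ? cr : cm;
}

// [[Rcpp::export]]
List rad_step_cpp(NumericVector rho0, NumericVector m0, double dt,
                  double alpha, double kappa1, double kappa2, int nhill,
                  double pe, double K, bool advect_rho, bool advect_m,
                  double dx, bool periodic,
                  double rho_decay, double m_decay, int scheme) {
  Pars p{alpha, kappa1, kappa2, pe, K, dx, nhill,
         advect_rho, advect_m, periodic, rho_decay, m_decay, scheme};
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> v;
  int status = one_step(rho, m, v, dt, p);
  return List::create(_["rho"] = NumericVector(rho.begin(), rho.end()),
                      _["m"] = NumericVector(m.begin(), m.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["status"] = status);
}

// [[Rcpp::export]]
List rad_simulate_cpp(NumericVector rho0, NumericVector m0, double t0,
                      double alpha, double kappa1, double kappa2, int nhill,
                      double pe, double K, bool advect_rho, bool advect_m,
                      double dx, bool periodic,
                      double t_end, double record_every,
                      double rho_decay, double m_decay,
                      double cfl_diff, double cfl_adv, int scheme) {
  Pars p{alpha, kappa1, kappa2, pe, K, dx, nhill,
         advect_rho, advect_m, periodic, rho_decay, m_decay, scheme};
  const int n = rho0.size();
  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> v = velocity(m, p);

  int nrec = (int)std::ceil((t_end - t0) / record_every - 1e-12) + 1;
  if (nrec < 1) nrec = 1;
  NumericMatrix rho_xt(nrec, n), m_xt(nrec, n), v_xt(nrec, n);
  NumericVector times(nrec);
  auto record = [&](int k, double t) {
    times[k] = t;
    for (int i = 0; i < n; ++i) {
      rho_xt(k, i) = rho[i];
      m_xt(k, i) = m[i];
      v_xt(k, i) = v[i];
    }
  };
  record(0, t0);

  const double dt_diff = cfl_diff * p.dx * p.dx;
  double t = t0;
  int aborted = 0;
  int k_done = 0;
  for (int k = 1; k < nrec; ++k) {
    double t_next = t0 + k * record_every;
    while (t < t_next - 1e-12) {
      double umax = 0.0;
      if (p.pe > 0.0 && (p.advect_rho || p.advect_m)) {
        for (int i = 0; i + 1 < n; ++i) {
          double u = std::fabs(p.pe * 0.5 * (v[i] + v[i + 1]));
          if (u > umax) umax = u;
        }
        if (p.periodic) {
          double u = std::fabs(p.pe * 0.5 * (v[n - 1] + v[0]));
          if (u > umax) umax = u;
        }
      }
      double dt = dt_diff;
      if (umax > 0.0) dt = std::min(dt, cfl_adv * p.dx / umax);
      if (t + dt > t_next) dt = t_next - t;
      int status = one_step(rho, m, v, dt, p);
      if (status != 0) { aborted = status; break; }
      t += dt;
    }
    if (aborted) break;
    record(k, t_next);
    k_done = k;
    if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }

  if (aborted) {
    // keep only the valid rows
    int keep = k_done + 1;
    NumericMatrix r2(keep, n), m2(keep, n), v2(keep, n);
    NumericVector t2(keep);
    for (int k = 0; k < keep; ++k) {
      t2[k] = times[k];
      for (int i = 0; i < n; ++i) {
        r2(k, i) = rho_xt(k, i); m2(k, i) = m_xt(k, i); v2(k, i) = v_xt(k, i);
      }
    }
    return List::create(_["times"] = t2, _["rho_xt"] = r2, _["m_xt"] = m2,
                        _["v_xt"] = v2, _["aborted"] = aborted);
  }
  return List::create(_["times"] = times, _["rho_xt"] = rho_xt,
                      _["m_xt"] = m_xt, _["v_xt"] = v_xt, _["aborted"] = 0);
}
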