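---
title: "Modeling stationary RhoA signaling zones in a contractile cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stationary RhoA signaling zones in a contractile cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(rhozone)
```

## The model

Epithelial cells maintain a sharply bounded zone of active (GTP-loaded)
RhoA at the apical zonula adherens, even though RhoA is a lipid-anchored
molecule free to diffuse in the membrane and its turnover is fast compared
with the lifetime of the zone.  `rhozone` simulates a minimal mechanochemical
explanation: a bistable RhoA--NMIIA positive feedback embedded in a
one-dimensional contractile cortex, where diffusion-driven spreading of the
active state is opposed by advective flow generated by the myosin it
recruits.

The non-dimensional equations solved by the package are

$$
\partial_t \rho + \mathrm{Pe}\,\partial_x(v\rho)
  = \alpha\!\left(\frac{m^n}{\kappa_1^n + m^n} - \rho\right)
  + \partial_x^2 \rho,
\qquad
\partial_t m + \mathrm{Pe}\,\partial_x(v m)
  = \alpha\!\left(\frac{\rho^n}{\kappa_2^n + \rho^n} - m\right)
  + \partial_x^2 m,
$$

with the cortical flow obtained at every instant from the quasi-static
force balance

$$
v = \partial_x^2 v + \partial_x\!\left(\frac{m}{K + m}\right).
$$

Here $\rho$ and $m$ are the cortical RhoA and NMIIA concentrations in units
of their saturation level $s/k$, length is in units of the hydrodynamic
screening length $\ell = \sqrt{\eta/\gamma}$, and time in units of
$\ell^2/D$.  Three non-dimensional groups control the behaviour:

* **Pe** $= \varsigma/(\gamma D)$ --- contractile advection relative to
  diffusion.  The central control parameter.
* **$\alpha$** --- the ratio of the diffusion timescale to the reaction
  timescale; it multiplies the kinetics.  We adopt
  $\alpha = (\eta/(\gamma D))\,k$ in `nondimensionalize()`: the printed
  form $\eta/(k\gamma D)$ found in some statements of the model is
  dimensionally inconsistent with the description of $\alpha$ as a time
  ratio, so the non-dimensional equations (where $\alpha$ multiplies the
  kinetics) are treated as authoritative and the formula in use is always
  reported alongside the derived value.
* **K** --- half-saturation of the active stress in $m$; the saturation
  prevents runaway self-contraction.

The kinetics alone (`kinetic_params()`, `find_fixed_points()`) are bistable
for sufficiently small $\kappa_{1,2}$: a low state at the origin coexists
with a high contractile state, separated by a saddle whose stable manifold
(`separatrix()`) is the basin boundary.  With $\kappa_1 = \kappa_2$ all
fixed points lie on the diagonal and solve
$c^{n+1} - c^n + \kappa^n c = 0$, which the test suite exploits as an
independent polynomial-root oracle.

```{r phase-portrait, fig.height = 4.5}
plot_phase_portrait(kinetic_params(kappa1 = 0.4))
```

With diffusion but no advection ($\mathrm{Pe} = 0$) a super-threshold local
pulse ignites the high state, which then invades the domain as a pair of
constant-speed bistable fronts.  With advection, myosin recruited in the
active zone generates a stress gradient at the zone edges that drives flow
*toward* the zone.  Below a critical Peclet number fronts still propagate,
only slower; above it the inward advective flux balances front propagation
and a stationary, localized zone forms --- the model's account of the stable
junctional RhoA zone.

## Defaults and the conditions they encode

All defaults mirror the conditions of the published simulations:

| Parameter | Default | Meaning |
|---|---|---|
| $\alpha$ | 1 | diffusion and reaction timescales comparable |
| $\kappa_1 = \kappa_2$ | 0.2 | deep bistable regime, high state at $\rho \approx 0.998$ |
| $n$ | 4 | Hill coefficient of the recruitment feedback |
| $K$ | 1 | stress half-saturation |
| domain | 40 $\times$ 400 cells | $dx = 0.1$: stationary widths of 1.5--3 units resolved by 15--30 cells |
| pulse | top-hat, half-width 1, amplitude $\rho^{\mathrm{high}}$ | "localized, super-threshold" |
| stationarity | rel. change $< 10^{-3}$ over 20 time units, boundary margin 2 | separates the Pe = 10 and Pe = 12 regimes cleanly |
| horizon | `t_end = 200` | transients at $\alpha = 1$ die by $t \approx 100$; twice the trailing window remains |

A zone's *width* is the trapezoidal integral of $\rho$ over the domain.
Because the high-state plateau is at $\rho \approx 0.998$ for
$\kappa = 0.2$, this integral and the geometric (half-maximum) extent agree
within a few percent for well-formed zones; the integral is adopted
throughout, with `zone_extent()` as the cross-check.

## Numerical scheme

Each step of the integrator (`simulate_cortex()`, compiled core) performs,
in order: (1) a direct tridiagonal solve of the screened-Poisson force
balance for $v$ from the current $m$; (2) conservative finite-volume
advection of the advected species with face velocities $\mathrm{Pe}\,v$;
(3) explicit diffusion; (4) an explicit reaction update evaluated on the
pre-update fields so the $\rho \leftrightarrow m$ exchange symmetry is
preserved exactly.  The time step is re-evaluated continuously as
$\min(0.2\,dx^2,\ 0.4\,dx/\max|\mathrm{Pe}\,v|)$.

Advection uses a second-order upwind reconstruction with minmod slope
limiting by default (`scheme = "muscl"`), with plain first-order donor-cell
upwind available as `scheme = "upwind"`.  The choice matters near the
depinning point and was made on measured grounds: at $dx = 0.1$ the
first-order scheme's numerical diffusion inflates near-critical stationary
widths by roughly 15--30% (Pe = 12: 4.24 vs 3.65 integral units; Pe = 30:
1.65 vs 1.49) and produces lattice-pinned states whose width depends on the
initial zone size, violating the model's property that the stationary width
is independent of whether one starts from a small or a big active zone.
With the limited scheme the Pe = 12 width is identical to four decimals
from a narrow (half-width 1) and a wide (half-width 6) initial pulse.

Boundary conditions default to rigid walls ($v = 0$) with no-flux
concentrations, which conserves total protein exactly (the advective wall
fluxes vanish and both transport steps are in flux form); periodic
boundaries are supported and used by the velocity-solver verification
against the closed form $v = q\cos(qx)/(1+q^2)$ for a $\sin(qx)$ stress.
Concentrations within $10^{-12}$ below zero are clipped; anything larger
aborts the run, distinguishing round-off from scheme failure.  Blow-up
(NaN/Inf) aborts with the record truncated at the last valid frame.

Verdicts near the regime boundary are protected from the finite domain:
a front that enters the 2-unit boundary margin yields the verdict
*censored*, never *stationary*, and the bisection in `critical_pe()`
re-runs censored cases on a doubled domain before classifying.

## Diagnostics and sweeps

`zone_width_series()` produces the width-versus-time trace (the
machine-readable twin of the published width plots); `front_speed()` fits
the late-time slope and divides by $2\rho^{\mathrm{high}}$ (two fronts,
each carrying the plateau concentration); `detect_stationary()` applies the
trailing-window criterion; `cluster_count()` counts topographically
prominent maxima, capturing the clustering instability of the advected
contractile component at intermediate Pe in the myosin-only mode, where the
NMIIA field condenses into periodic clusters behind the front while RhoA
stays unimodal.

At the default grid the package reproduces: propagation at Pe = 10 and
pinning at Pe = 12 (the critical value from bisection is $10.875$,
bracket $(10.75, 11)$); a stationary width of $1.49$ at
Pe = 30; monotone decrease of front speed with Pe and increase with
$\alpha$; a myosin-only critical Pe of $\approx 31$--$33$ with the NMIIA
profile narrower than RhoA at stationarity.  One published quantity is
*not* matched by the faithful scan protocol: scanning Pe downward with
0.25-unit refinement, stationary verdicts extend to Pe = 11 where the width
is $\approx 4.6$ integral units, exceeding the $\approx 3$ quoted for the
largest finite width.  Widths of $\approx 3$ occur 1.5--4 Pe units above
the critical point (3.65 at Pe = 12, 2.67 at Pe = 15); the published value
is consistent with a coarser scan that stops near Pe = 12 rather than with
the limit of the pinned branch, which in both schemes and at grids up to
1600 cells keeps widening as Pe approaches depinning.  We report the
faithful scan result rather than tuning the protocol toward the printed
number.

## Perturbation protocols

`run_protocol()` switches, at `t_switch`, the Peclet number and multiplies
the linear dissociation terms by per-species factors (the recruitment terms
are untouched; with identity factors the run is bit-identical to the
unperturbed one).  The canonical inhibition experiment
(`inhibition_protocol()`) models ROCK inhibition: contractility off
($\mathrm{Pe} \to 0$) plus a 2-fold increase of the dissociation rate,
applied *to both species*.

That both-species choice is deliberate and worth spelling out.  Doubling
only the NMIIA dissociation, the nominal reading of the published
perturbation, leaves the system bistable --- the effective fixed-point
structure is that of an asymmetric system with $\kappa_1' = 0.4$, retaining
a stable contractile state near $(\rho, m) = (0.975, 0.499)$ --- and the
high state remains dynamically dominant: from any consolidated zone the
post-switch front *expands* and takes over the domain instead of
inactivating (`bistability_check(kp, decay = c(1, 2))` confirms the
bistability; the acceptance suite demonstrates the takeover).  Applying the
same 2-fold destabilization to both species is equivalent, after rescaling
concentrations by 2, to the symmetric system at $\kappa = 0.4$; it is still
formally bistable, but at slow kinetics ($\alpha = 0.02$, molecular
turnover slower than diffusion) the unconfined zone spreads and dilutes
below the (raised) saddle threshold before the kinetics can re-establish a
front, producing exactly the reported biphasic response: a transient
broadening of the threshold-based width followed by complete inactivation,
with the total RhoA integral falling below 1% of its pre-switch value.
True loss of bistability would require a destabilization factor of roughly
6 on NMIIA alone.

At $\alpha = 0.02$ a RhoA-only pulse cannot ignite a zone within 40 time
units (the kinetic time is $1/\alpha = 50$), so protocol runs start from a
both-species pulse, which consolidates into a zone before the switch.

## Kymograph quantification

`quantify_kymograph()` mirrors the imaging analysis: per frame the line is
re-centred on the junction ($X = 0$), the zone is the maximal contiguous
above-background run containing $X = 0$, and width and mean intensity are
normalized to their $t = 0$ values.  The original analysis states only
"a threshold above the background"; when no background is given the package
uses the median of the lowest decile of pixels plus three of their standard
deviations, and this divergence from the (unpublished) original rule is
deliberate and documented here.  `synth_kymograph()` generates Gaussian
ridges with prescribed width/peak profiles and seeded noise; the suite
checks that a prescribed two-fold broadening is recovered within 10% at
signal-to-noise 10.  The generator emulates a single junction-orthogonal
line with stationary background statistics; it does not emulate junction
curvature, photobleaching trends, or neighbouring-structure crosstalk, so
passing recovery tests demonstrate correctness of the measurement operator,
not robustness to every imaging artefact.

`record_to_kymograph()` bridges simulation records to the same
quantification, with the junction reference at the zone centroid of the
first frame.

## Known limitations

* One spatial dimension; the published two-dimensional generalization is
  out of scope here.
* Total protein is not limiting (the cytoplasmic pool is implicit and
  inexhaustible) and decay rates are spatially uniform.
* The depinning neighbourhood is delicate: verdicts within ~0.5 Pe units
  of the critical value depend on grid and horizon more than anywhere else
  in parameter space, which is why the critical Pe is reported with its
  bracket.
* GEF/GAP regulators are folded into the feedback phenomenology, not
  modelled explicitly.
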