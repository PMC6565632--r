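---
title: "Cycle-averaged wall shear stress indicators: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-averaged wall shear stress indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowss)
```

## The problem

Blood flowing over the vessel wall exerts a tangential viscous traction,
the wall shear stress (WSS). Endothelial cells sense not just its
magnitude but its temporal pattern over the cardiac cycle: steady axial
shear is physiological, while low, oscillatory, or multidirectional shear
is associated with wall remodeling and disease, and locally very high
shear with jet impingement from a narrow feeding vessel. In pathologies
such as dissection of a collateral-fed descending aorta, the question is
whether the jets from the collateral arteries strike the wall, and whether
they wash it along the axis or around the circumference.

`hemowss` post-processes a time-resolved WSS vector field
$\mathrm{WSS}(s, t)$ on a triangulated wall surface into the standard
cycle-averaged indicators, and provides the exact pulsatile tube-flow
(Womersley) solution both as a physically valid signal generator and as a
numerical cross-check.

## The indicators

With $T$ the heartbeat period, per wall node:

* **TAWSS** $= \frac{1}{T}\int_0^T |\mathrm{WSS}(s,t)|\,dt$ — the mean
  shear magnitude (Pa).
* **OSI** $= \tfrac12\left[1 -
  \frac{|\int_0^T \mathrm{WSS}\,dt|}{\int_0^T |\mathrm{WSS}|\,dt}\right]$
  — 0 for unidirectional shear, 0.5 for purely oscillatory (zero-mean)
  shear. It is blind to direction changes perpendicular to the mean.
* **RRT** $\propto \frac{1}{(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}}$ — a
  surrogate for near-wall particle residence time. Only defined up to a
  proportionality constant; see below.
* **TransWSS** $= \frac{1}{T}\int_0^T \left|\mathrm{WSS}\cdot\left(n
  \times e_m\right)\right| dt$, with $n$ the outward wall normal and
  $e_m$ the unit cycle-mean WSS direction — the mean shear component
  transverse to the mean flow direction, capturing the
  multidirectionality OSI misses. It lies in $[0, \mathrm{TAWSS}]$.
* **OSItr** $= \mathrm{TransWSS}/\mathrm{TAWSS} \in [0,1]$ — the
  normalized transverse fraction.

Zone classification marks nodes with TAWSS strictly below 0.4 Pa as
low-shear and strictly above 5 Pa as high-shear; values exactly at a
threshold are classified normal, because the thresholds are defined with
strict inequalities. Both thresholds are arguments
(`classify_zones(tawss, low, high)`).

### Washing direction

Whether a jet "washes" the wall axially or circumferentially is reported
verbally in the clinical literature without a formula. We operationalize
it as the angle $\arccos |e_m \cdot \hat a|$ between the cycle-mean WSS
direction and the local axial direction $\hat a$, folded into
$[0^\circ, 90^\circ]$, labelling a node *circumferential* above a
threshold (default $45^\circ$, the natural midpoint; the boundary itself
is labelled axial). This is a deliberate operationalization, flagged as
such: other definitions (e.g. time-resolved instead of mean-direction
angles) are defensible.

### Numerical choices

* **Quadrature.** All cycle integrals use the trapezoidal rule with an
  explicit wrap-around segment from the last sample back to the first
  (shifted by $T$), so the periodicity of the cycle is honored and
  non-uniform sample grids are supported. On smooth non-uniform grids the
  rule converges at second order; the test suite measures the observed
  order on an exact pulsatile shear signal.
* **Degenerate nodes.** OSI is undefined where the mean shear magnitude
  vanishes, TransWSS where the mean *vector* vanishes (a perfectly
  rotating field), and RRT at the OSI $=0.5$ singularity (guard band
  $10^{-9}$). These nodes are flagged invalid (`NA`), never raised as
  errors and never written as infinities, so downstream maps stay
  renderable.
* **Tangency.** WSS is tangential by definition, but discrete CFD exports
  carry small normal residues; vectors are projected to the tangent plane
  on load (`v - (v\cdot n)n`) rather than rejected.
* **RRT constant.** The literature writes RRT as a proportionality, not
  an equality. The package default is $k = 1$ (bare reciprocal). Reported
  RRT columns in clinical tables often carry an unstated normalization;
  `calibrate_rrt_constant()` recovers $k$ from one reference row, and the
  worked example in the test suite shows that a constant calibrated on
  one tear-zone row of the reference table ($k \approx 0.0278$)
  reproduces the other rows after 3-decimal rounding — internal evidence
  that the published column is a single rescaled reciprocal.

## The Womersley module

The governing equations for incompressible Newtonian blood
($\rho = 1050\ \mathrm{kg/m^3}$, $\mu = 3.5\times10^{-3}\ \mathrm{kg/(m\,s)}$)
reduce, in a rigid straight tube with unidirectional flow, to a radial
diffusion equation in which the convective term vanishes identically and
incompressibility holds by construction. This reduction has the classical
exact solution: harmonic 0 of the pressure-gradient forcing gives the
Poiseuille profile, and each harmonic $k$ the Bessel-function profile in
$\Lambda = i^{3/2}\alpha_k$ with Womersley number
$\alpha_k = R\sqrt{k\omega\rho/\mu}$. Wall shear follows in closed form:
$G_0 R/2$ for the steady part and
$\mathrm{Re}\{G_k (R/\Lambda)\, J_1(\Lambda)/J_0(\Lambda)\, e^{ik\omega t}\}$
per harmonic. Complex arithmetic is kept throughout and the real part
taken only at output, which avoids phase bookkeeping errors. $J_0, J_1$
of complex argument are evaluated by their ascending series; on the
$135^\circ$ ray where $\Lambda$ lives the functions grow exponentially,
so the series does not suffer catastrophic cancellation at aortic scale
($\alpha \lesssim 40$).

An independent Crank–Nicolson finite-difference solver
(`fd_solver()`) marches the same reduced equation from rest — symmetry at
the axis, no-slip at the wall, one-sided second-order wall-gradient
stencil — and serves as the numerical oracle: the tests verify
second-order convergence to the Bessel form, sub-0.5% wall-shear error at
200 radial points, and wall-shear phase agreement within 0.5°.

**Transient shedding.** The start-up transient decays per cycle by
$\exp(-j_{0,1}^2\, 2\pi/\alpha^2)$, so the number of warm-up cycles needed
grows quadratically with $\alpha$. The solver defaults to 5 cycles with a
reported cycle-to-cycle periodicity residual; accuracy and convergence
tests run at $\alpha = 3$–$5$ with 8–12 cycles, where the periodic state
is genuinely reached. At full aortic scale ($R = 16$ mm,
$\alpha \approx 24.6$) hundreds of cycles would be required, which is why
the oracle comparisons are performed at moderate Womersley number — the
analytic solution itself is valid at any $\alpha$.

## Waveforms and flow bookkeeping

The inflow is represented as a truncated Fourier series of the
cross-section mean velocity (the flow-rate convention is convertible; one
had to be fixed). The built-in aortic-like template has a raised-sine
systolic pulse peaking near $T/4$, a brief dicrotic reverse dip and a low
diastolic baseline, fitted once to 12 harmonics; `synthesize_waveform()`
rescales it linearly so the cycle mean equals the target. The default
target mean velocity is the value closing the inlet Reynolds balance
$\mathrm{Re} = \rho U D/\mu = 1090$ at $D = 32$ mm, i.e.
$U \approx 0.11354$ m/s. The cycle period defaults to 0.8 s —
a normal resting heart rate, and long enough to contain the four named
analysis instants T1–T4 = 0.11, 0.22, 0.36, 0.58 s (early/mid/late
systole, early diastole).

Outlet bookkeeping interprets a "bilateral $x\%$" outflow as $x\%$ *per
vessel*: that is the only reading under which the reference split
(carotid 6.48, subclavian 18.15, mammary 8.73, descending aorta 33.28)
closes the mass balance, since
$2(6.48 + 18.15 + 8.73) + 33.28 = 100$.

## Morphometrics

Branch angles follow the clinical convention: $\alpha$ is the elevation
of the branch axis above the wall tangent plane
($90^\circ$ minus the angle to the plane normal), $\beta$ the angle to
the main-vessel reference axis; both are folded into $[0^\circ, 90^\circ]$
because published tables report them in that range and orientation signs
are not stated. The reference axis for $\beta$ is deliberately an
*input*: against a curved vessel, "centerline direction" and "vertical
axis" differ, and both conventions appear; the package takes the vector
as given rather than guessing. Hydraulic diameter is $4A/P$ on the
section polygon via the shoelace formula (bit-reproducible, no meshing
dependence); mean branch diameter averages equivalent-area diameters
$2\sqrt{A/\pi}$. Centerline frames are parallel-transported to avoid the
frame flips of a Frenet frame at inflections.

## The synthetic generator

No patient geometry ships with the package (clinical CTA data are not
public), so every pipeline input is generated with known ground truth:

* `make_tube()` — structured cylinder with exactly radial normals.
* `womersley_wss_on_tube()` — the exact pulsatile wall shear painted
  uniformly along the axis: a physically valid periodic signal.
* `prescribed_osi_field()` — inverse design: a two-sample two-phase
  series $+a\,e$, $-b\,e$ with $a = 2s(1-\theta)$, $b = 2s\theta$ yields
  OSI $= \theta$ and TAWSS $= s$ *identically* under the period-closing
  trapezoidal rule, for any target $\theta \in [0, 0.5]$ — so round-trip
  tests can demand $10^{-12}$ agreement.
* `jet_impingement_field()` — a Gaussian footprint in the tube's
  unrolled (axial, arc-length) chart, direction radiating from the
  impingement point then biased axially or circumferentially, pulsing
  with the inflow-waveform envelope normalized to unit mean. The unrolled
  chart is an exact geodesic chart on a cylinder, which avoids a general
  geodesic solver.
* `make_branched_tube()` — a tube plus a branch stub realizing requested
  $(\alpha, \beta)$ exactly. When $\beta \ge \alpha$ the reference axis
  is the tube axis itself; $\beta < \alpha$ is geometrically impossible
  against an in-plane axis, so the generator then tilts the reference
  axis out of the tangent plane — exactly the situation of a branch
  angle measured against the centerline of a *curved* main vessel. The
  stub is attached non-conformally (no boolean union); angle-recovery
  tests re-estimate the axis from the stub nodes and the normal from the
  recomputed mesh normals.

What the generator does *not* emulate: a dissected double-lumen geometry,
the real multi-collateral topology, or CFD-faithful jet physics. Passing
tests therefore demonstrate the correctness of the indicator pipeline on
physically valid and adversarially designed fields, not the fidelity of
any patient-specific simulation.

## Problem sizes used in the tests

The suite exercises tubes of 48–560 nodes with 2–64 time samples,
finite-difference grids up to 200 radial points × 2000 steps × 8–12
cycles, and 1000-series random bound checks; these sizes give observed
convergence orders stable to two decimals while keeping the full suite
fast.

## A worked example

```{r example}
tube <- make_tube(radius = 16, length = 100, n_axial = 16, n_circ = 24)
case <- womersley_case(0.016, 0.8, c(1.5, 1 + 0.5i, 0.3 - 0.2i))
series <- womersley_wss_on_tube(tube, case, n_samples = 48)
idx <- compute_wss_indices(tube, series, axial = c(0, 0, 1))
glance(idx)
```

```{r rrt}
ref <- iaa_tear_reference()
k <- calibrate_rrt_constant(ref$tawss[1], ref$osi[1], ref$rrt[1])
round(rrt(ref$tawss, ref$osi, k = k), 3)
```

## Known limitations

* The indicators are only as good as the supplied WSS field; no 3-D flow
  solver is included, and pressure-based indices are out of scope.
* Probing supports nearest-node and barycentric modes because published
  tear-zone tables do not state whether their values are point samples or
  small-area averages; the package provides both and does not guess.
* The finite-difference oracle is practical at moderate Womersley number;
  at full aortic scale use the analytic solution.
* The washing-direction metric is a declared operationalization of a
  verbal clinical description.
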