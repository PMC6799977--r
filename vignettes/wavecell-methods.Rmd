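---
title: "Mechanochemical phase-field model of cell migration modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanochemical phase-field model of cell migration modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wavecell)
```

## The model

`wavecell` simulates a two-dimensional cell whose migration is driven by
intracellular signaling waves.  Two ingredients are coupled:

**Biochemistry.** An activator `A` (phosphoinositide lipids, upstream of
actin polymerization) and an inhibitor `R` (a phosphatase such as PTEN)
react and diffuse inside the cell:

$$\partial_t A = D_A \nabla^2 A + F(A) - G(R)\,A, \qquad
  \partial_t R = D_R \nabla^2 R + (c_2 A - c_1 R)/\tau,$$

with $F(A) = [k_a A^2/(K_a^2+A^2) + b](A_t - A)$ and
$G(R) = d_1 + d_2 R$.  Because the inhibitor timescale $\tau$ (10 s) is
much slower than the activator's ($1/k_a$ = 0.1 s), the system is a
relaxation oscillator: with the reference parameters the interior fixed
point, `fixed_point()` $\approx (0.26, 3.9)$ µM, is unstable, and the
well-mixed dynamics spike fast and recover slowly
(`simulate_well_mixed()`; period $\approx 18$ s).  Spatially, the same
kinetics support traveling activator fronts with the inhibitor
accumulating in a refractory tail behind them.

**Mechanics.** The cell is represented by a phase field $\phi$ (1 inside,
0 outside; the membrane is the $\phi = 1/2$ contour) obeying a force
balance between protrusion, line tension, area conservation and
substrate friction:

$$\xi\,\partial_t\phi = \eta\,M(A)\,|\nabla\phi|
  + \gamma\!\left(\nabla^2\phi - \frac{G'(\phi)}{\epsilon^2}\right)
  - B_S\!\left(\textstyle\int\phi\,d^2r - S_0\right)|\nabla\phi|,$$

where $M(A) = A^n/(A^n + A_0^n)$ converts the local activator level into
an outward protrusive force.  The concentrations are transported with
the moving domain through the conservative form
$\partial_t(\phi A) = D_A\nabla\cdot(\phi\nabla A) + \phi\,[\ldots]$,
which automatically enforces no-flux conditions at the membrane.

Varying a single mechanical parameter, the protrusive strength $\eta$,
moves the cell through three migration modes: *oscillatory* (waves fire
but the boundary barely moves), *amoeboid-like* (waves deform the
boundary transiently, the cell wanders) and *keratocyte-like* (a single
wave is captured by the boundary and drives fast, persistent, straight
motion).

## Numerical scheme

All updates are explicit forward Euler with centered second-order
stencils on a periodic grid (reference resolution $256^2$ over
$50\times50$ µm, $\Delta t = 10^{-3}$ s).  Within each step the phase
field is advanced first; the reaction–diffusion update then uses both
$\phi^{(n)}$ and $\phi^{(n+1)}$ through the product rule
$\partial_t(\phi A) \approx \phi^{(n)}\Delta A/\Delta t +
A^{(n)}\Delta\phi/\Delta t$, and the diffusion term uses the
face-averaged flux stencil.  The reaction–diffusion system is solved
only where $\phi > \chi = \tfrac12 + \tfrac12\tanh(-3\epsilon_0/\epsilon)
\approx 0.0025$ ($\epsilon_0 = 2$ µm); concentrations are held at zero
outside (`restricted_region_threshold()`).  Configuration-time guards
reject time steps violating $D\,\Delta t/\Delta x^2 > 0.25$ or
$\gamma\,\Delta t/(\xi\,\Delta x^2) > 0.25$.

Noise enters as Wiener increments inside the $\phi$ mask.  The printed
per-cell recipe $\sqrt{\sigma\,\Delta t}\,N(0,1)$ omits the spatial
density factor implied by $\sigma$'s units (µM²/µm²/s); the default is
the density-normalized $\sqrt{\sigma\,\Delta t/(\Delta x\,\Delta y)}$,
with `literal_noise = TRUE` available for the literal recipe.  Negative
concentration excursions caused by noise are clipped to zero and
counted (`clip_count`).

The double well is fixed to $G(\phi) = 18\,\phi^2(1-\phi)^2$ — the
unique quartic for which the initialization profile
$\tfrac12[1+\tanh(3(r_0-r)/\epsilon)]$ is the exact 1D interface
equilibrium, making $\gamma$ the line tension.  (The interior must carry
$\phi = 1$; the sign of the tanh argument is chosen accordingly.)
Membrane bending is neglected.  Under tension and friction alone a disk
then shrinks at the mean-curvature-flow rate $\dot R_0 = -\gamma/(\xi
R_0)$, which the test suite verifies within 10%.

### The protrusion threshold A0

The half-activation level $A_0$ of $M(A)$ is not part of the published
parameter table.  It is calibrated here to 0.35 µM from two
requirements: the protrusive force must remain essentially off at the
resting activator level ($A^* \approx 0.26$ µM, $M \approx 0.29$), and
it must be near-saturated across the activator band of a traveling wave
(amplitude $\approx 1$–1.2 µM in the coupled simulations, $M > 0.95$).
The second requirement is what produces the reported near-saturated
boundary-averaged activation $\alpha$ and the linear speed law
$v = \alpha\,\eta/\xi$ of keratocyte-like cells; with $A_0 \gtrsim 1$ µM
the measured $\alpha$ drops to $\sim$0.2 and the speed law fails to
match its own front-band integral.  Note that for a near-equilibrium
tanh interface the front-band integral
$\int_{-\epsilon}^{\epsilon} M(A)\,\phi\,dx/(2\epsilon)$ is bounded by
$\approx 0.5$ even at full saturation; the package measures
$\alpha \approx 0.49$–0.50 on reduced grids, slightly below the
published 0.55.

## Trajectory analysis and mode classification

The center of mass is the $\phi$-weighted centroid computed through
circular means (continuous across the periodic seam) and unwrapped in
time.  After discarding a 20 s transient:

* `mean_speed()` — net displacement over elapsed time.  "Vanishing
  center-of-mass speed" is operationalized as `mean_speed < 0.02` µm/s
  (about 3% of the keratocyte speed scale; exposed as `v_threshold`).
* `trajectory_curvature()` — circumscribed-circle curvature of point
  triplets after resampling to 0.5 µm arclength, averaged along the
  path; keratocyte-like cells fall below 0.02 µm$^{-1}$.
* `angle_dispersion()` — circular standard deviation of headings taken
  every 3 s (up to 100 intervals); the keratocyte boundary is 2°.
* `classify_simulation()` labels oscillatory by the speed gate, then
  keratocyte-like versus amoeboid-like by the curvature pathway, with
  the angle pathway retained as a cross-check and disagreements flagged.

The experiment-resolution classifier (`classify_experiment()`) mirrors
the lower-cadence pipeline: headings between positions 30 s apart,
standard deviation over five consecutive pairs, keratocyte-like strictly
below 25°.  Area oscillations (`oscillation_metrics()`) follow the
three-part rule COV > 5%, relative peak-to-valley P > 19% and total
oscillating time above 40 min; peaks and valleys are local extrema of a
5-frame moving average with a 1% prominence floor, and `T_tot` is the
span of the alternating extrema — the published rule names no detector,
so this operationalization is the package's own.

## One-dimensional traveling waves

`simulate_front_1d()` integrates the same kinetics on a line.  Because
the homogeneous quiescent state is not steady (basal activation fires
the whole domain within a few seconds), naive front measurements are
contaminated; the toolkit therefore provides controlled settings:

* clamped-inhibitor fronts (`clamp_R = TRUE`) over a uniform background
  — the bistable benchmark whose speed decreases with the background
  inhibitor level;
* the cubic-reaction oracle (`simulate_cubic_front()`), checked against
  the closed form $c = \sqrt{kD/2}\,(u_1 - 2u_2 + u_3)$ within 2%;
* ring pulses (`ring_pulse_scan()`): a pulse circulating on a periodic
  ring of length $L$ is an infinite wave train of spacing $L$.  Cold
  starts seeded from the well-mixed limit cycle probe which spacings a
  freshly nucleated train survives (down to $\approx 16$ µm at
  $\tau = 20$ s); warm-started continuation (`continue = TRUE`) follows
  the stable branch to its fold near 12 µm, where the slowest stable
  front speed $c_{\min}$ is measured.  Front speeds are read from
  level-crossing trajectories at a threshold set relative to the
  late-time pulse amplitude, since marginal trains run below half of
  $A_t$.

Simulation time units are compressed for efficiency; `to_physical()`
multiplies times by 5, divides speeds by 5 and doubles $\tau$ — pure
bookkeeping, never applied inside a solver.  The diffusion–decay
estimate $\lambda \approx 2\sqrt{D\tau}$ underestimates the measured
spacing by a factor $\approx 2.5$ and is kept only as an
order-of-magnitude guide (`wavelength_estimate()`).

## Campaign drivers and problem sizes

`phase_diagram()`, `eta_ramp()`, `variation_suite()` and
`variant_run()` reproduce the study designs: the $(\eta, r)$ phase
diagram with boundaries $\eta_{c,1}$ (size-independent) and
$\eta_{c,2}$ (growing with size, saturating at large radii), the
quasi-static hysteresis ramps around the subcritical onset of motion
(default hold time 60 s per $\eta$ step, 40 s in the test suite; the
published protocol states no value.  With 1 pN steps and 40 s holds the
bistable window sits at $\eta = 3$: the upward branch is still
non-motile there while the warm-started downward branch keeps moving),
the
speed-law collapse across $\{\xi \to 2\xi_0, \gamma \to 2\gamma_0,
\tau \to \tau_0/2\}$, and the excitable ($c_2 = 30$, $\sigma = 0.1$) and
relaxed-area ($B_S = 0.1$) variants.

The package's default working resolution for analyses and tests is a
$128^2$ grid over $50\times50$ µm with $\Delta t = 2\times10^{-3}$ s —
at this resolution keratocyte speeds differ from the $256^2$ reference
by under 5% — with runs of 120–200 s of model time; extended-radius
cells use a $64\times64$ µm domain at the same spacing.  Grids coarser
than about $96^2$ under-resolve the activator band (the cell stalls)
and are used only for mechanics-only checks.  The full-resolution phase
diagram at 0.25 pN × 0.5 µm steps is a cluster-scale computation and is
not run by the test suite; the coarsened sweep checks the boundary
shape properties instead.

### Noise normalization and the phase boundaries

Two noise conventions are provided (see above).  They are not
interchangeable at reduced resolution: the density-normalized default
injects $1/\sqrt{\Delta x\,\Delta y}$ more noise per cell ($\approx
2.6\times$ at $128^2$), which over-stirs small cells and inverts the
apparent size-ordering of the polarity boundary $\eta_{c,2}(r)$.  Under
the per-cell (literal) recipe the expected ordering appears cleanly —
at 5 pN a 5 µm cell is already persistent while an 8 µm cell still
wanders — so the boundary-ordering and excitable-variant checks in the
test suite use `literal_noise = TRUE`, and the vignette treats the
boundary ordering as established only under that recipe.

A second scale mismatch worth knowing about: relaxed-area model cells
oscillate in area with a period of roughly 1.5 physical minutes, faster
than the ~6 min periods of the experimental cells the three-part
oscillation rule was designed for.  The 5-frame moving average inside
the peak detector averages such fast rhythms away, so model cells pass
the windowed COV gate (> 5% at $\eta = 3.5$) but not the full
COV/P/T$_{tot}$ rule at experimental cadence.

## What the synthetic conditions do and do not show

All inputs are generated in code: disk initial conditions (A = R = 0
with dynamical noise, or the asymmetric half-disk excitation used for
bifurcation ramps), synthetic trajectories for classifier oracles, and
1D profiles.  The model emulates wave-driven motility of an idealized
flat cell; it contains no cytosolic flow, no membrane bending, no 3D
shape, no chemotactic input and no cell-to-cell variability.  Passing
tests therefore demonstrate internal consistency of the
model-and-estimator pipeline and agreement with the published emergent
quantities — not that any particular real cell obeys the model.  The
experiment-resolution classifier is exercised on synthetic tracks with
known ground truth only.

## Known limitations

* The boundary-averaged activation $\alpha$ saturates near 0.5 under the
  $\phi = 1/2$-centered band convention (see above); the published 0.55
  presumably reflects a slightly different convention or interface
  distortion at their resolution.
* Mode labels near phase boundaries depend on the realization of the
  noise; the drivers majority-vote across seeds, but individual cells
  within a step of a boundary can flip.
* The quiescent state of the oscillator variant is globally unstable, so
  free-running 1D wave trains never settle from noise alone on
  accessible timescales; wavelength statements are tied to the seeded
  train protocol described above.
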