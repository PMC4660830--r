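---
title: "Resonant vitreous motion in a rotating sphere: model, synthetic PIV and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resonant vitreous motion in a rotating sphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitreflow)
```

## The physical model and its assumptions

`vitreflow` models the vitreous chamber as a rigid sphere of radius $R$
filled with an incompressible linear viscoelastic fluid of density
$\rho$ and complex modulus $G^*(\omega) = G'(\omega) + iG''(\omega)$.
The sphere rotates about a diameter with angular displacement
$\varepsilon(t^*) = A\sin(\omega t^*)$ — the simplest idealization of a
train of back-and-forth saccades of given amplitude and duration. The
assumptions inherited from this idealization are:

* **Small amplitude.** The governing equations are linearized in $A$;
  nonlinear corrections to the azimuthal velocity enter only at third
  order in the strain, so for amplitudes of a few degrees the periodic
  flow is a single harmonic at the forcing frequency.
* **Linear rheology.** $G^*$ depends on frequency but not on strain
  amplitude or shear rate. Real vitreous (and agar/hyaluronic-acid
  surrogates) are shear-thinning at larger strains; this spatial and
  temporal modulation of the modulus is the main physics the model
  omits, and it matters most near resonance, where strain is largest.
* **Spherical chamber, periodic regime.** The real vitreous chamber is
  mildly aspherical (most notably the lens indentation), and the
  transient spin-up from rest is not described — only the
  periodic-in-time limit cycle.

Scaling velocity with the peak wall speed $A\omega R$, lengths with $R$
and time with $1/\omega$, the azimuthal velocity on the equatorial
plane (where the polar-angle factor is unity) is

$$V_\theta(r, t) = g(r)\,e^{it} + \mathrm{c.c.}, \qquad
  g(r) = \frac{j_1(kr)}{2\,j_1(k)}, \qquad
  k^2 = \frac{\rho\,\omega^2 R^2}{G^*(\omega)},$$

with $j_1$ the spherical Bessel function of order one. The factor $1/2$
makes the wall move as $\cos t$ ($2|g(1)| = 1$, no slip), and
$g(0) = 0$ by regularity. The complex wavenumber $k$ generalizes the
Womersley number: $|k|$ measures how deeply the oscillatory shear wave
penetrates, and $\arg k$ encodes the viscous/elastic balance. For a
Newtonian fluid $G^* = i\omega\mu$ and $k = \sqrt{\rho\omega
R^2/\mu}\,e^{-i\pi/4}$; for a purely elastic fluid $k$ is real and
$j_1(k)$ can vanish — the undamped resonances

$$\omega_n = \lambda_n\sqrt{G'/\rho}\,/R,$$

where $\lambda_n$ are the positive roots of $j_1$ ($\lambda_1 \approx
4.4934$). Any nonzero loss modulus keeps $j_1(k)$ away from zero and
turns these into finite-amplitude damped resonance peaks; the package
raises a near-singular error (advising a nonzero $G''$) if $|j_1(k)| <
10^{-14}$.

Two scalar summaries are used throughout:

* the **normalized time-averaged kinetic energy**
  $\bar K = 16\int_0^1 |g|^2 r\,dr$, i.e. the time average of the
  planar kinetic-energy integral
  $K(t) = \int_0^{2\pi}\!\!\int_0^1 \frac{1}{2}(v_r^2 +
  v_\theta^2)\,r\,dr\,d\theta$ divided by the rigid-body value $\pi/8$.
  A rigid body gives exactly 1, purely viscous fluids stay strictly
  below 1, and $\bar K > 1$ diagnoses resonant amplification. (The
  normalization is defined by that rigid-body quotient; a prefactor
  $8/\pi$ applied to the *integral* of $K$ over a period, rather than
  its average, would inflate the rigid-body value by $2\pi$.)
* the **maximum shear strain**
  $\gamma_{\max}(r) = A\,|g'(r) - g(r)/r|$, the temporal peak of the
  off-diagonal strain $\gamma_{r\theta} = -\frac{iA}{2}(g' - g/r)
  e^{it} + \mathrm{c.c.}$; rigid rotation shears nothing and the
  $r \to 0$ limit replaces $g/r$ by $g'(0)$.

## Rheology containers

Fluids are constant-modulus, Newtonian ($G^* = i\omega\mu$, exposed as
a named constructor so the purely viscous limit is testable), or
tabulated against angular frequency. Tabulated moduli are interpolated
linearly in $\log\omega$ — rheometer sweeps are customarily log-spaced
— and never extrapolated: queries outside the table raise a range
error naming the admissible interval. The default density is
1000 kg/m³ (the vitreous is ~99 % water); every angular frequency in
the package is rad/s and every amplitude rad, with explicit
`deg`/`hz` unit fields converted exactly on input, because published
experiment tables are notoriously ambiguous about these units.

## What the synthetic generator emulates — and what it does not

`generate_ensemble()` reproduces the *sampling structure* of a
phase-locked PIV experiment on the equatorial plane:

* a regular Cartesian grid (default 64 samples across the diameter,
  comparable to PIV interrogation-window counts at megapixel camera
  resolution) clipped to the disc;
* 20–50 phases per period (default 32; 24 in the quick examples) and
  ~40 ensemble repeats per phase;
* i.i.d. per-component Gaussian noise with standard deviation
  `noise_rel` × (spatial mean speed of that phase's noise-free field),
  default 5 % — the simplest model consistent with reporting a single
  aggregate ensemble-scatter figure. Whether real PIV noise is additive
  or proportional to the *local* speed is not knowable from such a
  figure; the spatial-mean reference was chosen once and kept;
* an optional masked sector (default 15° on the $+x$ side) mimicking
  laser-entry reflections.

The noise-free field is the closed-form solution itself, so the
generator cannot probe model error: passing end-to-end tests
demonstrates that the *pipeline* is faithful (interpolation, averaging,
fitting and quadrature do not distort the signal), not that the model
describes any particular real fluid. Phenomena absent from the
generator include correlated noise between neighbouring vectors,
peak-locking, out-of-plane loss of particles, wall reflections beyond a
clean sector, and drift of fluid properties between repeats.

Every stochastic path is seeded explicitly; the same seed reproduces
ensembles bit for bit, and generation restores the caller's RNG state.

## Pipeline numerics

**Polar interpolation.** Mean frames are interpolated bilinearly onto a
polar grid (default 64 radii × 96 azimuths, $r_i = i/64$) and rotated
into $(v_r, v_\theta)/(A\omega R)$. Nodes whose enclosing Cartesian
cell touches a masked sample are masked, never extrapolated. A
geometric consequence: every cell containing a point of the bounding
circle has a corner outside it, so the ring at exactly $r = 1$ is
unmeasurable — as in real PIV, where wall vectors are unreliable. The
pipeline therefore reports the outermost radius as missing rather than
guessing it.

**Coverage accounting.** The kinetic-energy quadrature requires 90 %
unmasked coverage, measured relative to the *interpolable support*
(the nodes that could be measured at all given the disc geometry):
artifact sectors and dropouts count against the threshold, the
unavoidable wall ring does not. Measuring against the full disc instead
would let the geometric deficit (~6 % at 64-sample resolution,
$r$-weighted) eat most of the artifact budget and reject valid runs
with a standard 15° sector.

**Imputation.** Masked nodes are filled with the azimuthal mean of the
unmasked nodes at the same radius before quadrature (the integrand is
axisymmetric to leading order, so this is unbiased); a fully masked
ring borrows the nearest measured radius. For the rigid-body case this
approximation changes $\bar K$ by ~0.1 %. The alternative —
renormalizing the azimuthal measure per ring — differs by less than
0.5 % at the default artifact size and was not implemented.

**Quadrature.** Radial integrals use composite Simpson on uniform
odd-length grids and trapezoid otherwise. Simpson matters for one
stated property: the rigid-body integrand $r^3$ is integrated exactly,
so $\bar K$ of a rigid body is exactly 1 and the purely viscous bound
$\bar K < 1$ holds *numerically*, not just analytically (trapezoid's
$O(h^2)$ overshoot on a convex integrand would push near-rigid
Newtonian sweeps to $1 + 3\cdot10^{-5}$). The azimuthal and temporal
means use the periodic trapezoid rule, which is spectrally accurate on
uniform phase grids — exact for the $\cos^2$ energy signal of the
first harmonic.

**Harmonic fit.** At each radius, ordinary least squares of
$V_\theta(r, t) \approx a\cos t + b\sin t$ over the sampled phases
(uniform weights; phases need not be uniform), $g = (a - ib)/2$. The
pooled residual fraction (RSS/TSS) measures higher harmonics plus
noise; for linear-model synthetic data it is at rounding level, and a
value above 5 % in a report flags either strong nonlinearity or a
corrupted ensemble.

**Differentiation.** Strain uses a 3-point Lagrange derivative —
second-order central stencils inside and second-order one-sided ones at
the ends (first-order end formulas would already cost ~1 % at the wall
on a 256-point grid, where $|g''| \sim |k|^2|g|$). Because
differentiation amplifies measurement noise, `max_strain()` offers
optional boxcar pre-smoothing of $g$ (width 3; off by default so that
clean data are never biased).

**Resonance scans.** $\bar K(\omega)$ is computed either from the
closed form (theoretical mode) or by running the full
generate–average–polar–energy chain per frequency (synthetic mode). The
resonant frequency is the argmax; theoretical mode refines it with a
3-point parabolic interpolation around the discrete peak
(the refinement is skipped in synthetic mode, where noise makes
sub-grid refinement spurious, and at sweep boundaries, which are
flagged `peak_at_boundary` — the situation where every tested frequency
is below resonance and only the rising branch is visible). For
dispersive (tabulated) fluids the wavenumber uses $G^*$ at each forcing
frequency being scanned; the elastic estimate $\omega_n$ then needs a
stated reference frequency for $G'$, and for loss factors up to 0.2 it
agrees with the damped peak to a few percent.

**Branch choice.** $k$ takes the square root with $\operatorname{Re} k
> 0$. Nothing depends on it: $j_1$ is odd, so $g$ is even in $k$ — a
property asserted by a test rather than assumed.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| chamber radius $R$ | 0.0125 m | human vitreous chamber scale |
| density $\rho$ | 1000 kg/m³ | vitreous is ~99 % water |
| amplitude $A$ | 0.035 rad (2°) | small-amplitude regime of typical experiments (presets 0.035/0.14 rad) |
| phases / period | 32 | inside the 20–50 phase-locked sampling window |
| repeats | 40 | typical PIV ensemble size |
| `noise_rel` | 0.05 | reported ensemble scatter ceiling |
| polar grid | 64 × 96 | matches 64-sample Cartesian resolution |
| root/bisection tolerance | $10^{-10}$ relative | far below any physical uncertainty |
| $j_1$ series switch | $|z| < 10^{-2}$ | series and closed form agree to $10^{-12}$ on the overlap annulus |

Test and example problem sizes (64–128 sample grids, 24 phases, 2–40
repeats, 5–41 frequency sweeps) were chosen as the smallest sizes at
which the quadrature and interpolation tolerances above are comfortably
met; results are insensitive to moderate refinement.

## Worked check

```{r resonance, eval = FALSE}
fluid <- viscoelastic_fluid(10, 2)          # loss factor 0.2
chamber <- chamber_spec()
natural_frequencies(fluid, chamber, 1)      # elastic estimate
scan <- resonance_scan(fluid, chamber,
                       omega_list = seq(20, 60, length.out = 41))
scan$omega_res                              # damped peak, ~0.5% above
```

## Known limitations

* The model is linear in both amplitude and rheology; near resonance,
  where strains are largest, shear-rate dependence of $G^*$ in real
  gels will blunt the predicted peaks.
* Only the equatorial plane is represented; the full spherical-harmonic
  structure off that plane (the $\sin\theta_{\text{polar}}$ factor) is
  out of scope, as are retinal wall stresses, which require a wall
  model and $G^*$ times the strain.
* The outermost radius is reported as unmeasured; studies needing wall
  gradients must extrapolate externally and deliberately.
* The generator's noise model is the simplest consistent with an
  aggregate scatter figure; pipelines tuned on it may be optimistic
  about structured PIV error.
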