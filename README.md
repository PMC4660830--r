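# vitreflow

Oscillatory flow of a viscoelastic fluid in a periodically rotating
sphere, with PIV-style post-processing — a computational model of
vitreous humour motion during eye rotations.

## The problem

During saccadic eye rotations the vitreous humour moves relative to the
eye globe. The resulting shear stresses on the retina and within the gel
have been implicated in vitreous liquefaction and posterior vitreous
detachment. Because the vitreous is viscoelastic, the fluid-filled
chamber behaves as a damped oscillator: near certain *natural
frequencies* the interior fluid velocity can resonantly exceed the wall
velocity, amplifying the mechanical load. Those frequencies fall inside
the range spanned by ordinary saccades (a saccade of duration *D*
corresponds to an angular frequency ω = π/D), which makes the question
clinically relevant — both for understanding retinal pathology and for
the design of vitreous substitute fluids, where too little damping
invites resonance.

`vitreflow` is aimed at researchers in ocular biomechanics and
biofluid dynamics who want to explore this system quantitatively: it
couples the closed-form linear-viscoelastic solution for the flow in a
sinusoidally rotating rigid sphere with a synthetic generator of
particle-image-velocimetry (PIV) style measurements and the standard
post-processing chain used on such measurements.

## The model

A rigid sphere of radius *R* filled with fluid of density ρ and complex
modulus *G*\*(ω) = *G*′ + i*G*″ rotates about a diameter with angle
ε(t\*) = *A* sin(ω t\*). Scaling velocity by the peak wall speed *AωR*
and time by 1/ω, the small-amplitude azimuthal velocity on the
equatorial plane is a single harmonic

    V_θ(r, t) = g(r) e^{it} + c.c.,   g(r) = j₁(k r) / (2 j₁(k)),
    k² = ρ ω² R² / G*(ω),

with j₁ the spherical Bessel function of order one. The wall moves as
cos *t* (2|g(1)| = 1), and as k → 0 the fluid rotates rigidly
(g = r/2). Derived statistics:

- **Normalized kinetic energy** K̄ = 16 ∫₀¹ |g|² r dr — the
  time-averaged planar kinetic energy divided by the rigid-body value;
  K̄ < 1 for purely viscous fluids, K̄ > 1 signals resonance.
- **Natural frequencies** ωₙ = λₙ √(G′/ρ)/R, with λₙ the positive
  roots of j₁ (λ₁ ≈ 4.4934).
- **Maximum shear strain** γ_max(r) = A |g′(r) − g(r)/r|, the peak over
  time of the off-diagonal strain γ_rθ.

The synthetic generator emits phase-locked ensembles of planar vector
fields (20–50 phases per period, ~40 repeats, per-component Gaussian
noise referenced to the spatial mean speed, optional masked sector
mimicking laser-entry reflections), and the pipeline recovers g(r), K̄
and γ_max(r) from them: ensemble averaging → bilinear interpolation
onto polar coordinates and nondimensionalization → azimuthal averaging
→ least-squares first-harmonic fit → quadrature of the kinetic-energy
integral.

## Worked example

```r
library(vitreflow)

# an artificial vitreous: G' = 10 Pa, G'' = 2 Pa (loss factor 0.2),
# in a human-scale chamber (R = 1.25 cm)
fluid   <- viscoelastic_fluid(g_prime = 10, g_loss = 2, name = "s-ref")
chamber <- chamber_spec(0.0125)

natural_frequencies(fluid, chamber, n = 1)
#> [1] 35.94728
saccade_equivalent_frequency(0.1)   # a 100 ms saccade
#> [1] 31.41593

scan <- resonance_scan(fluid, chamber,
                       omega_list = seq(20, 60, length.out = 41))
scan
#> <resonance_scan mode=theoretical> 41 frequencies in [20, 60] rad/s
#>   omega_res = 36.1095 rad/s (kbar max = 19.3808)

k    <- complex_wavenumber(fluid, scan$omega_res, chamber)
prof <- amplitude_profile(k)
max(2 * Mod(prof$g))   # peak interior speed, wall speed = 1
#> [1] 4.434302

# synthetic PIV experiment at resonance, analyzed end to end
protocol <- rotation_protocol(amplitude = 0.035, omega = scan$omega_res)
ens <- generate_ensemble(fluid, protocol, chamber,
                         n_phases = 24, n_repeats = 40,
                         noise_rel = 0.05, seed = 1)
res <- analyze_ensemble(ens)
res$kbar
#> [1] 19.35387
res$residual_fraction
#> [1] 6.4864e-07
max(res$strain$gamma_max)
#> [1] 0.2470311
```

Reading: the elastic estimate puts the first natural frequency at
36 rad/s, within the frequency range of real saccades; the damped K̄
peak sits 0.5 % above it. At resonance the interior fluid moves 4.4
times faster than the wall, and the full noisy pipeline recovers the
theoretical K̄ ≈ 19.4 to 0.1 % with a negligible higher-harmonic
residual. The peak dimensionless shear strain of ≈ 0.25 (for a 2°
rotation amplitude) concentrates in the outer half of the radius.

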