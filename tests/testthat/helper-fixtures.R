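# shared fixtures: the low-loss reference fluid (loss factor 0.2), the
# human-scale chamber, and independent oracles used across test files

ref_fluid <- function() viscoelastic_fluid(g_prime = 10, g_loss = 2,
                                           density = 1000, name = "ref")
ref_chamber <- function() chamber_spec(0.0125)

# independent root oracle for the first positive zero of j1: base-R
# uniroot on the closed form, bracketed in (4, 5)
lambda1_oracle <- function() {
  uniroot(function(x) sin(x) / x^2 - cos(x) / x, c(4, 5),
          tol = .Machine$double.eps)$root
}

# direct (non-package) evaluation of j1 for cross-checks
j1_direct <- function(z) sin(z) / z^2 - cos(z) / z

# linear interpolation of a complex profile onto new radii
interp_profile <- function(profile, r_new) {
  complex(real = approx(profile$r, Re(profile$g), xout = r_new)$y,
          imaginary = approx(profile$r, Im(profile$g), xout = r_new)$y)
}
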