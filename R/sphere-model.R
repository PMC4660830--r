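#' Spherical chamber geometry
#'
#' @param radius internal radius of the spherical chamber \[m\]. The
#'   default, 1.25 cm, is the size of the human vitreous chamber.
#' @return object of class \code{chamber_spec}.
#' @export
chamber_spec <- function(radius = 0.0125) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    vf_stop("vf_domain_error", "chamber radius must be a positive number (m)")
  structure(list(radius = radius), class = "chamber_spec")
}

#' Sinusoidal rotation protocol
#'
#' The chamber rotates about a diameter with angular displacement
#' \eqn{\epsilon(t^*) = A \sin(\omega t^*)}: amplitude \eqn{A} \[rad\] and
#' angular frequency \eqn{\omega} \[rad/s\]. A sinusoid is the simplest
#' stand-in for a train of back-and-forth saccades of prescribed amplitude
#' and duration. Amplitudes may be given in degrees and frequencies in Hz;
#' they are converted to rad and rad/s on construction.
#'
#' @param amplitude rotation amplitude, in \code{amplitude_unit}.
#' @param omega angular frequency, in \code{omega_unit}.
#' @param amplitude_unit \code{"rad"} (default) or \code{"deg"}.
#' @param omega_unit \code{"rad_s"} (default) or \code{"hz"}.
#' @return object of class \code{rotation_protocol} with fields
#'   \code{amplitude} \[rad\] and \code{omega} \[rad/s\].
#' @examples
#' rotation_protocol(0.035, 10 * pi)
#' rotation_protocol(2, 5, amplitude_unit = "deg", omega_unit = "hz")
#' @export
rotation_protocol <- function(amplitude, omega, amplitude_unit = "rad",
                              omega_unit = "rad_s") {
  amplitude_unit <- match.arg(amplitude_unit, c("rad", "deg"))
  omega_unit <- match.arg(omega_unit, c("rad_s", "hz"))
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude <= 0)
    vf_stop("vf_domain_error", "rotation amplitude must be positive")
  if (amplitude_unit == "deg") amplitude <- amplitude * pi / 180
  omega <- check_omega(omega)
  if (length(omega) != 1L)
    vf_stop("vf_domain_error", "omega must be a scalar")
  if (omega_unit == "hz") omega <- omega * 2 * pi
  structure(list(amplitude = amplitude, omega = omega),
            class = "rotation_protocol")
}

#' Spherical Bessel function of the first kind, order one
#'
#' Evaluates \eqn{j_1(z) = \sin(z)/z^2 - \cos(z)/z} for real or complex
#' arguments. Near the origin (\eqn{|z| < 10^{-2}}) the closed form loses
#' digits to cancellation, so the truncated power series
#' \eqn{z/3 - z^3/30 + z^5/840} is used instead; \eqn{j_1(0) = 0} exactly.
#'
#' @param z finite numeric or complex vector.
#' @return complex vector of the same length.
#' @export
spherical_j1 <- function(z) {
  if (length(z) == 0L) return(complex(0))
  z <- as.complex(z)
  if (any(!is.finite(z)))
    vf_stop("vf_domain_error", "spherical_j1 requires finite arguments")
  out <- z  # placeholder, overwritten below
  small <- abs(z) < 1e-2
  if (any(small)) {
    zs <- z[small]
    out[small] <- zs / 3 - zs^3 / 30 + zs^5 / 840
  }
  if (any(!small)) {
    zl <- z[!small]
    out[!small] <- sin(zl) / zl^2 - cos(zl) / zl
  }
  out
}

# derivative j1'(z) = j0(z) - 2 j1(z) / z, with the z -> 0 limit 1/3
spherical_j1_deriv <- function(z) {
  z <- as.complex(z)
  out <- z
  small <- abs(z) < 1e-2
  if (any(small)) {
    zs <- z[small]
    out[small] <- 1 / 3 - zs^2 / 10 + zs^4 / 168
  }
  if (any(!small)) {
    zl <- z[!small]
    out[!small] <- sin(zl) / zl - 2 * spherical_j1(zl) / zl
  }
  out
}

# first n positive roots of j1, by sign-change scan and bisection to a
# relative tolerance of 1e-10; lambda_1 = 4.4934...
besselj1_roots <- function(n, rel_tol = 1e-10) {
  stopifnot(n >= 1L)
  f <- function(x) Re(spherical_j1(x))
  roots <- numeric(0)
  xs <- seq(0.5, (n + 2) * pi, by = 0.25)
  fs <- f(xs)
  for (i in seq_len(length(xs) - 1L)) {
    if (length(roots) >= n) break
    if (fs[i] == 0) { roots <- c(roots, xs[i]); next }
    if (fs[i] * fs[i + 1L] < 0) {
      a <- xs[i]; b <- xs[i + 1L]; fa <- fs[i]
      while ((b - a) > rel_tol * b) {
        m <- (a + b) / 2; fm <- f(m)
        if (fm == 0) { a <- m; b <- m; break }
        if (fa * fm < 0) b <- m else { a <- m; fa <- fm }
      }
      roots <- c(roots, (a + b) / 2)
    }
  }
  if (length(roots) < n)
    vf_stop("vf_domain_error", "failed to bracket %d roots of j1", n)
  roots[seq_len(n)]
}

#' Complex dimensionless wavenumber of the oscillatory sphere flow
#'
#' The small-amplitude azimuthal flow of a linear viscoelastic fluid in a
#' sinusoidally rotating sphere is governed by the complex wavenumber
#' \eqn{k} with \eqn{k^2 = \rho \omega^2 R^2 / G^*(\omega)}: the ratio of
#' inertial to viscoelastic stresses (a viscoelastic generalization of the
#' square of the Womersley number). The square root branch with
#' \eqn{Re(k) > 0} is taken; for purely real positive \eqn{k^2} this is
#' the positive real root. The flow itself is invariant under
#' \eqn{k \to -k} because \eqn{j_1} is odd.
#'
#' @inheritParams complex_modulus
#' @param chamber a [chamber_spec()].
#' @return complex scalar (or vector along \code{omega}).
#' @export
complex_wavenumber <- function(fluid, omega, chamber = chamber_spec()) {
  stopifnot(inherits(chamber, "chamber_spec"))
  omega <- check_omega(omega)
  g <- complex_modulus(fluid, omega)
  if (any(abs(g) == 0))
    vf_stop("vf_degenerate_error", "G*(omega) = 0: wavenumber undefined")
  k2 <- fluid$density * omega^2 * chamber$radius^2 / g
  k <- sqrt(k2)  # principal branch: Re >= 0
  flip <- Re(k) < 0 | (Re(k) == 0 & Im(k) < 0)
  k[flip] <- -k[flip]
  k
}

#' Closed-form first-harmonic amplitude profile of the azimuthal velocity
#'
#' On the equatorial plane the dimensionless azimuthal velocity of the
#' periodic flow is a single harmonic,
#' \deqn{V_\theta(r, t) = g(r) e^{it} + c.c.,}
#' with the complex amplitude
#' \deqn{g(r) = \frac{j_1(k r)}{2\, j_1(k)},}
#' where \eqn{k} is the complex wavenumber of [complex_wavenumber()].
#' Velocities are scaled by the peak wall speed \eqn{A\omega R} and time
#' by \eqn{1/\omega}, so the wall moves as \eqn{V_\theta(1, t) = \cos t}:
#' \eqn{2|g(1)| = 1} (no slip) and \eqn{g(0) = 0}. As \eqn{k \to 0}
#' (low frequency or large modulus) \eqn{g \to r/2}, rigid-body rotation.
#'
#' @param k complex wavenumber (scalar).
#' @param r_grid increasing radial grid in \[0, 1\] (dimensionless).
#' @return object of class \code{harmonic_profile}: list with fields
#'   \code{r} and complex \code{g}.
#' @export
amplitude_profile <- function(k, r_grid = seq(0, 1, length.out = 257)) {
  if (length(k) != 1L || !is.finite(k))
    vf_stop("vf_domain_error", "k must be a finite scalar wavenumber")
  r_grid <- as.numeric(r_grid)
  if (any(!is.finite(r_grid)) || any(r_grid < 0) || any(r_grid > 1) ||
      any(diff(r_grid) <= 0))
    vf_stop("vf_domain_error",
            "r_grid must be strictly increasing within [0, 1]")
  jk <- spherical_j1(k)
  if (abs(jk) < 1e-14)
    vf_stop("vf_degenerate_error",
            paste("j1(k) is numerically zero (undamped resonance);",
                  "use a fluid with a nonzero loss modulus"))
  g <- spherical_j1(k * r_grid) / (2 * jk)
  harmonic_profile(r_grid, g)
}

#' Construct a harmonic amplitude profile
#'
#' Container for a complex first-harmonic amplitude \eqn{g(r)} on a radial
#' grid; the reconstructed velocity is \eqn{V_\theta = g e^{it} + c.c.}
#' Radii where \eqn{g} could not be measured may be \code{NA}.
#'
#' @param r increasing radial grid in \[0, 1\].
#' @param g complex amplitudes, same length as \code{r}.
#' @return object of class \code{harmonic_profile}.
#' @export
harmonic_profile <- function(r, g) {
  r <- as.numeric(r)
  if (length(r) != length(g))
    vf_stop("vf_domain_error", "r and g must have equal length")
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1) || any(diff(r) <= 0))
    vf_stop("vf_domain_error", "r must be strictly increasing within [0, 1]")
  structure(list(r = r, g = as.complex(g)), class = "harmonic_profile")
}

#' @export
print.harmonic_profile <- function(x, ...) {
  ok <- is.finite(x$g)
  cat(sprintf(
    "<harmonic_profile> %d radii in [%g, %g]; max 2|g| = %g (wall %g)\n",
    length(x$r), min(x$r), max(x$r),
    if (any(ok)) max(2 * Mod(x$g[ok])) else NA_real_,
    2 * Mod(x$g[length(x$g)])))
  invisible(x)
}

#' Reconstructed azimuthal velocity at given radii and phases
#'
#' Evaluates \eqn{V_\theta(r, t) = g(r)e^{it} + c.c. = 2 Re\{g e^{it}\}}.
#'
#' @param profile a [harmonic_profile()].
#' @param t dimensionless phase(s) in \[0, 2pi).
#' @return matrix of dimension \code{length(profile$r) x length(t)}.
#' @export
reconstruct_velocity <- function(profile, t) {
  stopifnot(inherits(profile, "harmonic_profile"))
  t <- as.numeric(t)
  2 * Re(outer(profile$g, exp(1i * t)))
}

#' Natural frequencies of the fluid-filled sphere (elastic estimate)
#'
#' In the undamped elastic limit the oscillation modes of a fluid of
#' storage modulus \eqn{G'} and density \eqn{\rho} in a sphere of radius
#' \eqn{R} have angular frequencies
#' \deqn{\omega_n = \lambda_n \sqrt{G' / \rho} / R,}
#' with \eqn{\lambda_n} the positive roots of \eqn{j_1}. Near these
#' frequencies the flow is resonantly excited and interior velocities can
#' exceed the wall velocity. A fluid with nonzero loss modulus shifts the
#' damped response peak slightly; for small loss factors the shift is a
#' few percent.
#'
#' @param fluid a [viscoelastic_fluid()] with \eqn{G' > 0}.
#' @param chamber a [chamber_spec()].
#' @param n number of modes.
#' @param omega_ref reference frequency \[rad/s\] at which \eqn{G'} is
#'   evaluated for tabulated (dispersive) fluids; ignored for constant
#'   fluids.
#' @return numeric vector of \eqn{\omega_n} \[rad/s\].
#' @export
natural_frequencies <- function(fluid, chamber = chamber_spec(), n = 3L,
                                omega_ref = NULL) {
  stopifnot(inherits(fluid, "viscoelastic_fluid"),
            inherits(chamber, "chamber_spec"))
  m <- fluid$model
  gp <- switch(m$type,
    constant  = m$g_prime,
    newtonian = 0,
    table     = {
      if (is.null(omega_ref))
        vf_stop("vf_domain_error",
                "tabulated fluid: supply omega_ref for evaluating G'")
      Re(complex_modulus(fluid, omega_ref))
    })
  if (gp <= 0)
    vf_stop("vf_degenerate_error",
            "purely viscous fluid: no natural frequencies")
  besselj1_roots(n) * sqrt(gp / fluid$density) / chamber$radius
}

#' Normalized time-averaged kinetic energy of a harmonic profile
#'
#' The planar kinetic energy
#' \eqn{K(t) = \int_0^{2\pi}\!\!\int_0^1 \tfrac{1}{2}(v_r^2 + v_\theta^2)\,
#' r\,dr\,d\theta}
#' of a pure first harmonic \eqn{V_\theta = g e^{it} + c.c.} has time
#' average \eqn{2\pi \int_0^1 |g|^2 r\,dr}. Normalizing by the rigid-body
#' value \eqn{\pi/8} (obtained for \eqn{g = r/2}) gives
#' \deqn{\bar K = 16 \int_0^1 |g(r)|^2\, r\, dr,}
#' so that a rigid body yields exactly 1, purely viscous fluids stay below
#' 1, and values above 1 signal resonant amplification. Composite Simpson
#' quadrature is used on uniform odd-length grids (exact for the
#' rigid-body integrand), trapezoid otherwise.
#'
#' @param profile a [harmonic_profile()] with at least 8 radii (64+ for
#'   quadrature-grade accuracy).
#' @return dimensionless \eqn{\bar K}.
#' @export
theoretical_kbar <- function(profile) {
  stopifnot(inherits(profile, "harmonic_profile"))
  if (length(profile$r) < 8L)
    vf_stop("vf_resolution_error",
            "profile too coarse for quadrature (need >= 8 radii)")
  r <- profile$r
  g <- profile$g
  if (any(!is.finite(g)))
    vf_stop("vf_domain_error", "profile contains missing amplitudes")
  16 * quad_grid(r, Mod(g)^2 * r)
}

# second-order 3-point derivative on a (possibly non-uniform) grid:
# central stencils inside, one-sided at the ends (Lagrange differentiation)
deriv_3pt <- function(y, x) {
  n <- length(x)
  d <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i == 1L) 1:3 else if (i == n) (n - 2L):n else (i - 1L):(i + 1L)
    xa <- x[j[1]]; xb <- x[j[2]]; xc <- x[j[3]]
    x0 <- x[i]
    d[i] <- y[j[1]] * (2 * x0 - xb - xc) / ((xa - xb) * (xa - xc)) +
            y[j[2]] * (2 * x0 - xa - xc) / ((xb - xa) * (xb - xc)) +
            y[j[3]] * (2 * x0 - xa - xb) / ((xc - xa) * (xc - xb))
  }
  d
}

# shared strain kernel: gamma_max(r) = A |g'(r) - g(r)/r|, with central
# differences for g' (one-sided at the ends) and the r -> 0 limit
# g/r -> g'(0) so the integrand vanishes smoothly at the centre
strain_from_profile <- function(r, g, amplitude) {
  dg <- complex(real = deriv_3pt(Re(g), r),
                imaginary = deriv_3pt(Im(g), r))
  g_over_r <- g / r
  if (r[1] == 0) g_over_r[1] <- dg[1]
  amplitude * Mod(dg - g_over_r)
}

#' Maximum shear strain profile of a harmonic velocity profile
#'
#' For a single-harmonic azimuthal flow the off-diagonal shear strain on
#' the equatorial plane is
#' \deqn{\gamma_{r\theta} = -\frac{iA}{2}\left(\frac{\partial g}{\partial r}
#'   - \frac{g}{r}\right) e^{it} + c.c.,}
#' whose maximum over time at each radius is
#' \eqn{\gamma_{max}(r) = A\,|g'(r) - g(r)/r|} (a signal
#' \eqn{C e^{it} + c.c.} peaks at \eqn{2|C|}). Rigid-body rotation
#' (\eqn{g = r/2}) shears nothing. The radial derivative is taken by
#' central differences, one-sided at the grid ends; at \eqn{r = 0} the
#' ratio \eqn{g/r} is replaced by its limit \eqn{g'(0)}.
#'
#' @param profile a [harmonic_profile()] with at least 3 radii.
#' @param amplitude rotation amplitude \eqn{A} \[rad\].
#' @return object of class \code{strain_profile}: list with \code{r} and
#'   \code{gamma_max} (dimensionless strain).
#' @export
theoretical_strain <- function(profile, amplitude) {
  stopifnot(inherits(profile, "harmonic_profile"))
  if (length(profile$r) < 3L)
    vf_stop("vf_resolution_error", "strain needs >= 3 radial points")
  if (!is.numeric(amplitude) || amplitude <= 0)
    vf_stop("vf_domain_error", "amplitude must be positive (rad)")
  structure(list(r = profile$r,
                 gamma_max = strain_from_profile(profile$r, profile$g,
                                                 amplitude)),
            class = "strain_profile")
}

#' Equivalent angular frequency of a saccade
#'
#' A saccade of duration \eqn{D} corresponds, for a sinusoidal
#' back-and-forth idealization, to angular frequency \eqn{\omega = \pi/D}:
#' half an oscillation period per saccade. Typical saccade durations of
#' 0.05-0.1 s give \eqn{\omega} of 10pi-20pi rad/s, squarely in the range
#' where vitreous resonance is predicted.
#'
#' @param duration saccade duration \eqn{D} \[s\], positive.
#' @return angular frequency \[rad/s\].
#' @examples
#' saccade_equivalent_frequency(0.1)  # 10 * pi
#' @export
saccade_equivalent_frequency <- function(duration) {
  if (!is.numeric(duration) || any(!is.finite(duration)) ||
      any(duration <= 0))
    vf_stop("vf_domain_error", "saccade duration must be positive (s)")
  pi / duration
}
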