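#' Ensemble-average the repeats of each phase
#'
#' Pointwise mean of the velocity components over repeats, excluding
#' masked points, together with the per-phase spatial median of the
#' relative ensemble standard deviation (pooled over the two components,
#' referenced to the spatial mean speed of the averaged frame). A warning
#' is emitted for phases whose relative standard deviation exceeds 5
#' percent, the level typical of phase-locked PIV ensembles.
#'
#' @param set an [generate_ensemble()]/[read_ensemble()] ensemble with at
#'   least 2 repeats per phase.
#' @return list with \code{frames} (one mean [field_frame()] per phase),
#'   \code{rel_std} (numeric per phase) and \code{phases} (dimensionless
#'   phase grid).
#' @export
ensemble_average <- function(set) {
  stopifnot(inherits(set, "ensemble_set"))
  if (set$n_repeats < 2L)
    vf_stop("vf_domain_error", "ensemble averaging needs >= 2 repeats")
  ref <- set$frames[[1]]
  mean_frames <- vector("list", set$n_phases)
  rel_std <- numeric(set$n_phases)
  for (p in seq_len(set$n_phases)) {
    sx <- 0; sy <- 0; sx2 <- 0; sy2 <- 0; cnt <- 0
    for (rep in seq_len(set$n_repeats)) {
      fr <- ensemble_frame(set, p, rep)
      if (!isTRUE(all.equal(fr$x, ref$x)) ||
          !isTRUE(all.equal(fr$y, ref$y)))
        vf_stop("vf_integrity_error",
                "inconsistent grids across repeats (phase %d)", p)
      vx <- fr$vx; vy <- fr$vy
      vx[!fr$mask] <- 0; vy[!fr$mask] <- 0
      sx <- sx + vx; sy <- sy + vy
      sx2 <- sx2 + vx^2; sy2 <- sy2 + vy^2
      cnt <- cnt + fr$mask
    }
    mask <- cnt > 0
    mx <- sx / pmax(cnt, 1L); mx[!mask] <- NA_real_
    my <- sy / pmax(cnt, 1L); my[!mask] <- NA_real_
    mean_frames[[p]] <- field_frame(ref$x, ref$y, mx, my, mask,
                                    phase = p,
                                    time = ensemble_frame(set, p, 1)$time)
    full <- cnt == set$n_repeats & set$n_repeats >= 2L
    if (any(full)) {
      n <- set$n_repeats
      varx <- (sx2[full] - sx[full]^2 / n) / (n - 1)
      vary <- (sy2[full] - sy[full]^2 / n) / (n - 1)
      point_sd <- sqrt(pmax(varx + vary, 0) / 2)
      mean_speed <- mean(sqrt(mx[full]^2 + my[full]^2))
      rel_std[p] <- if (mean_speed > 0) median(point_sd) / mean_speed else 0
    }
  }
  if (any(rel_std > 0.05))
    vf_warn("ensemble relative standard deviation exceeds 5%% at %d phase(s) (max %.1f%%)",
            sum(rel_std > 0.05), 100 * max(rel_std))
  list(frames = mean_frames, rel_std = rel_std, phases = set$phases)
}

#' Default polar analysis grids
#'
#' Uniform radii \eqn{r_i = i/n_r} in (0, 1\] and uniform azimuths
#' covering \[0, 2pi) without the duplicate endpoint. 64 radii by 96
#' azimuths resolves a 64-sample-per-diameter Cartesian field without
#' oversampling it.
#'
#' @param n_r,n_theta number of radial / azimuthal nodes.
#' @return numeric grid vector.
#' @export
default_r_grid <- function(n_r = 64L) seq_len(n_r) / n_r

#' @rdname default_r_grid
#' @export
default_theta_grid <- function(n_theta = 96L)
  2 * pi * (seq_len(n_theta) - 1L) / n_theta

#' Interpolate a Cartesian frame onto polar coordinates and nondimensionalize
#'
#' Bilinearly interpolates the dimensional velocity components onto polar
#' nodes \eqn{(x, y) = R\,r(\cos\theta, \sin\theta)}, then applies the
#' rotation to radial/azimuthal components and divides by the wall speed
#' scale \eqn{A\omega R}:
#' \deqn{v_r = \frac{v_x^* \cos\theta + v_y^* \sin\theta}{A\omega R},
#' \quad v_\theta = \frac{-v_x^* \sin\theta + v_y^* \cos\theta}
#' {A\omega R}.}
#' Polar nodes whose enclosing Cartesian cell touches a masked sample are
#' masked rather than extrapolated; in particular the ring at exactly
#' \eqn{r = 1} is typically unmeasurable (every cell containing a point of
#' the bounding circle has a corner outside it), which mirrors the loss of
#' PIV vectors at the wall.
#'
#' @param frame a (mean) [field_frame()].
#' @param protocol a [rotation_protocol()] (for the velocity scale).
#' @param chamber a [chamber_spec()].
#' @param r_grid dimensionless radii in (0, 1\], increasing.
#' @param theta_grid azimuths in \[0, 2pi), uniform.
#' @return object of class \code{polar_field}: matrices \code{vr},
#'   \code{vtheta}, logical \code{mask} and logical \code{support} (nodes
#'   interpolable given the disc geometry alone) of dimension
#'   \code{length(r_grid) x length(theta_grid)}, plus the grids and phase
#'   metadata.
#' @export
to_polar <- function(frame, protocol, chamber = chamber_spec(),
                     r_grid = default_r_grid(),
                     theta_grid = default_theta_grid()) {
  stopifnot(inherits(frame, "field_frame"),
            inherits(protocol, "rotation_protocol"),
            inherits(chamber, "chamber_spec"))
  r_grid <- as.numeric(r_grid)
  if (any(r_grid <= 0) || any(r_grid > 1) || any(diff(r_grid) <= 0))
    vf_stop("vf_domain_error", "r_grid must be increasing within (0, 1]")
  if (!is_uniform_grid(theta_grid))
    vf_stop("vf_domain_error", "theta_grid must be uniform")
  R <- chamber$radius
  scale <- protocol$amplitude * protocol$omega * R

  nodes_r <- outer(r_grid, theta_grid, function(r, th) r)
  nodes_th <- outer(r_grid, theta_grid, function(r, th) th)
  xp <- as.vector(R * nodes_r * cos(nodes_th))
  yp <- as.vector(R * nodes_r * sin(nodes_th))
  # clamp nodes sitting on the outer grid line within double rounding
  xp <- pmin(pmax(xp, min(frame$x)), max(frame$x))
  yp <- pmin(pmax(yp, min(frame$y)), max(frame$y))

  # pracma::interp2 wants Z with rows along y; frame matrices are x-major
  vx_i <- pracma::interp2(frame$x, frame$y, t(frame$vx), xp, yp,
                          method = "linear")
  vy_i <- pracma::interp2(frame$x, frame$y, t(frame$vy), xp, yp,
                          method = "linear")
  dm <- dim(nodes_r)
  vx_i <- matrix(vx_i, dm[1], dm[2])
  vy_i <- matrix(vy_i, dm[1], dm[2])
  mask <- is.finite(vx_i) & is.finite(vy_i)
  # geometric support: nodes interpolable when only the disc clipping is
  # present; distinguishes unavoidable wall losses from data dropouts
  disc <- matrix(NA_real_, length(frame$x), length(frame$y))
  disc[outer(frame$x^2, frame$y^2, `+`) <= R^2] <- 1
  sup <- pracma::interp2(frame$x, frame$y, t(disc), xp, yp,
                         method = "linear")
  support <- matrix(is.finite(sup), dm[1], dm[2])
  ct <- cos(nodes_th); st <- sin(nodes_th)
  vr <- (vx_i * ct + vy_i * st) / scale
  vth <- (-vx_i * st + vy_i * ct) / scale
  vr[!mask] <- NA_real_
  vth[!mask] <- NA_real_
  structure(list(r = r_grid, theta = as.numeric(theta_grid),
                 vr = vr, vtheta = vth, mask = mask, support = support,
                 phase = frame$phase, time = frame$time),
            class = "polar_field")
}

#' Azimuthally average the azimuthal velocity of a polar field
#'
#' Exploits the axial symmetry of the flow: at each radius, the arithmetic
#' mean of \eqn{v_\theta} over the unmasked azimuthal nodes gives the
#' radial profile \eqn{V_\theta(r)}. Radii with fewer than
#' \code{min_samples} unmasked azimuths are flagged (returned as
#' \code{NA}) instead of being silently averaged.
#'
#' @param pf a [to_polar()] result.
#' @param min_samples minimum unmasked azimuthal samples per radius.
#' @return list with \code{r}, \code{v_theta} (NA where flagged),
#'   \code{scatter} (azimuthal standard deviation) and logical
#'   \code{flagged}.
#' @export
azimuthal_average <- function(pf, min_samples = 8L) {
  stopifnot(inherits(pf, "polar_field"))
  n_ok <- rowSums(pf$mask)
  v <- rep(NA_real_, length(pf$r))
  sc <- rep(NA_real_, length(pf$r))
  ok <- n_ok >= min_samples
  for (i in which(ok)) {
    vals <- pf$vtheta[i, pf$mask[i, ]]
    v[i] <- mean(vals)
    sc[i] <- if (length(vals) > 1L) sd(vals) else 0
  }
  list(r = pf$r, v_theta = v, scatter = sc, flagged = !ok)
}

#' Planar kinetic energy of a polar field
#'
#' Computes the dimensionless kinetic energy integral over the equatorial
#' disc,
#' \deqn{K = \int_0^{2\pi}\!\!\int_0^1 \frac{v_r^2 + v_\theta^2}{2}
#' \, r \, dr \, d\theta,}
#' by periodic-trapezoid quadrature in \eqn{\theta} and composite
#' quadrature in \eqn{r} (the centre contributes a node of zero weight
#' since the integrand is proportional to \eqn{r}). Masked nodes are
#' imputed with the azimuthal mean of the unmasked nodes at the same
#' radius; a radius that is entirely masked (typically the \eqn{r = 1}
#' ring, lost to wall effects) borrows the nearest measured radius. The
#' unmasked fraction of the measurable disc (\eqn{r}-weighted, relative
#' to the nodes that are interpolable at all given the disc geometry)
#' must be at least \code{min_coverage}: losses to artifact sectors and
#' dropouts count against the threshold, the unavoidable geometric loss
#' of the outermost ring does not.
#'
#' @param pf a [to_polar()] result.
#' @param min_coverage minimum unmasked fraction of the measurable disc.
#' @return scalar dimensionless \eqn{K} with attribute \code{imputed}
#'   (number of imputed nodes).
#' @export
kinetic_energy <- function(pf, min_coverage = 0.9) {
  stopifnot(inherits(pf, "polar_field"))
  r <- pf$r
  nr <- length(r)
  nth <- length(pf$theta)
  support <- pf$support %||% matrix(TRUE, nr, nth)
  w_r <- r / sum(r)
  denom <- sum(w_r * rowSums(support) / nth)
  coverage <- if (denom > 0) sum(w_r * rowSums(pf$mask) / nth) / denom else 0
  if (coverage < min_coverage)
    vf_stop("vf_domain_error",
            "unmasked coverage %.1f%% below the %.0f%% threshold",
            100 * coverage, 100 * min_coverage)

  e <- (pf$vr^2 + pf$vtheta^2) / 2   # nr x nth, NA where masked
  n_imputed <- sum(!pf$mask)
  if (n_imputed > 0) {
    ring_mean <- rep(NA_real_, nr)
    for (i in seq_len(nr))
      if (any(pf$mask[i, ])) ring_mean[i] <- mean(e[i, pf$mask[i, ]])
    empty <- which(!is.finite(ring_mean))
    if (length(empty)) {
      filled <- which(is.finite(ring_mean))
      for (i in empty)
        ring_mean[i] <- ring_mean[filled[which.min(abs(filled - i))]]
    }
    for (i in seq_len(nr))
      e[i, !pf$mask[i, ]] <- ring_mean[i]
  }
  # theta is uniform on [0, 2pi): periodic trapezoid = mean * 2pi
  radial <- rowMeans(e) * r * 2 * pi
  # extend to r = 0 where the integrand vanishes
  K <- quad_grid(c(0, r), c(0, radial))
  attr(K, "imputed") <- n_imputed
  K
}

#' Normalized time-averaged kinetic energy from per-phase energies
#'
#' The time average of \eqn{K(t)} over one period, divided by the value
#' for a rigid body undergoing the same rotation. For the rigid body
#' \eqn{v_\theta = r\cos t}, so \eqn{K = (\pi/4)\cos^2 t} with time
#' average \eqn{\pi/8}; hence
#' \deqn{\bar K = \frac{\langle K \rangle}{\pi/8},}
#' i.e. \eqn{8/\pi} times the time average of \eqn{K}. \eqn{\bar K}
#' is below 1 for purely viscous fluids, tends to 1 in the rigid-body
#' limit, and exceeds 1 under resonant excitation. The time average uses
#' the periodic trapezoid rule, which is exact for the leading harmonics
#' on a uniform phase grid.
#'
#' @param K numeric vector of per-phase energies.
#' @param phases dimensionless phases in \[0, 2pi), increasing, spanning
#'   one period.
#' @return scalar \eqn{\bar K}.
#' @export
normalized_energy <- function(K, phases) {
  K <- as.numeric(K)
  phases <- as.numeric(phases)
  n <- length(K)
  if (n != length(phases) || n < 4L)
    vf_stop("vf_domain_error", "need matching K and phases (>= 4)")
  if (any(diff(phases) <= 0) || phases[1] < 0 || phases[n] >= 2 * pi)
    vf_stop("vf_domain_error", "phases must increase within [0, 2pi)")
  gaps <- diff(c(phases, phases[1] + 2 * pi))  # wrap around the period
  if (max(gaps) > 2 * pi / 3)
    vf_stop("vf_domain_error", "phases do not span the oscillation period")
  # periodic trapezoid: each node weighted by half its two adjacent gaps
  w <- (gaps + c(gaps[n], gaps[-n])) / 2
  avg <- sum(w * K) / (2 * pi)
  avg / (pi / 8)
}

#' Least-squares first-harmonic fit of azimuthally averaged profiles
#'
#' Fits, at each radius, the single-harmonic model
#' \eqn{V_\theta(r, t) = a(r)\cos t + b(r)\sin t} by ordinary least
#' squares over the sampled phases and forms the complex amplitude
#' \eqn{g(r) = (a - ib)/2}, so that \eqn{V_\theta = g e^{it} + c.c.}
#' Higher harmonics, negligible for small-amplitude forcing, end up in
#' the residual; the pooled residual fraction (residual sum of squares
#' over total sum of squares) measures their importance plus noise.
#'
#' @param v_theta matrix of profiles, radii in rows, phases in columns;
#'   \code{NA} rows (flagged radii) propagate to \code{NA} amplitudes.
#' @param phases dimensionless phases of the columns (need not be
#'   uniform), at least 8.
#' @param r radial grid of the rows.
#' @return list with \code{profile} (a [harmonic_profile()] possibly
#'   containing \code{NA}s) and \code{residual_fraction}.
#' @export
harmonic_fit <- function(v_theta, phases, r) {
  v_theta <- as.matrix(v_theta)
  phases <- as.numeric(phases)
  if (ncol(v_theta) != length(phases))
    vf_stop("vf_domain_error", "columns of v_theta must match phases")
  if (length(phases) < 8L)
    vf_stop("vf_domain_error",
            "harmonic fit needs >= 8 phases (got %d)", length(phases))
  X <- cbind(cos(phases), sin(phases))
  if (qr(X)$rank < 2L)
    vf_stop("vf_degenerate_error", "phase design is rank deficient")
  XtX_inv <- solve(crossprod(X))
  g <- rep(NA_complex_, nrow(v_theta))
  rss <- 0; tss <- 0
  for (i in seq_len(nrow(v_theta))) {
    yi <- v_theta[i, ]
    if (any(!is.finite(yi))) next
    beta <- XtX_inv %*% crossprod(X, yi)
    g[i] <- complex(real = beta[1], imaginary = -beta[2]) / 2
    fit <- X %*% beta
    rss <- rss + sum((yi - fit)^2)
    tss <- tss + sum(yi^2)
  }
  if (all(!is.finite(g)))
    vf_stop("vf_degenerate_error", "no radius had a complete phase record")
  list(profile = harmonic_profile(r, g),
       residual_fraction = if (tss > 0) rss / tss else 0)
}

#' Maximum shear strain from a fitted harmonic profile
#'
#' Same strain kernel as [theoretical_strain()] —
#' \eqn{\gamma_{max}(r) = A |g'(r) - g(r)/r|} — applied to measured
#' (possibly noisy) amplitude profiles. Because numerical differentiation
#' amplifies noise, an optional centered boxcar smoothing of \eqn{g} can
#' be applied first (\code{smooth_window = 3} is typical; default off).
#' Radii with missing amplitudes are dropped before differentiation.
#'
#' @param profile a [harmonic_profile()] (NAs allowed).
#' @param amplitude rotation amplitude \eqn{A} \[rad\].
#' @param smooth_window odd boxcar width for pre-smoothing \eqn{g};
#'   \code{NULL} disables smoothing.
#' @return object of class \code{strain_profile}.
#' @export
max_strain <- function(profile, amplitude, smooth_window = NULL) {
  stopifnot(inherits(profile, "harmonic_profile"))
  keep <- is.finite(profile$g)
  r <- profile$r[keep]
  g <- profile$g[keep]
  if (length(r) < 3L)
    vf_stop("vf_resolution_error", "strain needs >= 3 measured radii")
  if (!is.null(smooth_window)) {
    w <- as.integer(smooth_window)
    if (w < 3L || w %% 2L == 0L)
      vf_stop("vf_domain_error", "smooth_window must be odd and >= 3")
    half <- w %/% 2L
    gs <- g
    for (i in seq_along(g)) {
      lo <- max(1L, i - half); hi <- min(length(g), i + half)
      gs[i] <- mean(g[lo:hi])
    }
    g <- gs
  }
  structure(list(r = r,
                 gamma_max = strain_from_profile(r, g, amplitude)),
            class = "strain_profile")
}

#' Run the full post-processing chain on an ensemble
#'
#' Convenience wrapper: ensemble averaging, polar interpolation,
#' azimuthal averaging, per-phase kinetic energy, normalized energy,
#' harmonic fit and maximum strain.
#'
#' @param set an [generate_ensemble()]/[read_ensemble()] ensemble.
#' @param r_grid,theta_grid polar analysis grids (see [to_polar()]).
#' @param smooth_window optional strain pre-smoothing (see
#'   [max_strain()]).
#' @return list with \code{profile} ([harmonic_profile()]),
#'   \code{residual_fraction}, \code{K} (per phase), \code{kbar},
#'   \code{strain} (\code{strain_profile}), \code{v_theta} (radius x
#'   phase matrix), \code{phases}, \code{rel_std} and \code{flagged}
#'   radii.
#' @export
analyze_ensemble <- function(set, r_grid = default_r_grid(),
                             theta_grid = default_theta_grid(),
                             smooth_window = NULL) {
  stopifnot(inherits(set, "ensemble_set"))
  avg <- ensemble_average(set)
  n_phases <- set$n_phases
  V <- matrix(NA_real_, length(r_grid), n_phases)
  K <- numeric(n_phases)
  flagged <- rep(FALSE, length(r_grid))
  for (p in seq_len(n_phases)) {
    pf <- to_polar(avg$frames[[p]], set$protocol, set$chamber,
                   r_grid, theta_grid)
    az <- azimuthal_average(pf)
    V[, p] <- az$v_theta
    flagged <- flagged | az$flagged
    K[p] <- as.numeric(kinetic_energy(pf))
  }
  kbar <- normalized_energy(K, avg$phases)
  fit <- harmonic_fit(V, avg$phases, r_grid)
  strain <- max_strain(fit$profile, set$protocol$amplitude,
                       smooth_window = smooth_window)
  list(profile = fit$profile, residual_fraction = fit$residual_fraction,
       K = K, kbar = kbar, strain = strain, v_theta = V,
       phases = avg$phases, rel_std = avg$rel_std, flagged = flagged)
}

#' Scan the normalized kinetic energy across forcing frequency
#'
#' Computes \eqn{\bar K(\omega)} over a frequency sweep, either from the
#' closed-form profile (\code{mode = "theoretical"}) or by running the
#' full synthetic generate-average-polar-energy chain at each frequency
#' (\code{mode = "synthetic"}). The resonant frequency is the argmax of
#' the curve; in theoretical mode it is refined by a 3-point parabolic
#' interpolation around the discrete peak, while synthetic mode reports
#' the discrete argmax (noise makes sub-grid refinement spurious). When
#' the maximum sits at a sweep boundary the \code{peak_at_boundary} flag
#' is set: the true resonance lies outside the tested range (as happens
#' when every tested frequency is below resonance).
#'
#' @param fluid a [viscoelastic_fluid()].
#' @param chamber a [chamber_spec()].
#' @param amplitude rotation amplitude \[rad\] (used in synthetic mode).
#' @param omega_list increasing vector of at least 5 angular frequencies
#'   \[rad/s\].
#' @param mode \code{"theoretical"} or \code{"synthetic"}.
#' @param n_r radial resolution of the theoretical profile.
#' @param seed RNG seed (synthetic mode with noise).
#' @param generator named list of overrides passed to
#'   [generate_ensemble()] in synthetic mode (e.g. \code{n_phases},
#'   \code{n_repeats}, \code{noise_rel}, \code{grid_step}).
#' @param r_grid,theta_grid polar analysis grids for synthetic mode.
#' @return object of class \code{resonance_scan}: data.frame
#'   \code{curve} (omega, kbar), \code{omega_res}, logical
#'   \code{peak_at_boundary}, and \code{mode}.
#' @export
resonance_scan <- function(fluid, chamber = chamber_spec(), amplitude = 0.035,
                           omega_list, mode = c("theoretical", "synthetic"),
                           n_r = 256L, seed = NULL, generator = list(),
                           r_grid = default_r_grid(),
                           theta_grid = default_theta_grid()) {
  mode <- match.arg(mode)
  omega_list <- as.numeric(omega_list)
  if (length(omega_list) < 5L)
    vf_stop("vf_domain_error", "sweep needs at least 5 frequencies")
  if (any(diff(omega_list) <= 0))
    vf_stop("vf_domain_error", "omega_list must be strictly increasing")
  check_omega(omega_list)

  kb <- vapply(seq_along(omega_list), function(i) {
    om <- omega_list[i]
    if (mode == "theoretical") {
      k <- complex_wavenumber(fluid, om, chamber)
      prof <- amplitude_profile(k, seq(0, 1, length.out = n_r + 1L))
      theoretical_kbar(prof)
    } else {
      args <- c(list(fluid = fluid,
                     protocol = rotation_protocol(amplitude, om),
                     chamber = chamber,
                     seed = if (is.null(seed)) NULL else seed + i),
                generator)
      set <- do.call(generate_ensemble, args)
      res <- analyze_ensemble(set, r_grid = r_grid,
                              theta_grid = theta_grid)
      res$kbar
    }
  }, numeric(1))

  i_max <- which.max(kb)
  at_edge <- i_max == 1L || i_max == length(kb)
  omega_res <- omega_list[i_max]
  if (!at_edge && mode == "theoretical") {
    # vertex of the parabola through the three points around the peak
    x <- omega_list[(i_max - 1L):(i_max + 1L)]
    y <- kb[(i_max - 1L):(i_max + 1L)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
            x[1] * (y[3] - y[2])) / denom
    b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
            x[1]^2 * (y[2] - y[3])) / denom
    if (a < 0) omega_res <- -b / (2 * a)
  }
  structure(list(curve = data.frame(omega = omega_list, kbar = kb),
                 omega_res = omega_res, peak_at_boundary = at_edge,
                 mode = mode),
            class = "resonance_scan")
}

#' @export
print.resonance_scan <- function(x, ...) {
  cat(sprintf(
    "<resonance_scan mode=%s> %d frequencies in [%g, %g] rad/s\n",
    x$mode, nrow(x$curve), min(x$curve$omega), max(x$curve$omega)))
  cat(sprintf("  omega_res = %g rad/s (kbar max = %g)%s\n",
              x$omega_res, max(x$curve$kbar),
              if (x$peak_at_boundary) " [peak at sweep boundary]" else ""))
  invisible(x)
}

#' Compare a fitted harmonic profile with a theoretical one
#'
#' Resamples the fitted complex amplitude onto the model's radial grid
#' (linear interpolation, no extrapolation), reconstructs the velocity
#' profiles \eqn{V_\theta = g e^{it} + c.c.} for both at the given
#' phases, and reports the root-mean-square and maximum absolute
#' discrepancy over all (radius, phase) pairs. Both quantities are in
#' wall-amplitude units (the dimensionless wall velocity amplitude is 1),
#' so a value of 0.05 means 5 percent of the wall amplitude.
#'
#' @param fitted a [harmonic_profile()] from [harmonic_fit()] (NAs at
#'   unmeasured radii are allowed and excluded).
#' @param model a [harmonic_profile()] from [amplitude_profile()].
#' @param phases dimensionless phases at which to compare (default 16
#'   uniform).
#' @return list with \code{rms}, \code{max_abs}, \code{n_points} and the
#'   comparison grid \code{r}.
#' @export
compare_to_theory <- function(fitted, model,
                              phases = 2 * pi * (0:15) / 16) {
  stopifnot(inherits(fitted, "harmonic_profile"),
            inherits(model, "harmonic_profile"))
  keep <- is.finite(fitted$g)
  if (!any(keep))
    vf_stop("vf_domain_error", "fitted profile has no measured radii")
  rf <- fitted$r[keep]
  gf <- fitted$g[keep]
  r_common <- model$r[model$r >= min(rf) & model$r <= max(rf)]
  if (length(r_common) < 2L)
    vf_stop("vf_domain_error", "fitted and model radial supports disjoint")
  g_re <- approx(rf, Re(gf), xout = r_common)$y
  g_im <- approx(rf, Im(gf), xout = r_common)$y
  g_fit <- complex(real = g_re, imaginary = g_im)
  g_mod <- model$g[model$r >= min(rf) & model$r <= max(rf)]
  e <- exp(1i * phases)
  V_fit <- 2 * Re(outer(g_fit, e))
  V_mod <- 2 * Re(outer(g_mod, e))
  d <- V_fit - V_mod
  list(rms = sqrt(mean(d^2)), max_abs = max(abs(d)),
       n_points = length(d), r = r_common)
}
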