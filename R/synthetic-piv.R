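#' Construct a planar velocity field frame
#'
#' A \code{field_frame} holds one PIV-style snapshot of the equatorial
#' plane: a regular Cartesian grid clipped to the disc of radius \eqn{R},
#' dimensional velocity components, and a validity mask. Masked points
#' (outside the disc, or lost to optical artifacts such as laser-entry
#' reflections) carry \code{NA} velocities.
#'
#' @param x,y grid coordinates \[m\] (vectors; the grid is their outer
#'   product, x varying along rows of the matrices).
#' @param vx,vy velocity components \[m/s\], matrices of dimension
#'   \code{length(x) x length(y)}.
#' @param mask logical matrix, \code{TRUE} where the vector is valid.
#' @param phase integer phase index within the oscillation period.
#' @param time dimensional time \eqn{t^*} \[s\] of the snapshot.
#' @return object of class \code{field_frame}.
#' @export
field_frame <- function(x, y, vx, vy, mask, phase = 1L, time = 0) {
  dm <- c(length(x), length(y))
  for (nmat in list(vx = vx, vy = vy, mask = mask))
    if (!identical(dim(nmat), as.integer(dm)))
      vf_stop("vf_integrity_error",
              "velocity/mask arrays must be %d x %d", dm[1], dm[2])
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 vx = vx, vy = vy, mask = mask,
                 phase = as.integer(phase), time = as.numeric(time)),
            class = "field_frame")
}

# default artifact: a 15 degree masked sector on the +x side, where the
# laser sheet enters the chamber and reflections corrupt vectors
default_artifact <- function() {
  list(type = "sector", center_deg = 0, width_deg = 15)
}

artifact_mask <- function(artifact, x, y) {
  keep <- matrix(TRUE, length(x), length(y))
  if (is.null(artifact)) return(keep)
  if (isTRUE(artifact)) artifact <- default_artifact()
  if (!is.list(artifact) || !identical(artifact$type, "sector"))
    vf_stop("vf_usage_error",
            "unknown artifact spec (expected list(type = 'sector', ...))")
  c0 <- (artifact$center_deg %||% 0) * pi / 180
  hw <- (artifact$width_deg %||% 15) / 2 * pi / 180
  th <- outer(x, y, function(xx, yy) atan2(yy, xx))
  d <- atan2(sin(th - c0), cos(th - c0))  # wrapped angular distance
  keep[abs(d) <= hw] <- FALSE
  keep
}

#' Generate a synthetic PIV ensemble of the equatorial-plane flow
#'
#' Emulates the sampling structure of a phase-locked PIV experiment on a
#' sinusoidally rotating sphere filled with a viscoelastic fluid: the
#' noise-free field at dimensionless phase \eqn{t} is the closed-form
#' solution \eqn{v_\theta^* = A\omega R\,(g(r)e^{it} + c.c.)},
#' \eqn{v_r^* = 0}, rotated to Cartesian components; each of
#' \code{n_repeats} repeats per phase adds independent per-component
#' Gaussian noise with standard deviation \code{noise_rel} times the
#' spatial mean speed of that phase's noise-free field. Phases are uniform
#' over one period starting at \eqn{t = 0}. The same seed always
#' reproduces the identical ensemble.
#'
#' @param fluid a [viscoelastic_fluid()].
#' @param protocol a [rotation_protocol()].
#' @param chamber a [chamber_spec()].
#' @param grid_step Cartesian grid spacing \[m\]; must resolve the chamber
#'   (\code{grid_step < R/10}). The default gives 64 samples across the
#'   diameter.
#' @param n_phases snapshots per oscillation period (phase-locked
#'   sampling; experiments use 20-50).
#' @param n_repeats ensemble repeats per phase (experiments use about 40).
#' @param noise_rel per-component Gaussian noise level as a fraction of
#'   the spatial mean speed of the noise-free frame at each phase;
#'   ensemble standard deviations of at most 5 percent of the mean
#'   velocity are typical, hence the default 0.05.
#' @param seed integer RNG seed; required whenever \code{noise_rel > 0}.
#' @param artifact \code{NULL} (none), \code{TRUE} (default 15 degree
#'   masked sector on the +x side) or
#'   \code{list(type = "sector", center_deg =, width_deg =)}.
#' @param wavenumber optional complex wavenumber overriding
#'   [complex_wavenumber()] (e.g. \code{1e-6} to generate the rigid-body
#'   limit directly).
#' @return object of class \code{ensemble_set}: list of
#'   [field_frame()]s ordered phase-major, plus provenance.
#' @export
generate_ensemble <- function(fluid, protocol, chamber = chamber_spec(),
                              grid_step = 2 * chamber$radius / 63,
                              n_phases = 32L, n_repeats = 40L,
                              noise_rel = 0.05, seed = NULL,
                              artifact = NULL, wavenumber = NULL) {
  stopifnot(inherits(protocol, "rotation_protocol"),
            inherits(chamber, "chamber_spec"))
  R <- chamber$radius
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step >= R / 10)
    vf_stop("vf_resolution_error",
            "grid_step must be positive and below R/10 = %g m", R / 10)
  n_phases <- as.integer(n_phases)
  n_repeats <- as.integer(n_repeats)
  if (n_phases < 4L)
    vf_stop("vf_domain_error", "need at least 4 phases per period")
  if (n_repeats < 1L)
    vf_stop("vf_domain_error", "need at least 1 repeat")
  if (noise_rel < 0)
    vf_stop("vf_domain_error", "noise_rel must be non-negative")
  if (noise_rel > 0 && is.null(seed))
    vf_stop("vf_usage_error", "a seed is required for noisy generation")

  A <- protocol$amplitude
  omega <- protocol$omega
  k <- wavenumber %||% complex_wavenumber(fluid, omega, chamber)

  n_side <- floor(2 * R / grid_step) + 1L
  x <- seq(-R, R, length.out = n_side)
  y <- x
  xm <- matrix(x, n_side, n_side)
  ym <- matrix(y, n_side, n_side, byrow = TRUE)
  rr <- sqrt(xm^2 + ym^2)
  inside <- rr <= R
  keep <- inside & artifact_mask(artifact, x, y)

  # complex amplitude g at every grid radius; unit azimuthal direction
  g <- matrix(0i, n_side, n_side)
  g[inside] <- spherical_j1(k * rr[inside] / R) / (2 * spherical_j1(k))
  # azimuthal unit vector (-sin th, cos th); zero at the centre (v = 0)
  ex <- matrix(0, n_side, n_side)
  ey <- matrix(0, n_side, n_side)
  pos <- inside & rr > 0
  ex[pos] <- -ym[pos] / rr[pos]
  ey[pos] <- xm[pos] / rr[pos]

  phases <- 2 * pi * (seq_len(n_phases) - 1L) / n_phases
  scale <- A * omega * R

  build <- function() {
    frames <- vector("list", n_phases * n_repeats)
    for (p in seq_len(n_phases)) {
      t_dimless <- phases[p]
      vth <- scale * 2 * Re(g * exp(1i * t_dimless))  # dimensional v_theta*
      vx0 <- vth * ex
      vy0 <- vth * ey
      vx0[!keep] <- NA_real_
      vy0[!keep] <- NA_real_
      sd_p <- if (noise_rel > 0) {
        noise_rel * mean(sqrt(vx0[keep]^2 + vy0[keep]^2))
      } else 0
      for (rep in seq_len(n_repeats)) {
        vx <- vx0
        vy <- vy0
        if (sd_p > 0) {
          nk <- sum(keep)
          vx[keep] <- vx[keep] + rnorm(nk, 0, sd_p)
          vy[keep] <- vy[keep] + rnorm(nk, 0, sd_p)
        }
        frames[[(p - 1L) * n_repeats + rep]] <-
          field_frame(x, y, vx, vy, keep, phase = p,
                      time = t_dimless / omega)
      }
    }
    frames
  }
  frames <- if (is.null(seed)) build() else with_seed(seed, build())

  structure(list(frames = frames, n_phases = n_phases,
                 n_repeats = n_repeats, phases = phases,
                 seed = seed, noise_rel = noise_rel,
                 fluid = fluid, protocol = protocol, chamber = chamber,
                 artifact = artifact, wavenumber = k,
                 grid_step = grid_step),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<ensemble_set> %d phases x %d repeats, %d x %d grid, ",
    "noise %g, seed %s\n"),
    x$n_phases, x$n_repeats, length(x$frames[[1]]$x),
    length(x$frames[[1]]$y), x$noise_rel,
    if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

ensemble_frame <- function(set, phase, rep) {
  set$frames[[(phase - 1L) * set$n_repeats + rep]]
}

frame_file_name <- function(phase, rep) {
  sprintf("frame_p%03d_r%03d.txt", phase, rep)
}

#' Write an ensemble to a directory of delimited-text frames
#'
#' One file per frame with columns \code{x y vx vy mask} (header comment
#' \code{# x_m y_m vx_m_s vy_m_s mask}) plus a JSON manifest holding the
#' provenance: fluid, protocol, chamber, grid, seed and noise settings.
#' Values are written with 17 significant digits so a read-back reproduces
#' them bit for bit.
#'
#' @param set an [generate_ensemble()] result.
#' @param path directory to create/fill.
#' @return \code{path}, invisibly.
#' @export
write_ensemble <- function(set, path) {
  stopifnot(inherits(set, "ensemble_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fl <- set$fluid
  manifest <- list(
    format = "vitreflow-ensemble-1",
    n_phases = set$n_phases, n_repeats = set$n_repeats,
    noise_rel = set$noise_rel, seed = set$seed,
    grid_step = set$grid_step,
    amplitude_rad = set$protocol$amplitude,
    omega_rad_s = set$protocol$omega,
    radius_m = set$chamber$radius,
    density_kg_m3 = if (is.null(fl)) NULL else fl$density,
    fluid_name = if (is.null(fl)) NULL else fl$name,
    fluid_model = if (is.null(fl)) NULL else fl$model,
    artifact = set$artifact,
    wavenumber = c(Re(set$wavenumber), Im(set$wavenumber)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (p in seq_len(set$n_phases)) {
    for (rep in seq_len(set$n_repeats)) {
      fr <- ensemble_frame(set, p, rep)
      nx <- length(fr$x); ny <- length(fr$y)
      xm <- rep(fr$x, times = ny)
      ym <- rep(fr$y, each = nx)
      vx <- as.vector(fr$vx); vy <- as.vector(fr$vy)
      mk <- as.integer(as.vector(fr$mask))
      vx[is.na(vx)] <- 0; vy[is.na(vy)] <- 0
      lines <- c("# x_m y_m vx_m_s vy_m_s mask",
                 sprintf("# phase %d time_s %.17g", fr$phase, fr$time),
                 sprintf("%.17g %.17g %.17g %.17g %d", xm, ym, vx, vy, mk))
      writeLines(lines, file.path(path, frame_file_name(p, rep)))
    }
  }
  invisible(path)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' Validates the manifest, the frame count, grid congruence across frames
#' and the disc invariant (no unmasked vector outside radius \eqn{R}).
#'
#' @param path directory containing \code{manifest.json} and frame files.
#' @return an \code{ensemble_set}.
#' @export
read_ensemble <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    vf_stop("vf_integrity_error", "manifest.json missing in %s", path)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  need <- c("n_phases", "n_repeats", "amplitude_rad", "omega_rad_s",
            "radius_m")
  miss <- need[!need %in% names(man)]
  if (length(miss))
    vf_stop("vf_integrity_error", "manifest lacks field(s): %s",
            paste(miss, collapse = ", "))
  n_phases <- as.integer(man$n_phases)
  n_repeats <- as.integer(man$n_repeats)
  R <- man$radius_m
  files <- outer(seq_len(n_phases), seq_len(n_repeats), frame_file_name)
  missing_files <- !file.exists(file.path(path, files))
  if (any(missing_files))
    vf_stop("vf_integrity_error",
            "frame-count mismatch: %d of %d frame files missing",
            sum(missing_files), length(files))

  frames <- vector("list", n_phases * n_repeats)
  grid_ref <- NULL
  for (p in seq_len(n_phases)) {
    for (rep in seq_len(n_repeats)) {
      f <- file.path(path, frame_file_name(p, rep))
      hdr <- readLines(f, n = 2L)
      tm <- 0
      if (length(hdr) >= 2 && grepl("^# phase", hdr[2]))
        tm <- as.numeric(sub(".*time_s ", "", hdr[2]))
      tab <- read.table(f, header = FALSE, comment.char = "#",
                        col.names = c("x", "y", "vx", "vy", "mask"))
      x <- sort(unique(tab$x)); y <- sort(unique(tab$y))
      nx <- length(x); ny <- length(y)
      if (nrow(tab) != nx * ny)
        vf_stop("vf_integrity_error", "%s is not a complete grid",
                basename(f))
      if (is.null(grid_ref)) grid_ref <- list(x = x, y = y)
      else if (!isTRUE(all.equal(grid_ref$x, x)) ||
               !isTRUE(all.equal(grid_ref$y, y)))
        vf_stop("vf_integrity_error", "%s grid differs from other frames",
                basename(f))
      ord <- order(match(tab$y, y), match(tab$x, x))
      tab <- tab[ord, , drop = FALSE]
      mask <- matrix(tab$mask != 0, nx, ny)
      bad <- mask & matrix(tab$x^2 + tab$y^2 > R^2 * (1 + 1e-12), nx, ny)
      if (any(bad))
        vf_stop("vf_integrity_error",
                "%s has %d unmasked vector(s) outside the disc",
                basename(f), sum(bad))
      vx <- matrix(tab$vx, nx, ny); vx[!mask] <- NA_real_
      vy <- matrix(tab$vy, nx, ny); vy[!mask] <- NA_real_
      frames[[(p - 1L) * n_repeats + rep]] <-
        field_frame(x, y, vx, vy, mask, phase = p, time = tm)
    }
  }
  fluid <- NULL
  if (!is.null(man$fluid_model)) {
    fm <- man$fluid_model
    fluid <- switch(fm$type,
      constant  = viscoelastic_fluid(fm$g_prime, fm$g_loss,
                                     density = man$density_kg_m3,
                                     name = man$fluid_name %||% "fluid"),
      newtonian = newtonian_fluid(fm$mu, density = man$density_kg_m3,
                                  name = man$fluid_name %||% "newtonian"),
      table     = viscoelastic_fluid(fm$g_prime, fm$g_loss,
                                     omega = fm$omega,
                                     density = man$density_kg_m3,
                                     name = man$fluid_name %||% "fluid"),
      NULL)
  }
  wn <- if (!is.null(man$wavenumber))
    complex(real = man$wavenumber[1], imaginary = man$wavenumber[2])
  else NULL
  structure(list(frames = frames, n_phases = n_phases,
                 n_repeats = n_repeats,
                 phases = 2 * pi * (seq_len(n_phases) - 1L) / n_phases,
                 seed = man$seed, noise_rel = man$noise_rel %||% 0,
                 fluid = fluid,
                 protocol = rotation_protocol(man$amplitude_rad,
                                              man$omega_rad_s),
                 chamber = chamber_spec(R),
                 artifact = man$artifact,
                 wavenumber = wn,
                 grid_step = man$grid_step %||% diff(grid_ref$x[1:2])),
            class = "ensemble_set")
}
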