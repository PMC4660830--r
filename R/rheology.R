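#' Viscoelastic fluid with a constant or tabulated complex modulus
#'
#' Represents the linear viscoelastic rheology of a vitreous-like fluid
#' through its complex modulus \eqn{G^*(\omega) = G'(\omega) + iG''(\omega)},
#' where \eqn{G'} is the storage (elastic) modulus and \eqn{G''} the loss
#' (viscous) modulus, both in Pa. The modulus is either frequency
#' independent (a single \code{g_prime}/\code{g_loss} pair) or tabulated
#' against angular frequency, in which case queries interpolate each
#' modulus linearly in \eqn{\log\omega} and refuse to extrapolate.
#'
#' The default density is that of water, 1000 kg/m^3: the vitreous humour
#' is about 99 percent water and artificial vitreous substitutes are
#' dilute aqueous solutions.
#'
#' @param g_prime storage modulus G' \[Pa\]. Scalar for a constant fluid,
#'   or a vector parallel to \code{omega} for a tabulated one.
#' @param g_loss loss modulus G'' \[Pa\], same shape as \code{g_prime}.
#' @param omega optional vector of angular frequencies \[rad/s\] making the
#'   fluid tabulated; must be positive and strictly increasing.
#' @param density fluid density \[kg/m^3\].
#' @param name label used in printing and manifests.
#' @return An object of class \code{viscoelastic_fluid}.
#' @seealso [newtonian_fluid()], [complex_modulus()], [read_rheology_table()]
#' @examples
#' f <- viscoelastic_fluid(g_prime = 10, g_loss = 2)
#' complex_modulus(f, 30)
#' @export
viscoelastic_fluid <- function(g_prime, g_loss, omega = NULL,
                               density = 1000, name = "fluid") {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0)
    vf_stop("vf_domain_error", "density must be a positive number (kg/m^3)")
  if (any(!is.finite(g_prime)) || any(!is.finite(g_loss)))
    vf_stop("vf_domain_error", "moduli must be finite")
  if (any(g_prime < 0) || any(g_loss < 0))
    vf_stop("vf_domain_error", "moduli G', G'' must be non-negative")
  if (any(g_prime == 0 & g_loss == 0))
    vf_stop("vf_degenerate_error",
            "G' and G'' cannot both vanish at the same frequency")

  if (is.null(omega)) {
    if (length(g_prime) != 1L || length(g_loss) != 1L)
      vf_stop("vf_domain_error",
              "constant fluid takes scalar g_prime and g_loss")
    model <- list(type = "constant", g_prime = g_prime, g_loss = g_loss)
  } else {
    if (length(omega) < 2L)
      vf_stop("vf_domain_error", "a modulus table needs at least 2 rows")
    if (length(g_prime) != length(omega) || length(g_loss) != length(omega))
      vf_stop("vf_domain_error", "omega, g_prime, g_loss must align")
    if (any(!is.finite(omega)) || any(omega <= 0))
      vf_stop("vf_domain_error", "table frequencies must be positive")
    if (any(diff(omega) <= 0))
      vf_stop("vf_domain_error",
              "table frequencies must be strictly increasing")
    model <- list(type = "table", omega = as.numeric(omega),
                  g_prime = as.numeric(g_prime), g_loss = as.numeric(g_loss))
  }
  structure(list(name = name, density = density, model = model),
            class = "viscoelastic_fluid")
}

#' Newtonian fluid expressed through its oscillatory complex modulus
#'
#' A purely viscous fluid of dynamic viscosity \eqn{\mu} responds in
#' oscillatory shear with \eqn{G^*(\omega) = i\omega\mu}: zero storage
#' modulus and loss modulus \eqn{\omega\mu}. This constructor exposes that
#' purely viscous limit so the elastic resonance machinery can be checked
#' against it (a Newtonian fluid has no natural frequencies and its
#' normalized kinetic energy never exceeds 1).
#'
#' @param mu dynamic viscosity \[Pa s\], positive.
#' @inheritParams viscoelastic_fluid
#' @return An object of class \code{viscoelastic_fluid}.
#' @examples
#' complex_modulus(newtonian_fluid(1), 10)  # 0 + 10i
#' @export
newtonian_fluid <- function(mu, density = 1000, name = "newtonian") {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    vf_stop("vf_domain_error", "viscosity mu must be a positive number (Pa s)")
  if (!is.finite(density) || density <= 0)
    vf_stop("vf_domain_error", "density must be a positive number (kg/m^3)")
  structure(list(name = name, density = density,
                 model = list(type = "newtonian", mu = mu)),
            class = "viscoelastic_fluid")
}

#' @export
print.viscoelastic_fluid <- function(x, ...) {
  m <- x$model
  desc <- switch(m$type,
    constant  = sprintf("G* = %g + %gi Pa (constant)", m$g_prime, m$g_loss),
    newtonian = sprintf("G* = i omega mu, mu = %g Pa s", m$mu),
    table     = sprintf("tabulated on %d frequencies in [%g, %g] rad/s",
                        length(m$omega), min(m$omega), max(m$omega)))
  cat(sprintf("<viscoelastic_fluid '%s'> rho = %g kg/m^3, %s\n",
              x$name, x$density, desc))
  invisible(x)
}

check_omega <- function(omega) {
  if (!is.numeric(omega) || length(omega) == 0L || any(!is.finite(omega)) ||
      any(omega <= 0))
    vf_stop("vf_domain_error", "angular frequency must be positive (rad/s)")
  as.numeric(omega)
}

#' Complex modulus of a fluid at given angular frequencies
#'
#' Evaluates \eqn{G^*(\omega) = G'(\omega) + iG''(\omega)}. Constant fluids
#' return the same value at every frequency; Newtonian fluids return
#' \eqn{i\omega\mu}; tabulated fluids interpolate both moduli linearly in
#' \eqn{\log\omega} between nodes and raise a range error outside the
#' table (rheological measurements are not extrapolated).
#'
#' @param fluid a [viscoelastic_fluid()] or [newtonian_fluid()].
#' @param omega angular frequency \[rad/s\], scalar or vector, positive.
#' @return complex vector of moduli \[Pa\], same length as \code{omega}.
#' @export
complex_modulus <- function(fluid, omega) {
  stopifnot(inherits(fluid, "viscoelastic_fluid"))
  omega <- check_omega(omega)
  m <- fluid$model
  switch(m$type,
    constant  = rep(complex(real = m$g_prime, imaginary = m$g_loss),
                    length(omega)),
    newtonian = complex(real = 0, imaginary = omega * m$mu),
    table     = {
      lo <- min(m$omega); hi <- max(m$omega)
      if (any(omega < lo * (1 - 1e-12)) || any(omega > hi * (1 + 1e-12)))
        vf_stop("vf_range_error",
                "omega outside the tabulated range [%g, %g] rad/s", lo, hi)
      omega <- pmin(pmax(omega, lo), hi)
      gp <- approx(log(m$omega), m$g_prime, xout = log(omega))$y
      gl <- approx(log(m$omega), m$g_loss,  xout = log(omega))$y
      complex(real = gp, imaginary = gl)
    })
}

#' Loss factor G''/G' of a fluid
#'
#' The loss factor is the ratio of viscous to elastic response; small
#' values mean weak damping and stronger resonant amplification of the
#' flow inside the sphere.
#'
#' @inheritParams complex_modulus
#' @return numeric loss factor, same length as \code{omega}.
#' @export
loss_factor <- function(fluid, omega) {
  g <- complex_modulus(fluid, omega)
  if (any(Re(g) <= 0))
    vf_stop("vf_degenerate_error",
            "loss factor undefined: G' = 0 (purely viscous at this frequency)")
  Im(g) / Re(g)
}

rheology_columns <- c("omega_rad_s", "g_prime_pa", "g_double_prime_pa")

#' Read a rheology table from delimited text
#'
#' Expects a header line naming the columns \code{omega_rad_s},
#' \code{g_prime_pa} and \code{g_double_prime_pa} (any order, comma or
#' whitespace separated); lines starting with \code{#} are comments. Rows
#' are sorted by frequency on read; duplicated frequencies are rejected.
#' Density is not part of the file and is supplied by the caller.
#'
#' @param path file to read.
#' @inheritParams viscoelastic_fluid
#' @return a tabulated [viscoelastic_fluid()].
#' @seealso [write_rheology_table()]
#' @export
read_rheology_table <- function(path, density = 1000,
                                name = basename(path)) {
  if (!file.exists(path))
    vf_stop("vf_parse_error", "rheology table not found: %s", path)
  first <- grep("^\\s*#", readLines(path, warn = FALSE), value = TRUE,
                invert = TRUE)[1]
  if (is.na(first))
    vf_stop("vf_parse_error", "rheology table %s is empty", path)
  sep <- if (grepl(",", first)) "," else ""
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = sep, comment.char = "#",
               stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e)
      vf_stop("vf_parse_error", "cannot parse %s: %s", path,
              conditionMessage(e)))
  missing <- setdiff(rheology_columns, names(tab))
  if (length(missing))
    vf_stop("vf_parse_error", "missing column(s): %s",
            paste(missing, collapse = ", "))
  for (col in rheology_columns) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      vf_stop("vf_parse_error", "non-numeric value in column %s, data row %d",
              col, bad[1])
    tab[[col]] <- v
  }
  dup <- which(duplicated(tab$omega_rad_s))
  if (length(dup))
    vf_stop("vf_parse_error", "duplicated frequency at data row %d", dup[1])
  tab <- tab[order(tab$omega_rad_s), , drop = FALSE]
  viscoelastic_fluid(g_prime = tab$g_prime_pa, g_loss = tab$g_double_prime_pa,
                     omega = tab$omega_rad_s, density = density, name = name)
}

#' Write a fluid's modulus table to delimited text
#'
#' Constant and Newtonian fluids are sampled at \code{probe_omega} so that
#' any fluid can be round-tripped through the tabular format.
#'
#' @param fluid a [viscoelastic_fluid()].
#' @param path file to write.
#' @param probe_omega frequencies \[rad/s\] used to sample non-tabulated
#'   fluids.
#' @return \code{path}, invisibly.
#' @export
write_rheology_table <- function(fluid, path,
                                 probe_omega = pi * c(1, 2, 5, 10, 30)) {
  stopifnot(inherits(fluid, "viscoelastic_fluid"))
  if (fluid$model$type == "table") {
    omega <- fluid$model$omega
  } else {
    omega <- sort(check_omega(probe_omega))
  }
  g <- complex_modulus(fluid, omega)
  tab <- data.frame(omega_rad_s = omega, g_prime_pa = Re(g),
                    g_double_prime_pa = Im(g))
  lines <- c(sprintf("# rheology table for '%s' (density not stored)",
                     fluid$name),
             paste(rheology_columns, collapse = " "),
             sprintf("%.17g %.17g %.17g", tab$omega_rad_s, tab$g_prime_pa,
                     tab$g_double_prime_pa))
  writeLines(lines, path)
  invisible(path)
}
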