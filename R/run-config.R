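#' Read and validate a run configuration
#'
#' A run configuration is a flat-ish JSON file describing the fluid, the
#' rotation protocol, the chamber, and the generator/pipeline/sweep
#' settings of a reproducible run. Unit-ambiguous quantities carry
#' explicit unit fields: amplitudes are \code{"rad"} or \code{"deg"},
#' frequencies \code{"rad_s"} or \code{"hz"}; everything is converted to
#' rad and rad/s on read and the conversion is reported. A seed is
#' mandatory for any stochastic run (\code{noise_rel > 0}).
#'
#' Recognized blocks (missing settings fall back to the package
#' defaults, which mirror typical vitreous-model experiments:
#' R = 1.25 cm, 32 phases, 40 repeats, 5 percent noise):
#' \describe{
#'   \item{fluid}{\code{type} = \code{"constant"}, \code{"newtonian"} or
#'     \code{"table"}; \code{g_prime}/\code{g_double_prime} \[Pa\],
#'     \code{mu} \[Pa s\] or \code{table_path}; \code{density}
#'     \[kg/m^3\]; \code{name}.}
#'   \item{protocol}{\code{amplitude} + \code{amplitude_unit},
#'     \code{omega} + \code{omega_unit}.}
#'   \item{chamber}{\code{radius} \[m\].}
#'   \item{generator}{\code{grid_step}, \code{n_phases},
#'     \code{n_repeats}, \code{noise_rel}, \code{seed},
#'     \code{artifact}.}
#'   \item{pipeline}{\code{n_r}, \code{n_theta}, \code{smooth_window}.}
#'   \item{sweep}{\code{omega} (explicit vector) or
#'     \code{from}/\code{to}/\code{n} (+ optional
#'     \code{spacing = "log"}), with \code{omega_unit}; \code{mode}.}
#' }
#'
#' @param path JSON file.
#' @return object of class \code{run_config} with resolved fields
#'   \code{fluid}, \code{protocol}, \code{chamber}, \code{generator},
#'   \code{pipeline}, \code{sweep} and a \code{hash} fingerprint of the
#'   resolved settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    vf_stop("vf_usage_error", "config file not found: %s", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    vf_stop("vf_usage_error", "cannot parse config: %s",
                            conditionMessage(e)))
  build_run_config(raw, dir = dirname(path))
}

build_run_config <- function(raw, dir = ".") {
  fl <- raw$fluid
  if (is.null(fl) || is.null(fl$type))
    vf_stop("vf_usage_error", "config field 'fluid.type' is required")
  density <- fl$density %||% 1000
  fluid <- switch(fl$type,
    constant = {
      if (is.null(fl$g_prime) || is.null(fl$g_double_prime))
        vf_stop("vf_usage_error",
                "constant fluid needs 'g_prime' and 'g_double_prime'")
      viscoelastic_fluid(fl$g_prime, fl$g_double_prime, density = density,
                         name = fl$name %||% "fluid")
    },
    newtonian = {
      if (is.null(fl$mu))
        vf_stop("vf_usage_error", "newtonian fluid needs 'mu'")
      newtonian_fluid(fl$mu, density = density,
                      name = fl$name %||% "newtonian")
    },
    table = {
      if (is.null(fl$table_path))
        vf_stop("vf_usage_error", "table fluid needs 'table_path'")
      tp <- fl$table_path
      if (!file.exists(tp)) tp <- file.path(dir, fl$table_path)
      read_rheology_table(tp, density = density,
                          name = fl$name %||% basename(tp))
    },
    vf_stop("vf_usage_error", "unknown fluid.type '%s'", fl$type))

  pr <- raw$protocol
  if (is.null(pr) || is.null(pr$amplitude) || is.null(pr$omega))
    vf_stop("vf_usage_error",
            "config fields 'protocol.amplitude' and 'protocol.omega' are required")
  a_unit <- pr$amplitude_unit %||% "rad"
  o_unit <- pr$omega_unit %||% "rad_s"
  protocol <- rotation_protocol(pr$amplitude, pr$omega,
                                amplitude_unit = a_unit,
                                omega_unit = o_unit)
  if (a_unit == "deg")
    message(sprintf("protocol: amplitude %g deg -> %.17g rad",
                    pr$amplitude, protocol$amplitude))
  if (o_unit == "hz")
    message(sprintf("protocol: omega %g Hz -> %.17g rad/s",
                    pr$omega, protocol$omega))

  chamber <- chamber_spec(raw$chamber$radius %||% 0.0125)

  gen_defaults <- list(n_phases = 32L, n_repeats = 40L, noise_rel = 0.05,
                       seed = NULL, artifact = NULL, grid_step = NULL)
  gen <- utils::modifyList(gen_defaults, as.list(raw$generator %||% list()))
  if ((gen$noise_rel %||% 0) > 0 && is.null(gen$seed))
    vf_stop("vf_usage_error",
            "config field 'generator.seed' is required when noise_rel > 0")

  pipe_defaults <- list(n_r = 64L, n_theta = 96L, smooth_window = NULL)
  pipe <- utils::modifyList(pipe_defaults, as.list(raw$pipeline %||% list()))

  sweep <- NULL
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    o_unit <- sw$omega_unit %||% "rad_s"
    omega <- if (!is.null(sw$omega)) {
      as.numeric(sw$omega)
    } else {
      if (is.null(sw$from) || is.null(sw$to) || is.null(sw$n))
        vf_stop("vf_usage_error",
                "sweep needs 'omega' or 'from'/'to'/'n'")
      if (identical(sw$spacing, "log"))
        exp(seq(log(sw$from), log(sw$to), length.out = sw$n))
      else seq(sw$from, sw$to, length.out = sw$n)
    }
    if (o_unit == "hz") omega <- omega * 2 * pi
    sweep <- list(omega = omega, mode = sw$mode %||% "theoretical")
  }

  resolved <- list(fluid = fluid, protocol = protocol, chamber = chamber,
                   generator = gen, pipeline = pipe, sweep = sweep)
  resolved$hash <- settings_hash(
    jsonlite::toJSON(list(fluid = fluid[c("name", "density", "model")],
                          protocol = unclass(protocol),
                          chamber = unclass(chamber),
                          generator = gen, pipeline = pipe, sweep = sweep),
                     auto_unbox = TRUE, digits = NA, null = "null",
                     complex = "list"))
  structure(resolved, class = "run_config")
}

write_kv_report <- function(path, kv) {
  lines <- vapply(names(kv), function(nm) {
    v <- kv[[nm]]
    sprintf("%s\t%s", nm, paste(format(v, digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate and store a synthetic ensemble described by a configuration
#'
#' @param config a [read_run_config()] result (or path to one).
#' @param out_dir directory receiving the frame files and manifest.
#' @return \code{out_dir}, invisibly; the provenance (seed, settings
#'   hash) is echoed via \code{message()}.
#' @export
run_simulate <- function(config, out_dir) {
  config <- as_run_config(config)
  gen <- config$generator
  args <- list(fluid = config$fluid, protocol = config$protocol,
               chamber = config$chamber,
               n_phases = gen$n_phases, n_repeats = gen$n_repeats,
               noise_rel = gen$noise_rel, seed = gen$seed,
               artifact = gen$artifact)
  if (!is.null(gen$grid_step)) args$grid_step <- gen$grid_step
  set <- do.call(generate_ensemble, args)
  write_ensemble(set, out_dir)
  message(sprintf("simulate: wrote %d frames to %s (seed %s, settings %s)",
                  length(set$frames), out_dir,
                  if (is.null(set$seed)) "none" else set$seed,
                  config$hash))
  invisible(out_dir)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1L)
    return(read_run_config(config))
  vf_stop("vf_usage_error", "config must be a run_config or a file path")
}

#' Analyze a stored ensemble and write result tables
#'
#' Runs the full chain (ensemble average, polar decomposition, azimuthal
#' average, harmonic fit, kinetic energy, normalized energy, maximum
#' strain) and writes four delimited-text outputs into \code{out_dir}:
#' \code{profile.txt} (r, re_g, im_g), \code{energy.txt} (phase, t, K),
#' \code{strain.txt} (r, gamma_max) and \code{report.txt} (key-value run
#' report with seed, settings hash, kbar, residual harmonic fraction and
#' warnings).
#'
#' @param ensemble_dir directory written by [run_simulate()] /
#'   [write_ensemble()].
#' @param config optional [read_run_config()] result (for pipeline
#'   settings); defaults are used when omitted.
#' @param out_dir output directory.
#' @return the [analyze_ensemble()] result, invisibly.
#' @export
run_analyze <- function(ensemble_dir, config = NULL, out_dir) {
  set <- read_ensemble(ensemble_dir)
  pipe <- if (is.null(config)) list(n_r = 64L, n_theta = 96L,
                                    smooth_window = NULL)
          else as_run_config(config)$pipeline
  res <- analyze_ensemble(set,
                          r_grid = default_r_grid(pipe$n_r),
                          theta_grid = default_theta_grid(pipe$n_theta),
                          smooth_window = pipe$smooth_window)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prof <- data.frame(r = res$profile$r, re_g = Re(res$profile$g),
                     im_g = Im(res$profile$g))
  write.table(prof, file.path(out_dir, "profile.txt"), row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(phase = seq_along(res$K), t = res$phases,
                         K = res$K),
              file.path(out_dir, "energy.txt"), row.names = FALSE,
              quote = FALSE)
  write.table(data.frame(r = res$strain$r, gamma_max = res$strain$gamma_max),
              file.path(out_dir, "strain.txt"), row.names = FALSE,
              quote = FALSE)
  hash <- if (is.null(config)) "default" else as_run_config(config)$hash
  write_kv_report(file.path(out_dir, "report.txt"), list(
    seed = set$seed %||% "none",
    settings_hash = hash,
    kbar = res$kbar,
    residual_fraction = res$residual_fraction,
    max_rel_std = max(res$rel_std),
    n_flagged_radii = sum(res$flagged),
    warn_rel_std_gt_5pct = any(res$rel_std > 0.05),
    warn_residual_gt_5pct = res$residual_fraction > 0.05))
  invisible(res)
}

#' Run a resonance scan described by a configuration
#'
#' @param config a [read_run_config()] with a \code{sweep} block.
#' @param out_file path of the delimited-text curve
#'   (\code{omega_rad_s kbar}); a companion \code{<out_file>.report.txt}
#'   records \code{omega_res} and the boundary flag.
#' @return the [resonance_scan()] result, invisibly.
#' @export
run_scan <- function(config, out_file) {
  config <- as_run_config(config)
  if (is.null(config$sweep))
    vf_stop("vf_usage_error", "config has no 'sweep' block")
  gen <- config$generator
  gen_over <- list(n_phases = gen$n_phases, n_repeats = gen$n_repeats,
                   noise_rel = gen$noise_rel, artifact = gen$artifact)
  if (!is.null(gen$grid_step)) gen_over$grid_step <- gen$grid_step
  scan <- resonance_scan(config$fluid, config$chamber,
                         amplitude = config$protocol$amplitude,
                         omega_list = config$sweep$omega,
                         mode = config$sweep$mode,
                         seed = gen$seed, generator = gen_over,
                         r_grid = default_r_grid(config$pipeline$n_r),
                         theta_grid = default_theta_grid(config$pipeline$n_theta))
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(omega_rad_s = scan$curve$omega,
                         kbar = scan$curve$kbar),
              out_file, row.names = FALSE, quote = FALSE)
  write_kv_report(paste0(out_file, ".report.txt"), list(
    settings_hash = config$hash,
    mode = scan$mode,
    omega_res_rad_s = scan$omega_res,
    kbar_max = max(scan$curve$kbar),
    peak_at_boundary = scan$peak_at_boundary))
  invisible(scan)
}

#' Compare a stored ensemble's fitted profile with the closed-form model
#'
#' Analyzes the ensemble, builds the theoretical [amplitude_profile()]
#' for the fluid and protocol recorded in the configuration (or the
#' ensemble manifest), and writes a per-phase RMS discrepancy table plus
#' overall figures.
#'
#' @param ensemble_dir ensemble directory.
#' @param config optional [read_run_config()]; when omitted the fluid is
#'   taken from the ensemble manifest.
#' @param out_file delimited-text output (\code{phase t rms}); overall
#'   rms/max go in \code{<out_file>.report.txt}.
#' @return the [compare_to_theory()] result, invisibly.
#' @export
run_compare <- function(ensemble_dir, config = NULL, out_file) {
  set <- read_ensemble(ensemble_dir)
  fluid <- if (!is.null(config)) as_run_config(config)$fluid else set$fluid
  if (is.null(fluid) && is.null(set$wavenumber))
    vf_stop("vf_usage_error",
            "no fluid available: supply a config with a fluid block")
  pipe <- if (is.null(config)) list(n_r = 64L, n_theta = 96L,
                                    smooth_window = NULL)
          else as_run_config(config)$pipeline
  res <- analyze_ensemble(set, r_grid = default_r_grid(pipe$n_r),
                          theta_grid = default_theta_grid(pipe$n_theta))
  k <- if (!is.null(fluid))
    complex_wavenumber(fluid, set$protocol$omega, set$chamber)
  else set$wavenumber
  model <- amplitude_profile(k, seq(0, 1, length.out = 257))
  cmp <- compare_to_theory(res$profile, model, phases = set$phases)
  per_phase <- vapply(set$phases, function(t0)
    compare_to_theory(res$profile, model, phases = t0)$rms, numeric(1))
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(phase = seq_along(set$phases), t = set$phases,
                         rms = per_phase),
              out_file, row.names = FALSE, quote = FALSE)
  write_kv_report(paste0(out_file, ".report.txt"), list(
    rms = cmp$rms, max_abs = cmp$max_abs, n_points = cmp$n_points))
  invisible(cmp)
}
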