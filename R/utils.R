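# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed errors so callers/tests can distinguish failure modes:
#   vf_domain_error      bad argument values (units, signs, empty sweeps)
#   vf_range_error       query outside a tabulated range
#   vf_degenerate_error  numerically/physically degenerate fluid or profile
#   vf_parse_error       malformed input files
#   vf_integrity_error   inconsistent ensembles / missing manifests
#   vf_resolution_error  grids too coarse for the requested statistic
#   vf_usage_error       bad run configuration
vf_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "vitreflow_error", "error", "condition")))
}

vf_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

is_uniform_grid <- function(x, tol = 1e-9) {
  if (length(x) < 3L) return(TRUE)
  h <- diff(x)
  max(abs(h - h[1])) <= tol * max(abs(h))
}

# Composite quadrature on a strictly increasing grid. Uses Simpson's rule
# when the grid is uniform with an odd number of nodes (needed so that the
# rigid-body integrand r^3 is integrated exactly and the purely viscous
# energy bound stays strict), trapezoid otherwise.
quad_grid <- function(x, y) {
  n <- length(x)
  if (n %% 2L == 1L && is_uniform_grid(x)) {
    h <- (x[n] - x[1]) / (n - 1L)
    w <- rep(c(2, 4), length.out = n)
    w[1] <- 1
    w[n] <- 1
    h / 3 * sum(w * y)
  } else {
    pracma::trapz(x, y)
  }
}

# Deterministic 31-bit rolling hash of a string, returned as 8 hex digits.
# Used only to tag run reports with a settings fingerprint.
settings_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  m <- 2147483647  # 2^31 - 1, keeps products exact in double arithmetic
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}
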