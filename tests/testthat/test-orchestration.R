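write_config <- function(dir, ...) {
  cfg <- utils::modifyList(list(
    fluid = list(type = "constant", g_prime = 10, g_double_prime = 2),
    protocol = list(amplitude = 0.035, omega = 36),
    generator = list(n_phases = 8, n_repeats = 2, noise_rel = 0, seed = 5),
    pipeline = list(n_r = 32, n_theta = 48)), list(...))
  path <- tempfile("config", tmpdir = dir, fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null")
  path
}

test_that("configs resolve units exactly and demand seeds for noisy runs", {
  d <- withr::local_tempdir()
  p <- write_config(d, protocol = list(amplitude = 2, amplitude_unit = "deg",
                                       omega = 5, omega_unit = "hz"))
  cfg <- suppressMessages(read_run_config(p))
  expect_identical(cfg$protocol$amplitude, 2 * pi / 180)
  expect_identical(cfg$protocol$omega, 10 * pi)
  expect_equal(cfg$chamber$radius, 0.0125)
  p2 <- write_config(d, generator = list(noise_rel = 0.05, seed = NULL))
  expect_error(read_run_config(p2), "seed", class = "vf_usage_error")
  p3 <- write_config(d, fluid = list(type = "table"))
  expect_error(read_run_config(p3), "table_path", class = "vf_usage_error")
  # settings fingerprint is a pure function of the resolved settings
  expect_identical(suppressMessages(read_run_config(p))$hash, cfg$hash)
  expect_false(identical(read_run_config(write_config(d))$hash, cfg$hash))
})

test_that("simulate writes the declared frame count and is seed-stable", {
  d <- withr::local_tempdir()
  cfg <- read_run_config(write_config(
    d, generator = list(n_phases = 4, n_repeats = 2, noise_rel = 0.05,
                        seed = 5)))
  e1 <- file.path(d, "e1"); e2 <- file.path(d, "e2")
  suppressMessages(run_simulate(cfg, e1))
  suppressMessages(run_simulate(cfg, e2))
  frames <- list.files(e1, pattern = "^frame_")
  expect_length(frames, 8L)
  expect_true(file.exists(file.path(e1, "manifest.json")))
  for (f in frames)
    expect_identical(readLines(file.path(e1, f)),
                     readLines(file.path(e2, f)))
  # Hz input lands in the manifest in rad/s
  cfg2 <- suppressMessages(read_run_config(write_config(
    d, protocol = list(amplitude = 0.035, omega = 5, omega_unit = "hz"),
    generator = list(n_phases = 4, n_repeats = 1, noise_rel = 0))))
  e3 <- file.path(d, "e3")
  suppressMessages(run_simulate(cfg2, e3))
  man <- jsonlite::read_json(file.path(e3, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$omega_rad_s, 10 * pi)
})

test_that("analyze closes the rigid-body loop and surfaces fit errors", {
  d <- withr::local_tempdir()
  # stiff elastic fluid: k ~ 1e-4, effectively rigid rotation
  cfg <- read_run_config(write_config(
    d, fluid = list(type = "constant", g_prime = 1e12, g_double_prime = 10),
    generator = list(n_phases = 24, n_repeats = 2, noise_rel = 0)))
  ens <- file.path(d, "ens")
  out <- file.path(d, "out")
  suppressMessages(run_simulate(cfg, ens))
  res <- run_analyze(ens, cfg, out)
  expect_equal(res$kbar, 1, tolerance = 0.02)
  expect_true(max(res$strain$gamma_max) <= 1e-6)
  expect_true(all(file.exists(file.path(out, c("profile.txt", "energy.txt",
                                               "strain.txt",
                                               "report.txt")))))
  rep_lines <- readLines(file.path(out, "report.txt"))
  expect_true(any(grepl("^kbar\t", rep_lines)))
  expect_true(any(grepl("^seed\t", rep_lines)))
  # an ensemble with too few phases for the harmonic fit errors out
  cfg2 <- read_run_config(write_config(
    d, generator = list(n_phases = 4, n_repeats = 2, noise_rel = 0)))
  ens2 <- file.path(d, "ens2")
  suppressMessages(run_simulate(cfg2, ens2))
  expect_error(run_analyze(ens2, cfg2, file.path(d, "out2")),
               "8 phases", class = "vf_domain_error")
})

test_that("artifact sectors barely move the analyzed energy (noise-free)", {
  d <- withr::local_tempdir()
  base <- read_run_config(write_config(
    d, generator = list(n_phases = 12, n_repeats = 2, noise_rel = 0)))
  with_art <- read_run_config(write_config(
    d, generator = list(n_phases = 12, n_repeats = 2, noise_rel = 0,
                        artifact = TRUE)))
  e1 <- file.path(d, "a"); e2 <- file.path(d, "b")
  suppressMessages(run_simulate(base, e1))
  suppressMessages(run_simulate(with_art, e2))
  r1 <- run_analyze(e1, base, file.path(d, "oa"))
  r2 <- run_analyze(e2, with_art, file.path(d, "ob"))
  expect_lt(abs(r1$kbar - r2$kbar) / r1$kbar, 0.01)
})

test_that("scan runs from config and flags all-subresonant sweeps", {
  d <- withr::local_tempdir()
  cfg <- read_run_config(write_config(
    d, sweep = list(from = 20, to = 60, n = 11, mode = "theoretical")))
  scan <- run_scan(cfg, file.path(d, "curve.txt"))
  expect_false(scan$peak_at_boundary)
  om1 <- natural_frequencies(cfg$fluid, cfg$chamber, 1)
  expect_lt(abs(scan$omega_res - om1) / om1, 0.1)
  curve <- read.table(file.path(d, "curve.txt"), header = TRUE)
  expect_identical(names(curve), c("omega_rad_s", "kbar"))
  expect_equal(nrow(curve), 11L)
  low <- run_scan(read_run_config(write_config(
    d, sweep = list(from = 5, to = 25, n = 6))), file.path(d, "low.txt"))
  expect_true(low$peak_at_boundary)
  expect_error(run_scan(read_run_config(write_config(d)),
                        file.path(d, "x.txt")),
               class = "vf_usage_error")
})

test_that("compare pits the fitted profile against the recorded model", {
  d <- withr::local_tempdir()
  cfg <- read_run_config(write_config(
    d, generator = list(n_phases = 16, n_repeats = 2, noise_rel = 0),
    pipeline = list(n_r = 64, n_theta = 96)))
  ens <- file.path(d, "ens")
  suppressMessages(run_simulate(cfg, ens))
  cmp <- run_compare(ens, cfg, file.path(d, "cmp.txt"))
  expect_lt(cmp$max_abs, 1e-2)
  tab <- read.table(file.path(d, "cmp.txt"), header = TRUE)
  expect_equal(nrow(tab), 16L)
  expect_true(all(tab$rms >= 0))
})
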