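test_that("noise-free rigid-limit frames are solid-body rotation", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 30)
  set <- generate_ensemble(NULL, pr, ch, n_phases = 8, n_repeats = 1,
                           noise_rel = 0, wavenumber = 1e-6 + 0i)
  A <- pr$amplitude; om <- pr$omega
  for (p in c(1, 3, 6)) {
    fr <- set$frames[[(p - 1) * 1 + 1]]
    Omega <- A * om * cos(om * fr$time)
    xm <- matrix(fr$x, length(fr$x), length(fr$y))
    ym <- matrix(fr$y, length(fr$x), length(fr$y), byrow = TRUE)
    ok <- fr$mask
    expect_equal(fr$vx[ok], (-Omega * ym)[ok], tolerance = 1e-6)
    expect_equal(fr$vy[ok], (Omega * xm)[ok], tolerance = 1e-6)
  }
})

test_that("identical seeds reproduce ensembles bit for bit", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  s1 <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4, n_repeats = 3,
                          noise_rel = 0.05, seed = 42)
  s2 <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4, n_repeats = 3,
                          noise_rel = 0.05, seed = 42)
  for (i in seq_along(s1$frames)) {
    expect_identical(s1$frames[[i]]$vx, s2$frames[[i]]$vx)
    expect_identical(s1$frames[[i]]$vy, s2$frames[[i]]$vy)
  }
  s3 <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4, n_repeats = 3,
                          noise_rel = 0.05, seed = 43)
  expect_false(identical(s1$frames[[1]]$vx, s3$frames[[1]]$vx))
  # generation does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1)
  invisible(generate_ensemble(ref_fluid(), pr, ch, n_phases = 4,
                              n_repeats = 2, noise_rel = 0.05, seed = 9))
  expect_identical(runif(1), a)
})

test_that("noise realizes the prescribed per-component standard deviation", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  set <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4,
                           n_repeats = 40, noise_rel = 0.05, seed = 11)
  clean <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4,
                             n_repeats = 1, noise_rel = 0)
  for (p in 1:2) {
    fr0 <- clean$frames[[p]]
    ok <- fr0$mask
    target <- 0.05 * mean(sqrt(fr0$vx[ok]^2 + fr0$vy[ok]^2))
    devs <- sapply(1:40, function(rep) {
      fr <- set$frames[[(p - 1) * 40 + rep]]
      c(fr$vx[ok] - fr0$vx[ok], fr$vy[ok] - fr0$vy[ok])
    })
    expect_equal(sd(as.vector(devs)), target, tolerance = 0.1)
  }
})

test_that("ensemble mean converges to the noise-free field like 1/sqrt(n)", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  clean <- generate_ensemble(ref_fluid(), pr, ch, grid_step = ch$radius / 12,
                             n_phases = 4, n_repeats = 1, noise_rel = 0)
  mad_of <- function(n_rep, seed) {
    s <- generate_ensemble(ref_fluid(), pr, ch, grid_step = ch$radius / 12,
                           n_phases = 4, n_repeats = n_rep,
                           noise_rel = 0.05, seed = seed)
    m <- suppressWarnings(ensemble_average(s))
    mean(abs(m$frames[[1]]$vx[clean$frames[[1]]$mask] -
               clean$frames[[1]]$vx[clean$frames[[1]]$mask]))
  }
  m40 <- mad_of(40, 5)
  m400 <- mad_of(400, 5)
  expect_equal(m40 / m400, sqrt(10), tolerance = 0.35)
})

test_that("phases half a period apart are exact negatives (noise-free)", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  set <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 8, n_repeats = 1,
                           noise_rel = 0)
  for (p in 1:4) {
    a <- set$frames[[p]]; b <- set$frames[[p + 4]]
    expect_equal(b$vx[a$mask], -a$vx[a$mask], tolerance = 1e-12)
    expect_equal(b$vy[a$mask], -a$vy[a$mask], tolerance = 1e-12)
  }
})

test_that("artifact sectors mask the requested wedge only", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  set <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4, n_repeats = 1,
                           noise_rel = 0, artifact = TRUE)
  none <- generate_ensemble(ref_fluid(), pr, ch, n_phases = 4, n_repeats = 1,
                            noise_rel = 0)
  fr <- set$frames[[1]]; fr0 <- none$frames[[1]]
  xm <- matrix(fr$x, length(fr$x), length(fr$y))
  ym <- matrix(fr$y, length(fr$x), length(fr$y), byrow = TRUE)
  th <- atan2(ym, xm)
  inside <- fr0$mask
  in_sector <- abs(th) <= 7.5 * pi / 180
  expect_true(all(!fr$mask[inside & in_sector]))
  expect_true(all(fr$mask[inside & !in_sector]))
  # unmasked values are untouched by the artifact
  expect_identical(fr$vx[fr$mask], fr0$vx[fr$mask])
  expect_error(generate_ensemble(ref_fluid(), pr, ch, n_phases = 4,
                                 n_repeats = 1, noise_rel = 0,
                                 artifact = list(type = "blob")),
               class = "vf_usage_error")
})

test_that("generator preconditions are enforced", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  expect_error(generate_ensemble(ref_fluid(), pr, ch,
                                 grid_step = ch$radius / 5, n_repeats = 1),
               class = "vf_resolution_error")
  expect_error(generate_ensemble(ref_fluid(), pr, ch, n_phases = 3,
                                 n_repeats = 1),
               class = "vf_domain_error")
  expect_error(generate_ensemble(ref_fluid(), pr, ch, n_phases = 4,
                                 n_repeats = 2, noise_rel = 0.05),
               class = "vf_usage_error")  # noisy run without a seed
})

test_that("ensembles round-trip through the directory format exactly", {
  ch <- ref_chamber()
  pr <- rotation_protocol(0.035, 36)
  set <- generate_ensemble(ref_fluid(), pr, ch, grid_step = ch$radius / 11,
                           n_phases = 4, n_repeats = 2, noise_rel = 0.05,
                           seed = 3)
  d <- withr::local_tempdir()
  write_ensemble(set, d)
  set2 <- read_ensemble(d)
  expect_identical(set2$n_phases, set$n_phases)
  for (i in seq_along(set$frames)) {
    expect_identical(set2$frames[[i]]$vx, set$frames[[i]]$vx)
    expect_identical(set2$frames[[i]]$vy, set$frames[[i]]$vy)
    expect_identical(set2$frames[[i]]$mask, set$frames[[i]]$mask)
  }
  expect_equal(set2$fluid$model$g_prime, 10)
  expect_equal(set2$protocol$omega, 36)

  # corruption cases
  file.remove(file.path(d, "manifest.json"))
  expect_error(read_ensemble(d), class = "vf_integrity_error")
  write_ensemble(set, d)
  file.remove(file.path(d, "frame_p002_r002.txt"))
  expect_error(read_ensemble(d), "mismatch", class = "vf_integrity_error")
  write_ensemble(set, d)
  # unmasking the corner vector (outside the disc) violates the invariant
  f1 <- file.path(d, "frame_p001_r001.txt")
  lines <- readLines(f1)
  stopifnot(grepl(" 0$", lines[3]))  # corner (-R, -R) is masked
  lines[3] <- sub(" 0$", " 1", lines[3])
  writeLines(lines, f1)
  expect_error(read_ensemble(d), "outside the disc",
               class = "vf_integrity_error")
})
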