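test_that("spherical_j1 matches direct evaluation, series and root oracle", {
  expect_equal(spherical_j1(0), 0 + 0i)
  expect_equal(spherical_j1(2), as.complex(sin(2) / 4 - cos(2) / 2),
               tolerance = 1e-15)
  # series and closed form agree on the matching annulus
  z <- complex(modulus = seq(1e-3, 1e-1, length.out = 41),
               argument = seq(0, 2 * pi, length.out = 41))
  closed <- j1_direct(z)
  expect_true(max(Mod(spherical_j1(z) - closed)) < 1e-12)
  # value at the first positive root found by an independent bisection
  lam1 <- lambda1_oracle()
  expect_lt(Mod(spherical_j1(lam1)), 1e-10)
  expect_error(spherical_j1(Inf), class = "vf_domain_error")
})

test_that("complex wavenumber honours k^2 = rho w^2 R^2 / G* and its branch", {
  ch <- ref_chamber()
  # purely elastic fluid at its first natural frequency gives k = lambda1
  lam1 <- lambda1_oracle()
  fe <- viscoelastic_fluid(g_prime = 10, g_loss = 0)
  om1 <- lam1 * sqrt(10 / 1000) / 0.0125
  expect_equal(complex_wavenumber(fe, om1, ch), as.complex(lam1),
               tolerance = 1e-12)
  # Newtonian: k = M exp(-i pi/4), M = sqrt(rho w R^2 / mu)
  fn <- newtonian_fluid(mu = 1, density = 1000)
  k <- complex_wavenumber(fn, 10, ch)
  M <- sqrt(1000 * 10 * 0.0125^2 / 1)
  expect_equal(k, M * exp(-1i * pi / 4), tolerance = 1e-12)
  expect_equal(M, 1.25)
  # scaling symmetry: G* x 4 halves k
  f1 <- viscoelastic_fluid(10, 2)
  f4 <- viscoelastic_fluid(40, 8)
  expect_equal(complex_wavenumber(f4, 30, ch),
               complex_wavenumber(f1, 30, ch) / 2, tolerance = 1e-12)
  expect_true(Re(complex_wavenumber(f1, 30, ch)) > 0)
})

test_that("amplitude profile satisfies no-slip, centre and rigid limits", {
  ks <- list(complex_wavenumber(ref_fluid(), 30, ref_chamber()),
             complex_wavenumber(ref_fluid(), 50, ref_chamber()),
             complex_wavenumber(newtonian_fluid(1), 10, ref_chamber()))
  for (k in ks) {
    p <- amplitude_profile(k)
    expect_equal(2 * Mod(p$g[length(p$g)]), 1, tolerance = 1e-10)
    expect_equal(p$g[1], 0 + 0i)
  }
  # k -> 0: rigid-body rotation g = r/2
  p <- amplitude_profile(1e-6 + 0i)
  expect_true(max(Mod(p$g - p$r / 2)) < 1e-6)
  # profile is invariant under the k -> -k branch flip (j1 is odd)
  k <- complex_wavenumber(ref_fluid(), 40, ref_chamber())
  expect_equal(amplitude_profile(-k)$g, amplitude_profile(k)$g,
               tolerance = 1e-12)
})

test_that("interior amplification exceeds the wall near resonance", {
  ch <- ref_chamber()
  f <- ref_fluid()
  om1 <- natural_frequencies(f, ch, 1)
  k <- complex_wavenumber(f, om1, ch)
  p <- amplitude_profile(k, seq(0, 1, length.out = 513))
  expect_gt(max(2 * Mod(p$g)), 2 * (2 * Mod(p$g[513])))
})

test_that("Newtonian profiles peak at the wall when nearly rigid", {
  ch <- ref_chamber()
  for (mu in c(5, 20)) {
    om <- mu / (1000 * 0.0125^2)  # rho w R^2 / mu = 1
    k <- complex_wavenumber(newtonian_fluid(mu), om, ch)
    p <- amplitude_profile(k)
    expect_equal(which.max(2 * Mod(p$g)), length(p$g))
  }
})

test_that("natural frequencies follow lambda_n sqrt(G'/rho)/R", {
  ch <- ref_chamber()
  f <- ref_fluid()
  lam1 <- lambda1_oracle()
  om <- natural_frequencies(f, ch, 3)
  expect_equal(om[1], lam1 * 0.1 / 0.0125, tolerance = 1e-9)
  expect_equal(length(om), 3L)
  expect_true(all(diff(om) > 0))
  # doubling R halves every natural frequency
  om2 <- natural_frequencies(f, chamber_spec(0.025), 3)
  expect_equal(om2, om / 2, tolerance = 1e-12)
  expect_error(natural_frequencies(newtonian_fluid(1), ch),
               class = "vf_degenerate_error")
})

test_that("theoretical kbar reproduces hand integrals and limits", {
  r <- seq(0, 1, length.out = 257)
  expect_equal(theoretical_kbar(harmonic_profile(r, r / 2)), 1,
               tolerance = 1e-12)
  expect_equal(theoretical_kbar(harmonic_profile(r, rep(0i, 257))), 0)
  # g = r^2/2: 16 * int r^5/4 dr = 2/3
  expect_equal(theoretical_kbar(harmonic_profile(r, r^2 / 2)), 2 / 3,
               tolerance = 1e-6)
  expect_error(theoretical_kbar(harmonic_profile(seq(0, 1, length.out = 5),
                                                 seq(0, 1, length.out = 5))),
               class = "vf_resolution_error")
  # rigid limit: kbar -> 1 as k -> 0
  expect_equal(theoretical_kbar(amplitude_profile(1e-6 + 0i)), 1,
               tolerance = 1e-10)
})

test_that("purely viscous fluids never reach kbar = 1", {
  ch <- ref_chamber()
  for (mu in c(0.1, 1, 10))
    for (om in exp(seq(log(1), log(100), length.out = 12))) {
      k <- complex_wavenumber(newtonian_fluid(mu), om, ch)
      expect_lt(theoretical_kbar(amplitude_profile(k)), 1)
    }
})

test_that("strain profiles match hand and analytic derivatives", {
  r <- seq(0, 1, length.out = 101)
  A <- 0.035
  # rigid rotation shears nothing
  s <- theoretical_strain(harmonic_profile(r, r / 2), A)
  expect_true(all(s$gamma_max < 1e-12))
  # g = r^2/2 -> gamma = A r / 2
  s2 <- theoretical_strain(harmonic_profile(r, r^2 / 2), A)
  expect_equal(s2$gamma_max, A * r / 2, tolerance = 1e-3)
  # finite differences vs analytic j1 derivative at resonance
  ch <- ref_chamber()
  f <- ref_fluid()
  om1 <- natural_frequencies(f, ch, 1)
  k <- complex_wavenumber(f, om1, ch)
  rg <- seq(0, 1, length.out = 257)
  p <- amplitude_profile(k, rg)
  s3 <- theoretical_strain(p, A)
  j1k <- j1_direct(k)
  j0 <- function(z) sin(z) / z
  dg_exact <- k * (j0(k * rg) - 2 * j1_direct(k * rg) / (k * rg)) / (2 * j1k)
  dg_exact[1] <- k / (6 * j1k)  # j1'(0) = 1/3
  g_over_r <- p$g / rg
  g_over_r[1] <- dg_exact[1]
  gamma_exact <- A * Mod(dg_exact - g_over_r)
  i_chk <- which(gamma_exact > 0.05 * max(gamma_exact))
  expect_lt(max(abs(s3$gamma_max[i_chk] - gamma_exact[i_chk]) /
                  gamma_exact[i_chk]), 0.01)
})

test_that("saccades map to omega = pi over duration", {
  expect_equal(saccade_equivalent_frequency(1), pi)
  expect_equal(saccade_equivalent_frequency(0.1), 10 * pi)
  expect_equal(saccade_equivalent_frequency(0.05), 20 * pi)
  expect_error(saccade_equivalent_frequency(0), class = "vf_domain_error")
})

test_that("rotation protocols convert degrees and hertz exactly", {
  p <- rotation_protocol(2, 5, amplitude_unit = "deg", omega_unit = "hz")
  expect_identical(p$amplitude, 2 * pi / 180)
  expect_identical(p$omega, 5 * 2 * pi)
  expect_error(rotation_protocol(-1, 10), class = "vf_domain_error")
  expect_error(rotation_protocol(0.1, 0), class = "vf_domain_error")
})
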