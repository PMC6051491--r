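test_that("pseudo-Voigt bands integrate to their nominal area", {
  w <- seq(1000, 2300, by = 0.1)
  for (mix in c(0, 0.5, 1)) {
    y <- pseudo_voigt(w, 1650, 15, 42, mix)
    area <- sum(diff(w) * (head(y, -1) + tail(y, -1)) / 2)
    tol <- if (mix > 0) 0.02 else 1e-3  # Lorentzian tails decay slowly
    expect_lt(abs(area - 42) / 42, tol)
  }
  # single narrow mixed band over a wide grid: within 0.1% as a generator check
  p <- raman_sim_params(band_centers = 1650, band_widths = 10, band_areas = 20,
                        mixing_fractions = 0, baseline_intercept = 0,
                        wavenumber_grid = seq(1200, 2100, by = 0.1))
  sp <- simulate_raman(p)$spectrum
  area <- sum(diff(sp$wavenumber) *
                (head(sp$intensity, -1) + tail(sp$intensity, -1)) / 2)
  expect_lt(abs(area - 20) / 20, 0.001)
})

test_that("simulation parameters are validated", {
  expect_error(raman_sim_params(band_centers = c(1650, 1600)), "increasing")
  expect_error(raman_sim_params(band_areas = c(1, 1, 1, 1, 1, -2)), "band_areas")
  expect_error(raman_sim_params(wavenumber_grid = seq(1600, 1800, 1)),
               "does not cover")
})

test_that("noiseless six-band spectra are decomposed essentially exactly", {
  sim <- simulate_raman(raman_sim_params())
  fit <- fit_bands(sim)
  expect_lt(fit$relative_residual, 1e-6)
  expect_equal(fit$bands$center, sim$bands$center, tolerance = 1e-4)
  expect_equal(fit$bands$area, sim$bands$area, tolerance = 1e-2)
  ss <- secondary_structure(fit)
  expect_equal(ss$alpha_pct, 50, tolerance = 0.01)
  expect_equal(ss$coil_pct, 30, tolerance = 0.01)
  expect_equal(ss$beta_pct, 20, tolerance = 0.01)
})

test_that("fit_bands refuses a spectrum that does not cover 1500-1800", {
  p <- raman_sim_params(wavenumber_grid = seq(1500, 1810, 0.5))
  sim <- simulate_raman(p)
  trunc <- sim$spectrum[sim$spectrum$wavenumber >= 1600, ]
  expect_error(fit_bands(trunc), "1500-1800")
})

test_that("structure percentages normalize the three structural bands and sum to 100", {
  bands <- data.frame(center = c(1650, 1670, 1680), area = c(5, 3, 2))
  ss <- secondary_structure(bands)
  expect_equal(c(ss$alpha_pct, ss$coil_pct, ss$beta_pct), c(50, 30, 20))
  eq <- secondary_structure(data.frame(center = c(1650, 1670, 1680),
                                       area = c(4, 4, 4)))
  expect_equal(eq$alpha_pct, 100 / 3, tolerance = 1e-12)
  # side-chain bands are excluded from the normalization
  all6 <- simulate_raman(raman_sim_params())$bands
  ss6 <- secondary_structure(all6)
  expect_equal(ss6$alpha_pct + ss6$coil_pct + ss6$beta_pct, 100, tolerance = 1e-9)
  expect_equal(ss6$coil_pct, 30)
  expect_error(secondary_structure(data.frame(center = c(1550, 1580),
                                              area = c(1, 1))),
               "structural")
})

test_that("band areas are scale-equivariant; structure and doublet ratios invariant", {
  sim <- simulate_raman(raman_sim_params(noise_sd = 0))
  scaled <- sim
  scaled$spectrum$intensity <- 7 * sim$spectrum$intensity
  f1 <- fit_bands(sim)
  f7 <- fit_bands(scaled)
  expect_equal(f7$bands$area, 7 * f1$bands$area, tolerance = 1e-4)
  s1 <- secondary_structure(f1)
  s7 <- secondary_structure(f7)
  expect_equal(s7$coil_pct, s1$coil_pct, tolerance = 1e-6)
  t1 <- tyr_doublet(tyr_spectrum(1.2))
  sp2 <- tyr_spectrum(1.2)
  sp2$spectrum$intensity <- 3 * sp2$spectrum$intensity
  t2 <- tyr_doublet(sp2)
  expect_equal(t2$ratio, t1$ratio, tolerance = 1e-6)
})

test_that("noisy decomposition recovers planted structural fractions", {
  base <- simulate_raman(raman_sim_params())
  noise <- 0.01 * max(base$spectrum$intensity)
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_raman(raman_sim_params(noise_sd = noise, seed = s))
    ss <- secondary_structure(fit_bands(sim))
    if (abs(ss$coil_pct - 30) <= 3) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Tyr doublet ratio and hydrogen-bonding classification behave as specified", {
  eq <- tyr_doublet(tyr_spectrum(1.0))
  expect_equal(eq$ratio, 1.0, tolerance = 1e-3)
  for (s in 1:5) {
    td <- tyr_doublet(tyr_spectrum(1.2, noise_frac = 0.02, seed = s))
    expect_gt(td$ratio, 1.1)
    expect_lt(td$ratio, 1.3)
    expect_identical(td$classification, "exposed")
  }
  bur <- tyr_doublet(tyr_spectrum(0.75))
  expect_equal(bur$ratio, 0.75, tolerance = 1e-3)
  expect_identical(bur$classification, "buried")
  amb <- tyr_doublet(tyr_spectrum(0.95))
  expect_identical(amb$classification, "ambiguous")
  # missing 830 peak: undefined ratio signal
  lone <- raman_sim_params(band_centers = 850, band_widths = 10, band_areas = 10,
                           mixing_fractions = 0.5,
                           wavenumber_grid = seq(795, 885, 0.5))
  expect_error(tyr_doublet(simulate_raman(lone)), "undefined")
  short <- tyr_spectrum(1.0)
  expect_error(tyr_doublet(short$spectrum[short$spectrum$wavenumber > 820, ]),
               "800-880")
})
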