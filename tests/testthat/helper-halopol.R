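# Shared fixture builders. Everything is generated in code at test time.

# Clean piecewise trace in nm: ramp / plateau / ramp, no noise, no drift.
make_ramp_pause_ramp <- function(rate_bases_s = 460, pause_s = 5,
                                 seg_s = c(5, 5), dt = 0.5,
                                 calibration = 3.76) {
  t1 <- seq(0, seg_s[1], by = dt)
  p <- seq(dt, pause_s, by = dt)
  t2 <- seq(dt, seg_s[2], by = dt)
  pos <- c(rate_bases_s * t1,
           rep(rate_bases_s * seg_s[1], length(p)),
           rate_bases_s * seg_s[1] + rate_bases_s * t2)
  tt <- seq(0, by = dt, length.out = length(pos))
  fs_trace("toy", "reaction", tt, pos / calibration, "nm")
}

# Small halophilic-parameter-set simulation used by several tests.
halo_sim <- function(seed = 1, n_rxn = 6) {
  simulate_traces(trace_sim_params(seed = seed, n_reaction_traces = n_rxn))
}

# Tyr-doublet spectrum with a planted area ratio.
tyr_spectrum <- function(ratio, noise_frac = 0, seed = 1, a830 = 10) {
  peak <- pseudo_voigt(830, 830, 10, a830, 0.5) + 0.2
  p <- raman_sim_params(band_centers = c(830, 850), band_widths = c(10, 10),
                        band_areas = c(a830, a830 * ratio),
                        mixing_fractions = c(0.5, 0.5),
                        baseline_intercept = 0.2,
                        wavenumber_grid = seq(795, 885, by = 0.5),
                        noise_sd = noise_frac * peak, seed = seed)
  simulate_raman(p)
}

expect_tiling <- function(segmentation) {
  iv <- rbind(
    as.matrix(segmentation$pauses[, c("start_index", "end_index")]),
    as.matrix(segmentation$segments[, c("start_index", "end_index")]))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  expect_equal(iv[1, 1], 0L, ignore_attr = TRUE)
  expect_equal(iv[nrow(iv), 2], segmentation$n_samples, ignore_attr = TRUE)
  if (nrow(iv) > 1)
    expect_equal(unname(iv[-1, 1]), unname(iv[-nrow(iv), 2]))
}
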