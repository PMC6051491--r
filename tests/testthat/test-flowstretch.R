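test_that("drift correction cancels exactly-shared drift and needs controls", {
  tt <- seq(0, 60, by = 0.5)
  drift <- 20 * sin(2 * pi * tt / 37 + 0.4) + 5 * sin(2 * pi * tt / 11)
  ramp <- 3 * tt
  rxn <- fs_trace("r", "reaction", tt, ramp + drift, "nm")
  ctl <- fs_trace("c", "control", tt, drift, "nm")
  out <- correct_drift(rxn, ctl)
  # control is mean-centered before subtraction, so correction removes the
  # drift shape but leaves the ramp plus the drift's (removed) mean offset
  expect_equal(out$extension, ramp + mean(drift), tolerance = 1e-10)
  expect_error(correct_drift(rxn, list()), "control")
  bad <- fs_trace("c2", "control", tt + 0.25, drift, "nm")
  expect_error(correct_drift(rxn, bad), "grid")
})

test_that("zero controls after centering leave the reaction unchanged", {
  tt <- seq(0, 30, by = 0.5)
  rxn <- fs_trace("r", "reaction", tt, 2 * tt, "nm")
  ctl <- fs_trace("c", "control", tt, rep(7, length(tt)), "nm")
  out <- correct_drift(rxn, ctl)
  expect_equal(out$extension, rxn$extension, tolerance = 1e-12)
})

test_that("noisy controls suppress drift to below the noise scale", {
  set.seed(31)
  tt <- seq(0, 100, by = 0.5)
  drift <- 20 * sin(2 * pi * tt / 53 + 1) + 6 * sin(2 * pi * tt / 17)
  controls <- lapply(1:3, function(i)
    fs_trace(paste0("c", i), "control", tt, drift + rnorm(length(tt), 0, 2), "nm"))
  rxn <- fs_trace("r", "reaction", tt, drift, "nm")  # pure drift, no noise
  out <- correct_drift(rxn, controls)
  # residual = drift estimation error: control noise / sqrt(3) ~ 1.2 nm RMS
  expect_lt(sqrt(mean(out$extension^2)), 2)
})

test_that("to_bases multiplies by the calibration and flips the unit flag", {
  tt <- seq(0, 10, by = 0.5)
  tr <- fs_trace("t", "reaction", tt, seq(0, 100, length.out = length(tt)), "nm")
  tb <- to_bases(tr)
  expect_equal(max(tb$extension), 376)
  expect_equal(min(tb$extension), 0)
  expect_identical(tb$unit, "bases")
  expect_error(to_bases(tb), "already in bases")
  id <- to_bases(tr, calibration = 1)
  expect_equal(id$extension, tr$extension)
  expect_identical(id$unit, "bases")
})

test_that("noise sd estimation is accurate, slope-invariant and near zero on ramps", {
  set.seed(7)
  x <- rnorm(1e4, 0, 2)
  expect_gt(estimate_noise_sd(x), 1.9)
  expect_lt(estimate_noise_sd(x), 2.1)
  ramp <- seq(0, 500, length.out = 1000)
  expect_lt(estimate_noise_sd(ramp), 1e-9)
  for (slope in c(0, 5, 50, 500)) {
    set.seed(slope + 1)
    y <- slope * seq_len(2000) + rnorm(2000, 0, 2)
    expect_lt(abs(estimate_noise_sd(y) - 2) / 2, 0.1)
  }
  expect_error(estimate_noise_sd(rnorm(10)), "20 samples")
})

test_that("segmentation applies the 6-point / 3-sigma pause rule on a hand case", {
  # 7-point ramp (+50 bases/sample), 8 flat points (+-0.5), 5-point ramp
  set.seed(2)
  flat_noise <- runif(8, -0.5, 0.5)
  x <- c(seq(0, 300, by = 50), 300 + flat_noise,
         300 + seq(50, 250, by = 50))
  tt <- seq(0, by = 0.5, length.out = length(x))
  tr <- fs_trace("hand", "reaction", tt, x, "bases")
  tr$unit <- "bases"
  s <- segment_trace(tr, noise_sd = 1)
  expect_identical(nrow(s$pauses), 1L)
  expect_identical(nrow(s$segments), 2L)
  # the pause covers the 8 flat samples; the junction sample of the
  # preceding ramp sits at the plateau level, so it may join the pause
  expect_lte(s$pauses$start_index, 7)
  expect_gte(s$pauses$start_index, 6)
  expect_equal(s$pauses$end_index, 15)
  expect_error(segment_trace(tr, noise_sd = 0), "noise_sd")
})

test_that("monotone ramp yields one segment, flat trace one pause", {
  tt <- seq(0, 10, by = 0.5)
  ramp <- fs_trace("ramp", "reaction", tt, 100 * tt, "nm")
  ramp <- to_bases(ramp, 1)
  s1 <- segment_trace(ramp, noise_sd = 1)
  expect_identical(nrow(s1$pauses), 0L)
  expect_identical(nrow(s1$segments), 1L)
  expect_equal(s1$segments$rate, 100, tolerance = 1e-10)
  flat <- fs_trace("flat", "reaction", tt, rep(5, length(tt)), "nm")
  flat <- to_bases(flat, 1)
  s2 <- segment_trace(flat, noise_sd = 1)
  expect_identical(nrow(s2$pauses), 1L)
  expect_identical(nrow(s2$segments), 0L)
  expect_equal(s2$pauses$duration, max(tt) + 0.5)
  expect_error(segment_trace(fs_trace("u", "reaction", tt, 100 * tt, "nm")),
               "bases")
})

test_that("pauses and segments tile every trace without overlap", {
  sim <- halo_sim(seed = 21, n_rxn = 5)
  res <- suppressMessages(analyze_traces(sim))
  for (s in res$segmentations) expect_tiling(s)
})

test_that("segment boundaries match ground truth exactly on clean traces", {
  p <- trace_sim_params(noise_sd = 0, drift_amplitude = 0,
                        n_reaction_traces = 3, n_control_traces = 0, seed = 13)
  sim <- simulate_traces(p)
  for (tr in traces_by_role(sim, "reaction")) {
    tb <- to_bases(tr)
    s <- suppressMessages(segment_trace(tb, noise_sd = 1e-9))
    truth <- sim$truth[[tr$trace_id]]
    tp <- truth[truth$type == "pause", ]
    expect_equal(s$pauses$start_index, tp$start_index)
    expect_equal(s$pauses$end_index, tp$end_index)
    ts <- truth[truth$type == "segment", ]
    detected_long <- s$segments[s$segments$n_points > 0, ]
    sub <- ts$end_index - ts$start_index > 0
    expect_equal(detected_long$start_index, ts$start_index[sub])
    expect_equal(detected_long$length, ts$length[sub], tolerance = 1e-9)
  }
})

test_that("Gaussian rate fit equals sample moments with sd/sqrt(n) uncertainty", {
  expect_error(fit_rate_distribution(c(100)), "at least 2")
  r0 <- fit_rate_distribution(c(100, 100, 100))
  expect_equal(r0$mean, 100)
  expect_equal(r0$sd, 0)
  r1 <- fit_rate_distribution(c(90, 110))
  expect_equal(r1$mean, 100)
  set.seed(83)
  rates <- rnorm(83, 460, 35)
  fit <- fit_rate_distribution(rates)
  expect_equal(fit$mean, mean(rates))
  expect_equal(fit$sd, sd(rates))
  expect_equal(fit$fit_uncertainty, sd(rates) / sqrt(83))
  expect_lt(abs(fit$mean - 460), 12)  # 3 * 35 / sqrt(83)
})

test_that("exponential processivity fit is the (censored) maximum likelihood mean", {
  expect_equal(fit_processivity(rep(1000, 5))$mean, 1000)
  expect_equal(fit_processivity(c(1000, 3000))$mean, 2000)
  expect_error(fit_processivity(c(-5, 100)), "positive")
  set.seed(11)
  lens <- rexp(500, 1 / 2000)
  fit <- fit_processivity(lens)
  expect_equal(fit$mean, mean(lens))            # MLE = sample mean oracle
  expect_lt(abs(fit$mean - 2000) / 2000, 0.10)
  # right-censoring: censored MLE = sum(all) / n_uncensored
  cens <- c(500, 1500, 2500, 2500)
  f2 <- fit_processivity(cens, censor_at = 2500)
  expect_equal(f2$mean, sum(cens) / 2)
  expect_identical(f2$n_censored, 2L)
  f3 <- fit_processivity(cens, censored = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(f3$mean, f2$mean)
  expect_error(fit_processivity(cens, censor_at = 100), "censored")
})

test_that("censored exponential MLE is consistent under type-I censoring", {
  set.seed(99)
  true_mean <- 2000
  draws <- rexp(600, 1 / true_mean)
  cap <- 2500
  obs <- pmin(draws, cap)
  fit <- fit_processivity(obs, censor_at = cap)
  expect_lt(abs(fit$mean - true_mean) / true_mean, 0.10)
})

test_that("full pipeline recovers simulation parameters within 10%", {
  sim <- simulate_traces(trace_sim_params(seed = 8, n_reaction_traces = 20))
  res <- suppressMessages(analyze_traces(sim))
  expect_lt(abs(res$rate$mean - 460) / 460, 0.10)
  expect_lt(abs(res$processivity$mean - 2000) / 2000, 0.15)
  expect_gt(res$rate$n_segments, 40)
})
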