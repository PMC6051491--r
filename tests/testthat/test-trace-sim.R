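test_that("parameter validation names the offending field", {
  expect_error(trace_sim_params(sampling_interval = 0), "sampling_interval")
  expect_error(trace_sim_params(calibration = -1), "calibration")
  expect_error(trace_sim_params(noise_sd = -0.1), "noise_sd")
  expect_error(trace_sim_params(pause_probability = 1.5), "pause_probability")
})

test_that("noiseless constant-rate trace has slope rate/calibration in nm/s", {
  p <- trace_sim_params(rate_mean = 470, rate_sd = 0, noise_sd = 0,
                        drift_amplitude = 0, pause_probability = 0,
                        processivity_mean = 1e5, template_length = 1e6,
                        n_reaction_traces = 1, n_control_traces = 0, seed = 3)
  sim <- simulate_traces(p)
  tr <- sim$traces[[1]]
  truth <- sim$truth[[1]]
  seg <- truth[truth$type == "segment", ][1, ]
  idx <- (seg$start_index + 1):(seg$end_index)  # 1-based samples of the ramp
  slopes <- diff(tr$extension[idx]) / diff(tr$time[idx])
  expect_equal(slopes, rep(470 / 3.76, length(slopes)), tolerance = 1e-12)
})

test_that("true segment lengths average to the processivity mean (LLN)", {
  p <- trace_sim_params(processivity_mean = 1000, template_length = 5.5e5,
                        pause_duration_mean = 3, noise_sd = 0,
                        drift_amplitude = 0, n_reaction_traces = 1,
                        n_control_traces = 0, seed = 42)
  # one long template so ~500 independent draws are all complete
  sch <- local({
    sim <- simulate_traces(p)
    tr <- sim$truth[[1]]
    tr[tr$type == "segment" & !tr$censored, ]
  })
  lens <- utils::head(sch$length, 500)
  expect_gt(length(lens), 400)
  expect_lt(abs(mean(lens) - 1000) / 1000, 0.10)
})

test_that("generators are bit-reproducible and respect the template bound", {
  p <- trace_sim_params(seed = 9, n_reaction_traces = 4)
  s1 <- simulate_traces(p)
  s2 <- simulate_traces(p)
  expect_identical(s1, s2)
  for (tr in s1$truth) {
    expect_lte(sum(tr$length), p$template_length + 1e-9)
    # noiseless position is non-decreasing by construction; check truth table
    expect_true(all(tr$length >= 0))
  }
})

test_that("reaction traces are non-decreasing in the noiseless limit", {
  p <- trace_sim_params(noise_sd = 0, drift_amplitude = 0,
                        n_reaction_traces = 3, n_control_traces = 0, seed = 5)
  sim <- simulate_traces(p)
  for (tr in traces_by_role(sim, "reaction"))
    expect_true(all(diff(tr$extension) >= -1e-12))
})

test_that("simulation respects pause-duration floor and shared drift", {
  p <- trace_sim_params(seed = 2, n_reaction_traces = 3, noise_sd = 0,
                        drift_amplitude = 15)
  sim <- simulate_traces(p)
  for (tr in sim$truth) {
    pauses <- tr[tr$type == "pause", ]
    # all but the trailing plateau respect the 3-s floor
    body <- utils::head(pauses, -1)
    if (nrow(body)) expect_true(all(body$t_end - body$t_start >= 3 - 1e-9))
  }
  ctl <- traces_by_role(sim, "control")
  expect_true(all(abs(ctl[[1]]$extension) <= 15 + 1e-9))
})
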