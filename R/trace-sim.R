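#' Flow-stretching trace simulation parameters
#'
#' Bundles and validates the parameters of the single-molecule trajectory
#' generator. Defaults mirror the experimental constants of the assay:
#' 500-ms sampling, a ~7.2-kb ssDNA template, and the 3.76 b/nm
#' ssDNA-to-dsDNA extension calibration at ~3 pN drag force.
#'
#' @param rate_mean Mean per-segment synthesis rate (bases/s).
#' @param rate_sd Between-segment sd of the synthesis rate (bases/s).
#' @param processivity_mean Mean synthesis-segment length (bases); segment
#'   lengths are exponential with this mean.
#' @param pause_duration_mean Mean pause duration (s).
#' @param pause_duration_min Minimum pause duration (s). Pauses are
#'   offset-exponential, `min + Exp(mean - min)`, so that every pause spans at
#'   least `min/sampling_interval` samples and is resolvable by the 6-point
#'   pause detector. Set to 0 for a plain exponential.
#' @param pause_probability Probability that a pause follows a synthesis
#'   segment (default 1).
#' @param sampling_interval Sampling interval in seconds (default 0.5).
#' @param noise_sd Per-sample Gaussian localization noise, in nm.
#' @param drift_amplitude Peak amplitude of the shared slow drift, in nm.
#' @param template_length ssDNA template length in bases (default 7249).
#' @param calibration Conversion factor, bases per nm (default 3.76).
#' @param n_reaction_traces,n_control_traces Numbers of traces to simulate.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (params, seed).
#' @return An object of class `trace_sim_params` (a validated list).
#' @seealso [simulate_traces()]
#' @export
trace_sim_params <- function(rate_mean = 460, rate_sd = 35,
                             processivity_mean = 2000,
                             pause_duration_mean = 5,
                             pause_duration_min = 3,
                             pause_probability = 1,
                             sampling_interval = 0.5,
                             noise_sd = 2, drift_amplitude = 10,
                             template_length = 7249, calibration = 3.76,
                             n_reaction_traces = 25, n_control_traces = 3,
                             seed = 1L) {
  check_that(is.numeric(rate_mean) && rate_mean > 0, "rate_mean", "must be > 0")
  check_that(is.numeric(rate_sd) && rate_sd >= 0, "rate_sd", "must be >= 0")
  check_that(processivity_mean > 0, "processivity_mean", "must be > 0")
  check_that(pause_duration_mean >= 0, "pause_duration_mean", "must be >= 0")
  check_that(pause_duration_min >= 0, "pause_duration_min", "must be >= 0")
  check_that(pause_duration_mean >= pause_duration_min, "pause_duration_mean",
             "must be >= pause_duration_min")
  check_that(pause_probability >= 0 && pause_probability <= 1,
             "pause_probability", "must lie in [0, 1]")
  check_that(sampling_interval > 0, "sampling_interval", "must be > 0")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(drift_amplitude >= 0, "drift_amplitude", "must be >= 0")
  check_that(template_length > 0, "template_length", "must be > 0")
  check_that(calibration > 0, "calibration", "must be > 0")
  check_that(n_reaction_traces >= 1, "n_reaction_traces", "must be >= 1")
  check_that(n_control_traces >= 0, "n_control_traces", "must be >= 0")
  structure(list(
    rate_mean = rate_mean, rate_sd = rate_sd,
    processivity_mean = processivity_mean,
    pause_duration_mean = pause_duration_mean,
    pause_duration_min = pause_duration_min,
    pause_probability = pause_probability,
    sampling_interval = sampling_interval,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    template_length = template_length, calibration = calibration,
    n_reaction_traces = as.integer(n_reaction_traces),
    n_control_traces = as.integer(n_control_traces),
    seed = as.integer(seed)
  ), class = "trace_sim_params")
}

#' Construct a bead-extension trace
#'
#' @param trace_id Character identifier.
#' @param role `"reaction"` or `"control"`.
#' @param time Strictly increasing time grid with constant step (s).
#' @param extension Extension values, nm (or bases after [to_bases()]).
#' @param unit `"nm"` or `"bases"`.
#' @return An object of class `fs_trace`.
#' @export
fs_trace <- function(trace_id, role = c("reaction", "control"),
                     time, extension, unit = c("nm", "bases")) {
  role <- match.arg(role)
  unit <- match.arg(unit)
  check_that(length(time) == length(extension), "extension",
             "must match time in length")
  check_that(length(time) >= 2, "time", "needs at least 2 samples")
  dt <- diff(time)
  check_that(all(dt > 0), "time", "must be strictly increasing")
  check_that(diff(range(dt)) < 1e-6 * mean(dt) + 1e-12, "time",
             "must have a constant step")
  check_that(all(is.finite(extension)), "extension", "must be finite")
  structure(list(trace_id = as.character(trace_id), role = role,
                 time = as.numeric(time), extension = as.numeric(extension),
                 unit = unit),
            class = "fs_trace")
}

#' @export
print.fs_trace <- function(x, ...) {
  cat(sprintf("<fs_trace %s> role=%s n=%d dt=%.3gs unit=%s range=[%.3g, %.3g]\n",
              x$trace_id, x$role, length(x$time), diff(x$time[1:2]), x$unit,
              min(x$extension), max(x$extension)))
  invisible(x)
}

# Shared low-frequency drift: sum of 3 sinusoids whose amplitudes sum to
# drift_amplitude, so |drift| never exceeds it. Returns a function of time.
make_drift <- function(amplitude, t_max) {
  if (amplitude <= 0) return(function(t) rep(0, length(t)))
  k <- 3L
  w <- stats::runif(k)
  amps <- amplitude * w / sum(w)
  periods <- stats::runif(k, t_max / 4, t_max)
  phases <- stats::runif(k, 0, 2 * pi)
  function(t) {
    out <- numeric(length(t))
    for (i in seq_len(k)) out <- out + amps[i] * sin(2 * pi * t / periods[i] + phases[i])
    out
  }
}

# Draw the event schedule (alternating synthesis segments and pauses) for one
# reaction trace. Intended burst lengths are iid exponential draws; the draw
# that overruns the template is clipped at the template end (and flagged
# censored), after which the trace plateaus. Cumulative synthesis therefore
# never exceeds template_length, and every uncensored emitted length is an
# untruncated exponential draw.
draw_schedule <- function(p) {
  seg <- list(); t <- 0; pos <- 0
  repeat {
    len <- stats::rexp(1, rate = 1 / p$processivity_mean)
    censored <- pos + len > p$template_length
    if (censored) len <- p$template_length - pos
    rate <- stats::rnorm(1, p$rate_mean, p$rate_sd)
    while (rate <= 0) rate <- stats::rnorm(1, p$rate_mean, p$rate_sd)
    t1 <- t + len / rate
    seg[[length(seg) + 1L]] <- list(type = "segment", t_start = t, t_end = t1,
                                    rate = rate, length = len,
                                    censored = censored,
                                    pos_start = pos, pos_end = pos + len)
    pos <- pos + len
    t <- t1
    if (censored) break
    if (stats::runif(1) <= p$pause_probability) {
      extra <- if (p$pause_duration_mean > p$pause_duration_min)
        stats::rexp(1, rate = 1 / (p$pause_duration_mean - p$pause_duration_min))
      else 0
      d <- p$pause_duration_min + extra
      seg[[length(seg) + 1L]] <- list(type = "pause", t_start = t, t_end = t + d,
                                      rate = 0, length = 0, censored = FALSE,
                                      pos_start = pos, pos_end = pos)
      t <- t + d
    }
  }
  seg
}

# Piecewise-linear template position (bases) at arbitrary times.
schedule_position <- function(schedule, t) {
  if (length(schedule) == 0L) return(rep(0, length(t)))
  knots_t <- c(0, vapply(schedule, `[[`, 0, "t_end"))
  knots_p <- c(0, vapply(schedule, `[[`, 0, "pos_end"))
  stats::approx(knots_t, knots_p, xout = t, rule = 2)$y
}

#' Simulate flow-stretching replication trajectories
#'
#' Generates reaction traces built from alternating synthesis segments
#' (exponential lengths, Gaussian per-segment rates, expressed in nm through
#' the bases/nm calibration) and pause plateaus (offset-exponential
#' durations), plus control traces that carry the same slow drift and
#' independent noise but no synthesis. All traces of one experiment share a
#' common time grid and an identical drift curve, matching the rationale for
#' drift correction by control-trace subtraction.
#'
#' @param params A [trace_sim_params()] object.
#' @return An object of class `fs_simulation`: a list with `traces` (list of
#'   [fs_trace()] objects, reactions then controls), `truth` (per-reaction
#'   ground-truth segment/pause tables with boundaries in seconds and in
#'   0-based half-open sample indices, plus per-segment true rate and length),
#'   `time` (the shared grid) and `params`.
#' @examples
#' sim <- simulate_traces(trace_sim_params(n_reaction_traces = 2, seed = 7))
#' sim$truth[[1]][, c("type", "t_start", "t_end", "rate", "length")]
#' @export
simulate_traces <- function(params) {
  stopifnot(inherits(params, "trace_sim_params"))
  p <- params
  with_private_seed(p$seed, {
    schedules <- replicate(p$n_reaction_traces, draw_schedule(p), simplify = FALSE)
    t_end <- vapply(schedules, function(s) {
      if (length(s)) s[[length(s)]]$t_end else 0
    }, 0)
    # extend the grid past the last event so every trace ends in a plateau
    # long enough for the minimum pause window to resolve
    t_max <- max(t_end) + 8 * p$sampling_interval
    time <- seq(0, t_max, by = p$sampling_interval)
    drift <- make_drift(p$drift_amplitude, t_max)
    drift_nm <- drift(time)

    truth <- vector("list", p$n_reaction_traces)
    traces <- vector("list", p$n_reaction_traces + p$n_control_traces)
    for (i in seq_len(p$n_reaction_traces)) {
      sch <- schedules[[i]]
      pos <- schedule_position(sch, time)
      ext <- pos / p$calibration + drift_nm +
        stats::rnorm(length(time), 0, p$noise_sd)
      id <- sprintf("rxn_%02d", i)
      traces[[i]] <- fs_trace(id, "reaction", time, ext, "nm")
      truth[[i]] <- schedule_truth(sch, time, id)
    }
    for (j in seq_len(p$n_control_traces)) {
      ext <- drift_nm + stats::rnorm(length(time), 0, p$noise_sd)
      traces[[p$n_reaction_traces + j]] <-
        fs_trace(sprintf("ctl_%02d", j), "control", time, ext, "nm")
    }
    names(truth) <- vapply(traces[seq_len(p$n_reaction_traces)], `[[`, "", "trace_id")
    structure(list(traces = traces, truth = truth, time = time, params = p),
              class = "fs_simulation")
  })
}

# Ground-truth event table for one trace on the sampled grid. The pause that
# (implicitly) follows the final event extends to the end of the grid.
schedule_truth <- function(schedule, time, trace_id) {
  n <- length(time)
  if (length(schedule) == 0L) {
    return(data.frame(trace_id = trace_id, type = "pause",
                      t_start = time[1], t_end = time[n],
                      start_index = 0L, end_index = n,
                      rate = 0, length = 0, censored = FALSE))
  }
  rows <- lapply(schedule, as.data.frame)
  df <- do.call(rbind, rows)
  df$trace_id <- trace_id
  # trailing plateau after the last event
  last <- df[nrow(df), ]
  if (last$type == "pause") {
    df$t_end[nrow(df)] <- time[n]
  } else {
    df <- rbind(df, data.frame(type = "pause", t_start = last$t_end,
                               t_end = time[n], rate = 0, length = 0,
                               censored = FALSE,
                               pos_start = last$pos_end, pos_end = last$pos_end,
                               trace_id = trace_id))
  }
  eps <- 1e-9
  df$start_index <- vapply(df$t_start, function(t0) sum(time < t0 - eps), 0L)
  df$end_index <- vapply(df$t_end, function(t1) sum(time <= t1 + eps), 0L)
  df[, c("trace_id", "type", "t_start", "t_end", "start_index", "end_index",
         "rate", "length", "censored")]
}

#' Split a simulation (or trace list) by role
#' @param traces An `fs_simulation` or list of `fs_trace` objects.
#' @param role `"reaction"` or `"control"`.
#' @return List of `fs_trace` objects with the requested role.
#' @export
traces_by_role <- function(traces, role = c("reaction", "control")) {
  role <- match.arg(role)
  if (inherits(traces, "fs_simulation")) traces <- traces$traces
  Filter(function(tr) tr$role == role, traces)
}
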