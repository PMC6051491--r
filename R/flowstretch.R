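#' Drift-correct reaction traces with tethered-bead controls
#'
#' Residual flow instabilities are shared across all beads of a field of
#' view, so they can be removed by subtracting traces of tethered DNA
#' molecules that were not enzymatically altered. Each control is first
#' mean-centered (so the subtraction removes drift, not the tether offset),
#' the centered controls are averaged pointwise, and the average is
#' subtracted from every reaction trace.
#'
#' @param reaction A list of [fs_trace()] objects (role `"reaction"`), or a
#'   single `fs_trace`.
#' @param controls A non-empty list of control [fs_trace()] objects on the
#'   identical time grid.
#' @return The corrected reaction traces (same shape as `reaction`).
#' @export
correct_drift <- function(reaction, controls) {
  single <- inherits(reaction, "fs_trace")
  if (single) reaction <- list(reaction)
  if (inherits(controls, "fs_trace")) controls <- list(controls)
  if (length(controls) == 0L)
    halopol_error("at least one control trace is required", "halopol_validation_error")
  grid <- reaction[[1]]$time
  for (tr in c(reaction, controls)) {
    if (length(tr$time) != length(grid) || any(abs(tr$time - grid) > 1e-9))
      halopol_error(sprintf("trace %s is not on the common time grid", tr$trace_id),
                    "halopol_grid_error")
  }
  centered <- vapply(controls, function(tr) tr$extension - mean(tr$extension),
                     numeric(length(grid)))
  drift_hat <- rowMeans(as.matrix(centered))
  out <- lapply(reaction, function(tr) {
    tr$extension <- tr$extension - drift_hat
    tr
  })
  if (single) out[[1]] else out
}

#' Convert a trace from nm to bases
#'
#' Bead displacement reflects the ssDNA-to-dsDNA extension difference at the
#' applied stretching force; the calibration factor converts nm of
#' displacement to numbers of synthesized nucleotides.
#'
#' @param trace An [fs_trace()] in nm.
#' @param calibration Bases per nm (default 3.76).
#' @return The trace with `extension` multiplied by `calibration` and the
#'   unit flag set to `"bases"`.
#' @export
to_bases <- function(trace, calibration = 3.76) {
  stopifnot(inherits(trace, "fs_trace"))
  check_that(calibration > 0, "calibration", "must be > 0")
  if (trace$unit == "bases")
    halopol_error(sprintf("trace %s is already in bases", trace$trace_id),
                  "halopol_unit_error")
  trace$extension <- trace$extension * calibration
  trace$unit <- "bases"
  trace
}

#' Robust per-trace noise sd
#'
#' Estimates the per-sample noise sd from differenced data, robustly via
#' the median absolute deviation. Second differences are used: they cancel
#' any locally linear signal — both pause plateaus and constant-rate
#' synthesis ramps — so the estimate is insensitive to slope and is not
#' inflated by the synthesis steps that contaminate first differences when
#' a large fraction of samples lies on ramps. Dividing by sqrt(6) undoes
#' the variance amplification of double differencing; the only remaining
#' contamination is the rare kink sample at segment/pause boundaries, which
#' the MAD ignores.
#'
#' @param trace An [fs_trace()] (any unit) or a numeric vector.
#' @return Estimated noise sd in the trace's units.
#' @export
estimate_noise_sd <- function(trace) {
  x <- if (inherits(trace, "fs_trace")) trace$extension else as.numeric(trace)
  if (length(x) < 20)
    halopol_error("noise estimation needs at least 20 samples",
                  "halopol_validation_error")
  stats::mad(diff(x, differences = 2)) / sqrt(6)
}

# Flat-run scan implementing the minimum-window pause rule: every window of
# exactly min_points consecutive samples whose amplitude fluctuation (max
# deviation from the window mean) is below the threshold marks its samples
# as paused; pauses are the maximal runs of marked samples (overlapping
# windows merge, so a long plateau is one pause even though its total range
# grows with length). The mean-deviation statistic has expectation ~1.27 sd
# for pure noise at min_points = 6, comfortably under the 3-sd threshold,
# whereas the total range (~2.53 sd expected) sits so close to it that flat
# windows fail stochastically and plateaus fragment. Returns 0-based
# half-open [start, end) intervals.
find_pause_runs <- function(x, threshold, min_points) {
  n <- length(x)
  if (n < min_points) return(list())
  paused <- logical(n)
  for (i in seq_len(n - min_points + 1L)) {
    win <- x[i:(i + min_points - 1L)]
    if (max(abs(win - mean(win))) < threshold)
      paused[i:(i + min_points - 1L)] <- TRUE
  }
  r <- rle(paused)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k])
      runs[[length(runs) + 1L]] <- c(starts[k] - 1L, ends[k])  # 0-based half-open
  }
  runs
}

# A synthesis burst shorter than one sampling interval leaves no sample on
# its ramp, so the flanking plateaus' marked runs touch and would merge into
# a single "pause" spanning a clear step in extension. Split each run at
# adjacent-sample jumps far beyond the noise level (|diff| > jump_threshold)
# and keep the >= min_points sub-runs as pauses; the zero-sample gap between
# them is emitted later as a detected (sub-resolution) burst.
split_runs_at_jumps <- function(runs, x, jump_threshold, min_points) {
  out <- list()
  for (run in runs) {
    i0 <- run[1] + 1L; i1 <- run[2]          # 1-based inclusive
    xr <- x[i0:i1]
    nr <- length(xr)
    cuts <- integer(0)                       # cut after local index j
    if (nr >= 2) {
      d1 <- diff(xr)
      cuts <- which(abs(d1) > jump_threshold)
    }
    if (nr >= 3) {
      # a burst spread over two intervals: neither single-step diff exceeds
      # the threshold but the two-sample level change does; drop the
      # mid-ramp sample by cutting on both sides of it
      d2 <- xr[3:nr] - xr[1:(nr - 2)]
      for (i in which(abs(d2) > jump_threshold)) {
        if (!any(cuts %in% c(i, i + 1L))) cuts <- c(cuts, i, i + 1L)
      }
      cuts <- sort(unique(cuts))
    }
    starts <- c(i0, i0 + cuts)
    ends <- c(i0 + cuts - 1L, i1)
    for (k in seq_along(starts)) {
      if (ends[k] - starts[k] + 1L >= min_points)
        out[[length(out) + 1L]] <- c(starts[k] - 1L, ends[k])
    }
  }
  out
}

#' Segment a trace into synthesis bursts and pauses
#'
#' Applies the operational pause definition: a pause is a run of at least
#' `min_pause_points` consecutive samples with no change in DNA length,
#' amplitude fluctuations below `k_sd` times the noise sd. The rule is
#' applied window-wise: every `min_pause_points`-sample window whose
#' fluctuation (maximum deviation from the window mean) is under the
#' threshold marks its samples as paused, and overlapping windows merge
#' into maximal runs (so long plateaus, whose total amplitude range grows
#' with duration, are still single pauses). Two pauses separated by an
#' outlier sample are not merged. The intervals between pauses (and trace
#' ends) are synthesis segments; per-segment rate is the least-squares slope
#' over the segment samples, and per-segment length is the extension change
#' measured plateau-to-plateau (from the last sample of the preceding pause
#' to the first sample of the following pause), which is unbiased by the
#' partial sampling interval at each boundary.
#'
#' @param trace An [fs_trace()] in bases (drift-corrected).
#' @param noise_sd Noise sd in bases; defaults to [estimate_noise_sd()] of
#'   the trace.
#' @param min_pause_points Minimum pause length in samples (default 6).
#' @param k_sd Amplitude-fluctuation threshold in noise-sd units (default 3).
#' @param jump_k Within-pause jump threshold in noise-sd units (default 6):
#'   a detected pause containing an adjacent-sample step larger than
#'   `jump_k * noise_sd` is split there, and the step is reported as a
#'   sub-resolution synthesis burst (`n_points = 0`) — a burst shorter than
#'   one sampling interval leaves no sample on its ramp but still shifts
#'   the plateau level.
#' @return An object of class `segmentation` with data frames `pauses`
#'   (0-based half-open `start_index`/`end_index`, `duration` s) and
#'   `segments` (`start_index`, `end_index`, `rate` bases/s, `length` bases,
#'   `n_points`, and flags `terminated` — segment is followed by a detected
#'   pause — and `rate_ok` — at least 3 samples, so the slope is usable).
#' @export
segment_trace <- function(trace, noise_sd = NULL, min_pause_points = 6L,
                          k_sd = 3.0, jump_k = 6.0) {
  stopifnot(inherits(trace, "fs_trace"))
  if (trace$unit != "bases")
    halopol_error("segment_trace requires a trace in bases (run to_bases first)",
                  "halopol_unit_error")
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(trace)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    halopol_error("noise_sd must be > 0", "halopol_validation_error")
  x <- trace$extension
  tt <- trace$time
  n <- length(x)
  dt <- tt[2] - tt[1]
  runs <- find_pause_runs(x, k_sd * noise_sd, as.integer(min_pause_points))
  runs <- split_runs_at_jumps(runs, x, jump_k * noise_sd,
                              as.integer(min_pause_points))
  pauses <- if (length(runs)) {
    data.frame(start_index = vapply(runs, `[[`, 0L, 1L),
               end_index = vapply(runs, `[[`, 0L, 2L))
  } else data.frame(start_index = integer(), end_index = integer())
  pauses$duration <- (pauses$end_index - pauses$start_index) * dt

  # complementary gaps -> synthesis segments
  bounds <- rbind(c(NA, 0L), cbind(pauses$start_index, pauses$end_index),
                  c(n, NA))
  segs <- list()
  for (g in seq_len(nrow(bounds) - 1L)) {
    a <- bounds[g, 2L]          # gap start (0-based)
    b <- bounds[g + 1L, 1L]     # gap end (0-based, exclusive)
    if (b < a) next
    preceded <- g > 1L
    followed <- g < nrow(bounds) - 1L
    if (b == a && !(preceded && followed)) next  # empty gap at a trace end
    lo_anchor <- if (preceded) a else a + 1L         # last pause sample / first gap sample
    hi_anchor <- if (followed) b + 1L else b         # first pause sample / last gap sample
    len <- x[hi_anchor] - x[lo_anchor]
    np <- b - a
    rate <- if (np >= 2) {
      idx <- (a + 1L):b         # 1-based sample indices of the gap
      unname(stats::coef(stats::lm.fit(cbind(1, tt[idx]), x[idx]))[2])
    } else NA_real_
    segs[[length(segs) + 1L]] <- data.frame(
      start_index = a, end_index = b, n_points = np,
      rate = rate, length = len,
      terminated = followed, rate_ok = np >= 3L)
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_index = integer(), end_index = integer(),
               n_points = integer(), rate = numeric(), length = numeric(),
               terminated = logical(), rate_ok = logical())
  n_short <- sum(!segments$rate_ok)
  if (n_short > 0)
    message(sprintf("trace %s: %d segment(s) shorter than 3 samples excluded from rate fitting",
                    trace$trace_id, n_short))
  structure(list(trace_id = trace$trace_id, n_samples = n, dt = dt,
                 noise_sd = noise_sd, k_sd = k_sd,
                 min_pause_points = as.integer(min_pause_points),
                 pauses = pauses, segments = segments),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation %s> %d samples, %d segment(s), %d pause(s), noise sd %.3g\n",
              x$trace_id, x$n_samples, nrow(x$segments), nrow(x$pauses),
              x$noise_sd))
  invisible(x)
}

# Pull a numeric column out of segments given as a vector, a data frame, a
# segmentation, or a list of segmentations.
segment_values <- function(segments, column) {
  if (is.numeric(segments)) return(as.numeric(segments))
  if (inherits(segments, "segmentation")) return(segments$segments[[column]])
  if (is.data.frame(segments)) return(segments[[column]])
  if (is.list(segments))
    return(unlist(lapply(segments, segment_values, column = column)))
  halopol_error("cannot interpret `segments`", "halopol_validation_error")
}

#' Gaussian fit of the per-segment rate distribution
#'
#' Maximum-likelihood Gaussian fit to the sample of per-segment synthesis
#' rates (equal to the sample mean and sd), with fit uncertainty sd/sqrt(n).
#'
#' @param segments Numeric vector of rates (bases/s), a `segmentation`
#'   object, a list of them, or a segment data frame with a `rate` column.
#' @return An object of class `rate_estimate` with `mean`, `sd`,
#'   `n_segments` and `fit_uncertainty`.
#' @export
fit_rate_distribution <- function(segments) {
  r <- segment_values(segments, "rate")
  r <- r[is.finite(r)]
  if (length(r) < 2)
    halopol_error("rate fitting needs at least 2 segments",
                  "halopol_validation_error")
  m <- mean(r); s <- stats::sd(r)
  structure(list(mean = m, sd = s, n_segments = length(r),
                 fit_uncertainty = s / sqrt(length(r))),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Synthesis rate: %.1f +/- %.1f bases/s (sd %.1f, n = %d segments)\n",
              x$mean, x$fit_uncertainty, x$sd, x$n_segments))
  invisible(x)
}

#' Exponential fit of the segment-length (processivity) distribution
#'
#' Single-exponential fit of segment lengths. Uncensored, the maximum
#' likelihood estimate of the mean is the sample mean. Right-censored
#' observations — bursts truncated by the template end or by the end of
#' acquisition, whose true length is only known to exceed the observed one
#' — can be flagged either with `censor_at` (lengths at or above the
#' threshold) or with an explicit logical `censored` vector; the censored
#' MLE sum(all lengths)/n_uncensored is then used.
#'
#' @param segments Numeric vector of lengths (bases), a `segmentation`, a
#'   list of them, or a segment data frame with a `length` column.
#' @param censor_at Optional censoring threshold in bases; `NULL` (default)
#'   fits all lengths as complete observations.
#' @param censored Optional logical vector marking right-censored lengths
#'   (mutually exclusive with `censor_at`).
#' @return An object of class `processivity_estimate` with `mean` (bases),
#'   `fit_uncertainty` (mean/sqrt(n_uncensored)), `n_segments` and
#'   `n_censored`.
#' @export
fit_processivity <- function(segments, censor_at = NULL, censored = NULL) {
  len <- segment_values(segments, "length")
  keep <- is.finite(len)
  len <- len[keep]
  if (!is.null(censored)) censored <- censored[keep]
  if (any(len <= 0))
    halopol_error("segment lengths must be positive", "halopol_validation_error")
  if (length(len) < 2)
    halopol_error("processivity fitting needs at least 2 segments",
                  "halopol_validation_error")
  if (!is.null(censor_at) && !is.null(censored))
    halopol_error("give either censor_at or censored, not both",
                  "halopol_validation_error")
  if (!is.null(censored)) {
    stopifnot(is.logical(censored), length(censored) == length(len))
    cens <- censored
  } else if (is.null(censor_at)) {
    cens <- rep(FALSE, length(len))
  } else {
    check_that(censor_at > 0, "censor_at", "must be > 0")
    cens <- len >= censor_at
  }
  n_obs <- sum(!cens)
  if (n_obs == 0)
    halopol_error("all segment lengths are censored; mean is unidentifiable",
                  "halopol_validation_error")
  m <- sum(len) / n_obs
  structure(list(mean = m, fit_uncertainty = m / sqrt(n_obs),
                 n_segments = length(len), n_censored = sum(cens)),
            class = "processivity_estimate")
}

#' @export
print.processivity_estimate <- function(x, ...) {
  cat(sprintf("Processivity: %.0f +/- %.0f bases (n = %d segments, %d censored)\n",
              x$mean, x$fit_uncertainty, x$n_segments, x$n_censored))
  invisible(x)
}

#' Full trajectory analysis pipeline
#'
#' Runs drift correction, nm-to-bases conversion, pause segmentation and the
#' population fits in one call: the estimator chain applied to real or
#' simulated flow-stretching data.
#'
#' The final synthesis segment of each trace is treated as right-censored
#' in the processivity fit: on a finite template every trajectory's last
#' burst is truncated, either by the template end or by the end of
#' acquisition, so its observed length is a lower bound. The censored
#' exponential MLE (total synthesis / number of complete bursts) uses these
#' lengths without biasing the mean. Censored segments are retained for the
#' rate fit, where a truncated ramp still yields an unbiased slope.
#'
#' @param reaction,controls Lists of [fs_trace()] objects in nm.
#' @param calibration Bases per nm (default 3.76).
#' @param min_pause_points,k_sd Pause-detection parameters (defaults 6, 3).
#' @param noise_sd Optional noise sd in bases applied to every trace;
#'   default estimates it per trace from differenced data.
#' @param min_rate_points Minimum samples for a usable per-segment slope
#'   (default 3).
#' @return A list with `segmentations` (per trace), `segments` (combined
#'   data frame with `trace_id`), `rate` ([fit_rate_distribution()] result),
#'   `processivity` ([fit_processivity()] result) and the resolved
#'   parameters.
#' @export
analyze_traces <- function(reaction, controls, calibration = 3.76,
                           min_pause_points = 6L, k_sd = 3.0,
                           noise_sd = NULL, min_rate_points = 3L) {
  if (inherits(reaction, "fs_simulation")) {
    sim <- reaction
    reaction <- traces_by_role(sim, "reaction")
    if (missing(controls)) controls <- traces_by_role(sim, "control")
  }
  corrected <- correct_drift(reaction, controls)
  segmentations <- lapply(corrected, function(tr) {
    trb <- to_bases(tr, calibration)
    segment_trace(trb, noise_sd = noise_sd,
                  min_pause_points = min_pause_points, k_sd = k_sd)
  })
  names(segmentations) <- vapply(corrected, `[[`, "", "trace_id")
  seg_df <- do.call(rbind, lapply(segmentations, function(s) {
    if (nrow(s$segments) == 0) return(NULL)
    d <- cbind(trace_id = s$trace_id, s$segments)
    # last burst of a trace is length-censored (template or acquisition end)
    d$censored <- !d$terminated | seq_len(nrow(d)) == nrow(d)
    d
  }))
  rownames(seg_df) <- NULL
  rate_seg <- seg_df[seg_df$rate_ok & seg_df$n_points >= min_rate_points &
                       is.finite(seg_df$rate), , drop = FALSE]
  proc_seg <- seg_df[seg_df$length > 0, , drop = FALSE]
  list(segmentations = segmentations,
       segments = seg_df,
       rate = fit_rate_distribution(rate_seg$rate),
       processivity = fit_processivity(proc_seg$length,
                                       censored = proc_seg$censored),
       params = list(calibration = calibration,
                     min_pause_points = as.integer(min_pause_points),
                     k_sd = k_sd, noise_sd = noise_sd,
                     min_rate_points = as.integer(min_rate_points)))
}
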