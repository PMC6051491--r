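#' Simulate camera frames of a diffraction-limited bead
#'
#' Each frame contains one symmetric 2-D Gaussian spot (the bead's point
#' spread function) on a flat background plus additive pixel noise. Pixel
#' centers sit at integer coordinates; `x` indexes columns and `y` rows,
#' both 1-based.
#'
#' @param true_positions A two-column matrix (or data frame) of spot centers
#'   `(x, y)` in pixels, one row per frame.
#' @param psf_sd Gaussian PSF sd in pixels (> 0).
#' @param amplitude Peak spot amplitude in counts.
#' @param noise_sd Additive Gaussian pixel noise sd in counts.
#' @param frame_size Frame side length in pixels (scalar, square frames) or
#'   `c(nx, ny)`.
#' @param offset Constant background level in counts (default 10).
#' @param seed Integer seed.
#' @return An object of class `bead_frames`: list with `frames` (list of
#'   `ny x nx` matrices) and `truth` (the positions matrix).
#' @export
simulate_bead_frames <- function(true_positions, psf_sd = 1.5,
                                 amplitude = 100, noise_sd = 0,
                                 frame_size = 64, offset = 10, seed = 1L) {
  pos <- as.matrix(true_positions)
  if (ncol(pos) != 2) halopol_error("true_positions must have 2 columns (x, y)",
                                    "halopol_validation_error")
  check_that(psf_sd > 0, "psf_sd", "must be > 0")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  if (length(frame_size) == 1) frame_size <- c(frame_size, frame_size)
  nx <- as.integer(frame_size[1]); ny <- as.integer(frame_size[2])
  if (any(pos[, 1] < 1 | pos[, 1] > nx | pos[, 2] < 1 | pos[, 2] > ny))
    halopol_error("spot position outside frame", "halopol_validation_error")
  xs <- seq_len(nx); ys <- seq_len(ny)
  with_private_seed(seed, {
    frames <- lapply(seq_len(nrow(pos)), function(i) {
      gx <- exp(-(xs - pos[i, 1])^2 / (2 * psf_sd^2))
      gy <- exp(-(ys - pos[i, 2])^2 / (2 * psf_sd^2))
      img <- offset + amplitude * outer(gy, gx)   # rows = y, cols = x
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
      img
    })
    structure(list(frames = frames, truth = pos), class = "bead_frames")
  })
}

#' Localize a bead by 2-D Gaussian fitting
#'
#' Least-squares fit of a symmetric 2-D Gaussian (free parameters: center
#' `x0`, `y0`, sd, amplitude, offset) to a single frame, the standard
#' sub-pixel centroid estimator for particle tracking.
#'
#' @param frame A numeric matrix (rows = y, columns = x), e.g. one element
#'   of `simulate_bead_frames()$frames`.
#' @return A list of class `bead_fit` with `x`, `y` (pixels), `sd`,
#'   `amplitude`, `offset` and `converged`. When the fit fails or the
#'   fitted amplitude does not rise above the pixel-noise floor, `converged`
#'   is `FALSE` and the coordinates are `NA` (the localization-failure
#'   signal).
#' @export
localize_bead <- function(frame) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  ny <- nrow(frame); nx <- ncol(frame)
  bg0 <- stats::median(frame)
  noise_floor <- stats::mad(frame)
  resid_img <- pmax(frame - bg0, 0)
  tot <- sum(resid_img)
  fail <- function() structure(list(x = NA_real_, y = NA_real_, sd = NA_real_,
                                    amplitude = NA_real_, offset = bg0,
                                    converged = FALSE), class = "bead_fit")
  if (tot <= 0 || max(frame) - bg0 <= 3 * noise_floor) return(fail())
  xs <- rep(seq_len(nx), each = ny)
  ys <- rep(seq_len(ny), times = nx)
  z <- as.vector(frame)
  # moment-based starts from a small region around the brightest pixel,
  # which is robust to background noise across the rest of the frame
  pk <- arrayInd(which.max(frame), dim(frame))
  roi_y <- max(1, pk[1] - 8):min(ny, pk[1] + 8)
  roi_x <- max(1, pk[2] - 8):min(nx, pk[2] + 8)
  wloc <- pmax(frame[roi_y, roi_x, drop = FALSE] - bg0, 0)
  wx <- rep(roi_x, each = length(roi_y))
  wy <- rep(roi_y, times = length(roi_x))
  wv <- as.vector(wloc)
  x0 <- sum(wx * wv) / sum(wv)
  y0 <- sum(wy * wv) / sum(wv)
  s0 <- sqrt(max(sum(wv * ((wx - x0)^2 + (wy - y0)^2)) / (2 * sum(wv)), 0.25))
  a0 <- max(frame) - bg0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + a * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2)),
      start = list(b = bg0, a = a0, cx = x0, cy = y0, s = s0),
      lower = c(b = -Inf, a = 0, cx = 0.5, cy = 0.5, s = 0.3),
      upper = c(b = Inf, a = Inf, cx = nx + 0.5, cy = ny + 0.5, s = max(nx, ny)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  if (cf[["a"]] <= 3 * noise_floor) return(fail())
  structure(list(x = unname(cf[["cx"]]), y = unname(cf[["cy"]]),
                 sd = unname(cf[["s"]]), amplitude = unname(cf[["a"]]),
                 offset = unname(cf[["b"]]), converged = TRUE),
            class = "bead_fit")
}

#' @export
print.bead_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<bead_fit> (%.3f, %.3f) px, sd %.2f, amp %.1f\n",
                x$x, x$y, x$sd, x$amplitude))
  else cat("<bead_fit> localization failed\n")
  invisible(x)
}
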