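#' SPR binding simulation parameters
#'
#' Equilibrium (steady-state) responses follow the 1:1 Langmuir isotherm
#' R(C) = Rmax * C / (Kd + C). The default concentration ladder is the
#' 10-600 nM series used for primer/template titrations.
#'
#' @param kd Equilibrium dissociation constant (nM, > 0).
#' @param rmax Saturating response (RU, > 0).
#' @param concentrations Strictly increasing positive analyte
#'   concentrations (nM).
#' @param noise_sd Additive response noise sd (RU).
#' @param noise_rel Multiplicative noise: responses are scaled by
#'   `1 + N(0, noise_rel)` (e.g. 0.02 for 2% RU noise).
#' @param seed Integer seed.
#' @return An object of class `binding_sim_params`.
#' @export
binding_sim_params <- function(kd, rmax = 400,
                               concentrations = c(10, 20, 50, 100, 200, 400, 600),
                               noise_sd = 0, noise_rel = 0, seed = 1L) {
  check_that(is.numeric(kd) && kd > 0, "kd", "must be > 0")
  check_that(rmax > 0, "rmax", "must be > 0")
  check_that(all(concentrations > 0), "concentrations", "must be positive")
  check_that(all(diff(concentrations) > 0), "concentrations",
             "must be strictly increasing")
  check_that(noise_sd >= 0, "noise_sd", "must be >= 0")
  check_that(noise_rel >= 0, "noise_rel", "must be >= 0")
  structure(list(kd = kd, rmax = rmax, concentrations = concentrations,
                 noise_sd = noise_sd, noise_rel = noise_rel,
                 seed = as.integer(seed)),
            class = "binding_sim_params")
}

#' Construct an equilibrium binding series
#' @param concentrations Analyte concentrations (nM).
#' @param responses Equilibrium responses (RU).
#' @param label Optional analyte/ligand identifier.
#' @return An object of class `binding_series`.
#' @export
binding_series <- function(concentrations, responses, label = "") {
  check_that(length(concentrations) == length(responses), "responses",
             "must match concentrations in length")
  check_that(all(concentrations > 0), "concentrations", "must be positive")
  structure(list(concentrations = as.numeric(concentrations),
                 responses = as.numeric(responses), label = label),
            class = "binding_series")
}

#' Simulate an equilibrium SPR series
#' @param params A [binding_sim_params()] object.
#' @return List of class `binding_simulation`: `series` (a
#'   [binding_series()]) and `truth` (`kd_nM`, `rmax_RU`).
#' @export
simulate_binding <- function(params) {
  stopifnot(inherits(params, "binding_sim_params"))
  p <- params
  r <- p$rmax * p$concentrations / (p$kd + p$concentrations)
  if (p$noise_sd > 0 || p$noise_rel > 0) {
    r <- with_private_seed(p$seed, {
      if (p$noise_rel > 0)
        r <- r * (1 + stats::rnorm(length(r), 0, p$noise_rel))
      if (p$noise_sd > 0) r <- r + stats::rnorm(length(r), 0, p$noise_sd)
      r
    })
  }
  structure(list(series = binding_series(p$concentrations, r),
                 truth = list(kd_nM = p$kd, rmax_RU = p$rmax),
                 params = p),
            class = "binding_simulation")
}

#' Subtract a reference flow-cell series
#'
#' Removes bulk refractive-index shifts and nonspecific surface binding by
#' pointwise subtraction of a reference (no-ligand) flow-cell series
#' recorded at matching analyte concentrations.
#'
#' @param raw,reference [binding_series()] objects with identical
#'   concentrations.
#' @return The corrected [binding_series()].
#' @export
subtract_reference <- function(raw, reference) {
  stopifnot(inherits(raw, "binding_series"), inherits(reference, "binding_series"))
  if (length(raw$concentrations) != length(reference$concentrations) ||
      any(abs(raw$concentrations - reference$concentrations) >
            1e-9 * pmax(raw$concentrations, 1)))
    halopol_error("raw and reference concentrations do not match",
                  "halopol_validation_error")
  binding_series(raw$concentrations, raw$responses - reference$responses,
                 label = raw$label)
}

#' Steady-state affinity fit
#'
#' Least-squares fit of the 1:1 Langmuir isotherm
#' R(C) = Rmax * C / (Kd + C) to equilibrium responses, the steady-state
#' affinity mode of SPR analysis. When the fitted Kd exceeds 10x the top
#' concentration the data do not approach saturation and Kd is not
#' identifiable; the estimate is returned with `converged = FALSE`.
#'
#' @param series A [binding_series()] (or `binding_simulation`).
#' @param weights `"none"` (default, unweighted) or `"relative"`
#'   (1/response weighting).
#' @param rmax_max Upper bound on Rmax in RU (default 500, the expected
#'   ceiling of protein binding responses on these surfaces).
#' @return List of class `affinity_estimate`: `kd` (nM), `rmax` (RU),
#'   `kd_uncertainty` (nM, from the fit covariance), `converged`, and
#'   `diagnostics`.
#' @export
steady_state_fit <- function(series, weights = c("none", "relative"),
                             rmax_max = 500) {
  if (inherits(series, "binding_simulation")) series <- series$series
  stopifnot(inherits(series, "binding_series"))
  weights <- match.arg(weights)
  conc <- series$concentrations
  resp <- series$responses
  if (length(unique(conc)) < 4)
    halopol_error("steady-state fitting needs >= 4 distinct concentrations",
                  "halopol_validation_error")
  rmax0 <- min(max(resp) * 1.2, rmax_max * 0.95)
  kd0 <- conc[which.min(abs(resp - max(resp) / 2))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc)
  wts <- if (weights == "relative") 1 / pmax(abs(resp), 1e-6) else rep(1, length(resp))
  fit <- tryCatch(
    minpack.lm::nlsLM(resp ~ rmax * conc / (kd + conc),
                      start = list(kd = kd0, rmax = rmax0),
                      lower = c(kd = 1e-12, rmax = 1e-12),
                      upper = c(kd = Inf, rmax = rmax_max),
                      weights = wts,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, rmax = NA_real_,
                          kd_uncertainty = NA_real_, converged = FALSE,
                          diagnostics = "fit failed"),
                     class = "affinity_estimate"))
  }
  cf <- stats::coef(fit)
  kd_se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                    error = function(e) NA_real_)
  non_sat <- cf[["kd"]] > 10 * max(conc)
  structure(list(kd = unname(cf[["kd"]]), rmax = unname(cf[["rmax"]]),
                 kd_uncertainty = unname(kd_se),
                 converged = !non_sat,
                 diagnostics = if (non_sat)
                   sprintf("non-saturating data: fitted Kd (%.3g nM) exceeds 10x the top concentration (%.3g nM)",
                           cf[["kd"]], max(conc)) else "ok"),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("Kd = %.2f nM (se %.2g), Rmax = %.1f RU\n",
                x$kd, x$kd_uncertainty, x$rmax))
  else cat(sprintf("Affinity fit not converged: %s\n", x$diagnostics))
  invisible(x)
}
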