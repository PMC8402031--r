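# Monte Carlo probability of target attainment for the AUC24/MIC >= 125
# efficacy target, and the creatinine-clearance vs MIC dosing nomogram.
# At steady state AUC24 = daily dose / CL for linear kinetics, so only
# clearance variability matters for this target: volume shifts the shape
# of the profile, not the daily exposure.

#' Monte Carlo probability of target attainment
#'
#' Draws `n_sim` individual clearances
#' `CL_i = typical_cl(model, clcr) * exp(eta)`, `eta ~ N(0, omega_CL^2)`,
#' computes `AUC24_i = daily_dose / CL_i`, and reports the percent of
#' simulated patients with `AUC24_i / MIC >= threshold` for each MIC.
#'
#' @param model A [pop_model()].
#' @param daily_dose Total daily dose, mg (scalar or vector).
#' @param clcr Creatinine clearance, mL/s (scalar or vector).
#' @param mic_grid MIC values, mg/L (default the doubling dilutions
#'   0.0625-1).
#' @param n_sim Simulated patients per cell (default 1000).
#' @param seed Optional RNG seed.
#' @param threshold PK/PD target ratio (default 125).
#' @return data.frame of class `pta_result`: daily_dose, clcr, mic, pta
#'   (percent), n_sim.
#' @export
pta_curve <- function(model, daily_dose, clcr,
                      mic_grid = c(0.0625, 0.125, 0.25, 0.5, 1),
                      n_sim = 1000, seed = NULL, threshold = 125) {
  stopifnot(inherits(model, "pop_model"), all(mic_grid > 0),
            all(clcr > 0), all(daily_dose > 0), threshold > 0)
  with_seed(seed, {
    grid <- expand.grid(daily_dose = daily_dose, clcr = clcr,
                        KEEP.OUT.ATTRS = FALSE)
    out <- list()
    for (g in seq_len(nrow(grid))) {
      tcl <- typical_cl(model, grid$clcr[g])
      cl_i <- tcl * exp(stats::rnorm(n_sim, 0, model$omega_cl))
      auc <- grid$daily_dose[g] / cl_i
      for (mic in mic_grid) {
        out[[length(out) + 1L]] <- data.frame(
          daily_dose = grid$daily_dose[g], clcr = grid$clcr[g],
          mic = mic, pta = 100 * mean(auc / mic >= threshold),
          n_sim = n_sim)
      }
    }
    res <- do.call(rbind, out)
    class(res) <- c("pta_result", class(res))
    res
  })
}

#' Closed-form probability of target attainment
#'
#' For log-normal clearance the target `AUC24/MIC >= threshold` is
#' equivalent to `CL_i <= daily_dose/(threshold * MIC)`, so
#' `PTA = 100 * Phi( (log(daily_dose/(threshold*mic)) - log typical CL)
#' / omega_CL )` — exact for the generative model of [pta_curve()] and
#' used as its analytic oracle. With `omega_CL = 0` the PTA is a 0/100
#' step at `MIC* = daily_dose / (threshold * typical CL)`.
#'
#' @inheritParams pta_curve
#' @param mic MIC value(s), mg/L.
#' @return PTA in percent (vectorized over `mic`).
#' @export
pta_closed_form <- function(model, daily_dose, clcr, mic, threshold = 125) {
  stopifnot(inherits(model, "pop_model"), all(mic > 0), clcr > 0,
            daily_dose > 0)
  tcl <- typical_cl(model, clcr)
  cl_star <- daily_dose / (threshold * mic)
  if (model$omega_cl == 0) return(ifelse(cl_star >= tcl, 100, 0))
  100 * stats::pnorm(log(cl_star / tcl) / model$omega_cl)
}

#' Nomogram coefficients
#'
#' Linear clearance-on-CLcr relation `CL = a * CLcr + b` underlying the
#' dosing nomogram; the default coefficients are the regression estimated
#' on the individual analysis of the critically ill cohort
#' (`CL = 18.54 CLcr + 3.261`, r2 = 0.63).
#'
#' @param a Slope, L/h per mL/s (must be positive).
#' @param b Intercept, L/h.
#' @return List of class `nomogram_coefficients`.
#' @export
nomogram_coefficients <- function(a = 18.54, b = 3.261) {
  if (a <= 0) stop("slope `a` must be positive", call. = FALSE)
  structure(list(a = a, b = b), class = "nomogram_coefficients")
}

#' Creatinine-clearance vs MIC attainment boundary
#'
#' From `AUC24 = daily_dose / CL` and `CL = a CLcr + b`, the target
#' `AUC24/MIC >= threshold` holds iff
#' `MIC <= MIC_max(CLcr) = daily_dose / (threshold (a CLcr + b))`, with
#' inverse `CLcr_max(MIC) = (daily_dose/(threshold MIC) - b) / a`. A
#' negative `CLcr_max` means the target is unattainable at any renal
#' function at that dose and MIC.
#'
#' @param daily_dose Total daily dose, mg.
#' @param coeffs A [nomogram_coefficients()].
#' @param threshold PK/PD target ratio (default 125).
#' @return List of class `nomogram_boundary` with vectorized functions
#'   `mic_max(clcr)` and `clcr_max(mic)` (the latter `NA` with a
#'   `"unattainable at any renal function"` message attribute when
#'   negative), plus `table(clcr_grid)` producing a CLcr-vs-MIC_max
#'   data.frame.
#' @export
nomogram_boundary <- function(daily_dose, coeffs = nomogram_coefficients(),
                              threshold = 125) {
  stopifnot(daily_dose > 0, inherits(coeffs, "nomogram_coefficients"),
            threshold > 0)
  a <- coeffs$a; b <- coeffs$b
  mic_max <- function(clcr) {
    stopifnot(all(clcr > 0))
    daily_dose / (threshold * (a * clcr + b))
  }
  clcr_max <- function(mic) {
    stopifnot(all(mic > 0))
    v <- (daily_dose / (threshold * mic) - b) / a
    ifelse(v > 0, v, NA_real_)
  }
  tab <- function(clcr_grid = seq(0.1, 3.5, by = 0.05)) {
    data.frame(clcr = clcr_grid, mic_max = mic_max(clcr_grid))
  }
  structure(list(daily_dose = daily_dose, coeffs = coeffs,
                 threshold = threshold, mic_max = mic_max,
                 clcr_max = clcr_max, table = tab),
            class = "nomogram_boundary")
}

#' @export
print.nomogram_boundary <- function(x, ...) {
  cat(sprintf(
    "Nomogram boundary: %g mg/day, CL = %.4g CLcr + %.4g, AUC24/MIC >= %g\n",
    x$daily_dose, x$coeffs$a, x$coeffs$b, x$threshold))
  for (mic in c(0.125, 0.25, 0.5, 1)) {
    cm <- x$clcr_max(mic)
    cat(sprintf("  MIC %g mg/L: attainable for CLcr <= %s mL/s\n", mic,
                ifelse(is.na(cm), "none (unattainable at any renal function)",
                       sprintf("%.3g", cm))))
  }
  invisible(x)
}
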