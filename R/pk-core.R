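#' Individual pharmacokinetic parameters
#'
#' Container for the two structural parameters of the one-compartment,
#' first-order-elimination model: clearance `CL` (L/h) and apparent volume
#' of distribution `Vd` (L). The elimination rate constant `ke = CL/Vd`
#' (1/h) and half-life `t1/2 = ln(2)/ke` (h) are derived, not stored.
#'
#' @param cl Clearance in L/h; must be positive.
#' @param vd Volume of distribution in L; must be positive.
#' @return An object of class `pk_params`.
#' @examples
#' pk <- pk_params(cl = 21.5, vd = 143)
#' elimination_params(pk)
#' @export
pk_params <- function(cl, vd) {
  if (!is.numeric(cl) || length(cl) != 1L || !is.finite(cl) || cl <= 0)
    stop("`cl` must be a single positive number (L/h)", call. = FALSE)
  if (!is.numeric(vd) || length(vd) != 1L || !is.finite(vd) || vd <= 0)
    stop("`vd` must be a single positive number (L)", call. = FALSE)
  structure(list(cl = cl, vd = vd), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  ep <- elimination_params(x)
  cat(sprintf("One-compartment PK parameters: CL = %.4g L/h, Vd = %.4g L\n",
              x$cl, x$vd))
  cat(sprintf("  ke = %.4g 1/h, t1/2 = %.4g h\n", ep$ke, ep$t_half))
  invisible(x)
}

#' Elimination rate constant and half-life
#'
#' @param pk A [pk_params()] object.
#' @return List with `ke` (1/h) and `t_half` (h).
#' @export
elimination_params <- function(pk) {
  stopifnot(inherits(pk, "pk_params"))
  ke <- pk$cl / pk$vd
  list(ke = ke, t_half = log(2) / ke)
}

#' A single intravenous infusion event
#'
#' @param start_time Start of the infusion, hours since the first dose.
#' @param amount Dose amount in mg; must be positive.
#' @param infusion_duration Infusion duration in h (default 0.5, i.e. the
#'   30-minute infusions used clinically for ciprofloxacin).
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(start_time, amount, infusion_duration = 0.5) {
  if (!is.numeric(start_time) || length(start_time) != 1L || start_time < 0)
    stop("`start_time` must be a single nonnegative number (h)", call. = FALSE)
  if (!is.numeric(amount) || length(amount) != 1L || amount <= 0)
    stop("`amount` must be a single positive number (mg)", call. = FALSE)
  if (!is.numeric(infusion_duration) || length(infusion_duration) != 1L ||
      infusion_duration <= 0)
    stop("`infusion_duration` must be positive (h)", call. = FALSE)
  structure(list(start_time = start_time, amount = amount,
                 infusion_duration = infusion_duration),
            class = "dose_event")
}

#' A multiple-dose intravenous regimen
#'
#' Builds a uniform regimen of repeated short infusions. The daily dose is
#' derived as `24/interval * amount` and must correspond to one of the
#' usual intensive-care ciprofloxacin regimens when used with the cohort
#' simulator (400 mg q12h, 400 mg q8h, 600 mg q12h), though any positive
#' combination is accepted here.
#'
#' @param amount Dose per administration, mg.
#' @param interval Dosing interval, h (8 or 12 clinically).
#' @param n_doses Number of doses in the regimen.
#' @param first_dose_time Start time of the first infusion (h), default 0.
#' @param infusion_duration Infusion duration, h (default 0.5).
#' @return An object of class `regimen`: list of [dose_event()]s plus
#'   `interval` and derived `daily_dose`.
#' @export
regimen <- function(amount, interval, n_doses,
                    first_dose_time = 0, infusion_duration = 0.5) {
  stopifnot(amount > 0, interval > 0, n_doses >= 1)
  events <- lapply(seq_len(n_doses) - 1L, function(k)
    dose_event(first_dose_time + k * interval, amount, infusion_duration))
  regimen_from_events(events, interval = interval)
}

#' Assemble a regimen from explicit dose events
#'
#' @param events List of [dose_event()] objects; will be sorted by start time.
#' @param interval Nominal dosing interval in h (optional for irregular
#'   regimens; required by steady-state helpers).
#' @return An object of class `regimen`.
#' @export
regimen_from_events <- function(events, interval = NA_real_) {
  if (length(events) == 0L)
    stop("a regimen needs at least one dose event", call. = FALSE)
  ok <- vapply(events, inherits, logical(1), what = "dose_event")
  if (!all(ok)) stop("all events must be `dose_event` objects", call. = FALSE)
  ord <- order(vapply(events, `[[`, numeric(1), "start_time"))
  events <- events[ord]
  amounts <- vapply(events, `[[`, numeric(1), "amount")
  daily <- if (is.finite(interval)) 24 / interval * amounts[[1L]] else NA_real_
  structure(list(events = events, interval = interval, daily_dose = daily),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %d infusion(s)", length(x$events)))
  if (is.finite(x$interval))
    cat(sprintf(", %g mg q%gh (%g mg/day)",
                x$events[[1L]]$amount, x$interval, x$daily_dose))
  cat("\n")
  invisible(x)
}

#' Concentration from a single short infusion
#'
#' Closed-form solution of the one-compartment model with zero-order input
#' at rate `R0 = amount/infusion_duration` and first-order elimination.
#' With `tau = t - start_time`: during the infusion
#' `C = (R0/CL) (1 - exp(-ke tau))`; after it
#' `C = (R0/CL) (1 - exp(-ke Tinf)) exp(-ke (tau - Tinf))`.
#' The profile is continuous at the end of infusion and nonnegative.
#'
#' @param pk A [pk_params()] object.
#' @param event A [dose_event()].
#' @param t Vector of times (h, same clock as `event$start_time`); all must
#'   be `>= event$start_time`.
#' @return Concentrations in mg/L, same length as `t`.
#' @export
conc_single_infusion <- function(pk, event, t) {
  stopifnot(inherits(pk, "pk_params"), inherits(event, "dose_event"))
  if (any(t < event$start_time))
    stop("all times must be at or after the infusion start", call. = FALSE)
  ke <- pk$cl / pk$vd
  r0 <- event$amount / event$infusion_duration
  tau <- t - event$start_time
  tin <- pmin(tau, event$infusion_duration)
  tout <- pmax(tau - event$infusion_duration, 0)
  (r0 / pk$cl) * (1 - exp(-ke * tin)) * exp(-ke * tout)
}

#' Concentration-time profile under a multiple-dose regimen
#'
#' Linear superposition of [conc_single_infusion()] over every dose event
#' that has started by each requested time; doses starting after a time
#' contribute nothing at that time.
#'
#' @param pk A [pk_params()] object.
#' @param reg A [regimen()] object.
#' @param times Vector of times (h since first dose).
#' @return Concentrations in mg/L.
#' @export
conc_profile <- function(pk, reg, times) {
  stopifnot(inherits(pk, "pk_params"), inherits(reg, "regimen"))
  if (length(reg$events) == 0L) stop("empty regimen", call. = FALSE)
  conc <- numeric(length(times))
  for (ev in reg$events) {
    live <- times >= ev$start_time
    if (any(live))
      conc[live] <- conc[live] + conc_single_infusion(pk, ev, times[live])
  }
  conc
}

#' Steady-state 24-hour exposure
#'
#' For linear kinetics the steady-state area under the concentration-time
#' curve over 24 h is `AUC24 = daily_dose / CL`, independent of the volume
#' of distribution and of the dosing schedule within the day.
#'
#' @param pk A [pk_params()] object.
#' @param daily_dose Total daily dose, mg.
#' @return AUC24 in mg·h/L.
#' @export
auc_steady_state <- function(pk, daily_dose) {
  stopifnot(inherits(pk, "pk_params"))
  if (!is.numeric(daily_dose) || any(daily_dose <= 0))
    stop("`daily_dose` must be positive (mg)", call. = FALSE)
  daily_dose / pk$cl
}
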