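# Synthetic cohorts emulating an intensive-care ciprofloxacin TDM study:
# 30-min infusions of 400 or 600 mg every 8 or 12 h, three samples per
# profile (1 h, 4 h and trough after end of infusion), one profile early
# in treatment (within 36 h) and one delayed (72-96 h), covariates
# re-measured on each sampling day.

#' Sampling design template
#'
#' @param infusion_duration Infusion duration, h.
#' @param sample_offsets Sample times after end of infusion, h, excluding
#'   the trough; the trough is taken at `interval - infusion_duration`
#'   after the end of the infusion (7.5 h for q8, 11.5 h for q12), i.e.
#'   immediately before the next dose.
#' @param early_dose_index Which dose the early profile follows (default
#'   2, keeping the profile within 36 h of treatment start for both
#'   intervals).
#' @param delayed_time Target time (h) of the delayed profile's dose; the
#'   dose nearest this time is used (default 84 h, the middle of the
#'   72-96 h window).
#' @return A list of class `study_design`.
#' @export
study_design <- function(infusion_duration = 0.5, sample_offsets = c(1, 4),
                         early_dose_index = 2, delayed_time = 84) {
  stopifnot(infusion_duration > 0, all(sample_offsets > 0),
            early_dose_index >= 1, delayed_time > 0)
  structure(list(infusion_duration = infusion_duration,
                 sample_offsets = sample_offsets,
                 early_dose_index = early_dose_index,
                 delayed_time = delayed_time),
            class = "study_design")
}

ln_spec <- function(median, range) {
  if (range[1] >= range[2]) stop("invalid range: min >= max", call. = FALSE)
  if (any(range <= 0)) stop("log-normal range must be positive", call. = FALSE)
  # spread chosen so the stated range is roughly a 95% interval
  list(mu = log(median), sigma = log(range[2] / range[1]) / (2 * 1.96))
}

#' Marginal distributions for the virtual cohort
#'
#' Positive-valued covariates are log-normal with the median as
#' geometric mean and spread set so the configured range is roughly a
#' 95% interval; fluid balance (signed) is normal; norepinephrine and
#' furosemide are zero-inflated log-normal. Defaults reproduce the
#' marginal summaries of the critically ill cohort this package
#' emulates. The delayed-occasion creatinine clearance is redrawn with a
#' narrower spread than the early one, matching the higher early-phase
#' spread of renal function seen clinically.
#'
#' @param clcr_median,clcr_range Early-occasion measured creatinine
#'   clearance, mL/s.
#' @param clcr_delayed_median,clcr_delayed_range Delayed-occasion CLcr.
#' @param age_median,age_range Years.
#' @param weight_median,weight_range kg.
#' @param height_median,height_range cm.
#' @param scr_median,scr_range Serum creatinine, umol/L.
#' @param bili_median,bili_range Total bilirubin, umol/L.
#' @param fluid_median,fluid_range Daily fluid balance, mL/day (normal).
#' @param p_male Probability of male sex.
#' @param p_smoker Probabilities for smoker yes/no/unknown.
#' @param p_cvvhd Probability of CVVHD support.
#' @param rho_age_clcr Optional correlation between log age and log CLcr
#'   (default 0 = independent).
#' @return A config list for [sample_cohort()].
#' @export
cohort_config <- function(clcr_median = 1.16, clcr_range = c(0.12, 3.32),
                          clcr_delayed_median = 1.36,
                          clcr_delayed_range = c(0.66, 2.49),
                          age_median = 58, age_range = c(35, 85),
                          weight_median = 90, weight_range = c(56, 140),
                          height_median = 175, height_range = c(150, 196),
                          scr_median = 85, scr_range = c(35, 320),
                          bili_median = 11.3, bili_range = c(3.5, 90.3),
                          fluid_median = -490, fluid_range = c(-4000, 4300),
                          p_male = 21 / 29,
                          p_smoker = c(yes = 15, no = 6, unknown = 8) / 29,
                          p_cvvhd = 1 / 30,
                          rho_age_clcr = 0) {
  if (fluid_range[1] >= fluid_range[2])
    stop("invalid range: min >= max", call. = FALSE)
  list(clcr = ln_spec(clcr_median, clcr_range),
       clcr_delayed = ln_spec(clcr_delayed_median, clcr_delayed_range),
       age = ln_spec(age_median, age_range),
       weight = ln_spec(weight_median, weight_range),
       height = ln_spec(height_median, height_range),
       scr = ln_spec(scr_median, scr_range),
       bili = ln_spec(bili_median, bili_range),
       fluid = list(mu = fluid_median,
                    sigma = diff(fluid_range) / (2 * 1.96)),
       norepi = list(p_zero = 0.2, mu = log(17), sigma = 0.65),
       furos = list(p_zero = 0.3, mu = log(10), sigma = 1.3),
       p_male = p_male, p_smoker = p_smoker, p_cvvhd = p_cvvhd,
       rho_age_clcr = rho_age_clcr)
}

rln <- function(n, s) exp(stats::rnorm(n, s$mu, s$sigma))

#' Draw a virtual cohort
#'
#' Two covariate records per subject (early and delayed occasion).
#' Anthropometrics and sex are constant across occasions; renal function
#' and day-level laboratory/clinical covariates are redrawn for the
#' delayed occasion.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Optional RNG seed for reproducibility.
#' @param config See [cohort_config()].
#' @return A data.frame with 2 rows per subject: SUBJ, OCC
#'   ("early"/"delayed"), CLCR (mL/s), AGE, SEX (1 = male, 0 = female),
#'   WT, HT, SCR, BILI, FLUID, NOREPI, FUROS, SMOKE ("Y"/"N"/NA), CVVHD.
#' @export
sample_cohort <- function(n, seed = NULL, config = cohort_config()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    if (config$rho_age_clcr != 0) {
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      rho <- config$rho_age_clcr
      la <- config$age$mu + config$age$sigma * z1
      lc <- config$clcr$mu +
        config$clcr$sigma * (rho * z1 + sqrt(1 - rho^2) * z2)
      age <- exp(la); clcr_e <- exp(lc)
    } else {
      age <- rln(n, config$age); clcr_e <- rln(n, config$clcr)
    }
    day_draw <- function(clcr) data.frame(
      CLCR = clcr,
      SCR = rln(n, config$scr),
      BILI = rln(n, config$bili),
      FLUID = stats::rnorm(n, config$fluid$mu, config$fluid$sigma),
      NOREPI = ifelse(stats::runif(n) < config$norepi$p_zero, 0,
                      exp(stats::rnorm(n, config$norepi$mu,
                                       config$norepi$sigma))),
      FUROS = ifelse(stats::runif(n) < config$furos$p_zero, 0,
                     exp(stats::rnorm(n, config$furos$mu,
                                      config$furos$sigma))))
    subj <- data.frame(
      SUBJ = seq_len(n),
      AGE = age,
      SEX = as.integer(stats::runif(n) < config$p_male),
      WT = rln(n, config$weight),
      HT = rln(n, config$height),
      SMOKE = sample(c("Y", "N", NA_character_), n, replace = TRUE,
                     prob = config$p_smoker),
      CVVHD = as.integer(stats::runif(n) < config$p_cvvhd))
    early <- cbind(subj, OCC = "early", day_draw(clcr_e))
    delayed <- cbind(subj, OCC = "delayed",
                     day_draw(rln(n, config$clcr_delayed)))
    out <- rbind(early, delayed)
    out <- out[order(out$SUBJ, out$OCC == "delayed"), ]
    rownames(out) <- NULL
    out[, c("SUBJ", "OCC", "CLCR", "AGE", "SEX", "WT", "HT", "SCR",
            "BILI", "FLUID", "NOREPI", "FUROS", "SMOKE", "CVVHD")]
  })
}

#' Assign dosing regimens
#'
#' The three regimens in clinical use: 400 mg q12h (800 mg/day),
#' 400 mg q8h and 600 mg q12h (both 1200 mg/day).
#'
#' @param n Number of subjects, or a cohort data.frame from
#'   [sample_cohort()] (its number of subjects is used).
#' @param policy `"random-mix"` (equal thirds) or `"fixed"`.
#' @param amount,interval Dose (mg) and interval (h) when `policy =
#'   "fixed"`; must be one of the three allowed regimens.
#' @param seed Optional RNG seed for the random mix.
#' @return data.frame SUBJ, AMT, INTERVAL, DAILY.
#' @export
assign_regimen <- function(n, policy = c("random-mix", "fixed"),
                           amount = 400, interval = 12, seed = NULL) {
  policy <- match.arg(policy)
  if (is.data.frame(n)) n <- length(unique(n$SUBJ))
  allowed <- data.frame(AMT = c(400, 400, 600), INTERVAL = c(12, 8, 12))
  if (policy == "fixed") {
    if (!any(allowed$AMT == amount & allowed$INTERVAL == interval))
      stop("allowed regimens: 400 q12h, 400 q8h, 600 q12h", call. = FALSE)
    idx <- rep(which(allowed$AMT == amount & allowed$INTERVAL == interval), n)
  } else {
    idx <- with_seed(seed, sample.int(3L, n, replace = TRUE))
  }
  data.frame(SUBJ = seq_len(n), AMT = allowed$AMT[idx],
             INTERVAL = allowed$INTERVAL[idx],
             DAILY = 24 / allowed$INTERVAL[idx] * allowed$AMT[idx])
}

#' Simulate a concentration-time dataset
#'
#' Draws individual parameters from the population model
#' (`CL_i = typical_cl(model, CLcr) * exp(eta_CL)`,
#' `Vd_i = Vdp * exp(eta_Vd)`, log-normal between-subject effects, with
#' optional per-occasion effects when the model's `iov_cl`/`iov_vd` are
#' nonzero), computes the one-compartment superposition profile over the
#' full dose history, and adds combined residual error
#' `y = f (1 + eps_prop) + eps_add`. Simulated concentrations are not
#' censored at zero: at clinically realistic additive error (about
#' 1 mg/L) trough concentrations sit within one residual SD of zero, so
#' truncation or rejection would put a sizable probability mass at the
#' boundary and bias the residual-error partition of any Gaussian
#' refit. Each observation's prediction uses its own occasion's
#' CLcr-derived clearance.
#'
#' @param cohort Cohort data.frame from [sample_cohort()].
#' @param regimens Regimen assignment from [assign_regimen()].
#' @param model A [pop_model()] (default [reference_model()]).
#' @param design A [study_design()].
#' @param seed Optional RNG seed.
#' @return Long-format data.frame (one row per dose or observation
#'   event): SUBJ, OCC, TIME, EVID (1 dose / 0 observation), AMT, DUR,
#'   DV, CLCR, AGE, SEX, WT, HT, BILI, FLUID, NOREPI, FUROS, SMOKE,
#'   CVVHD. The simulated individual parameters are attached as
#'   `attr(x, "individual_params")` (SUBJ, OCC, CL, VD).
#' @export
simulate_dataset <- function(cohort, regimens, model = reference_model(),
                             design = study_design(), seed = NULL) {
  stopifnot(inherits(model, "pop_model"), inherits(design, "study_design"))
  ids <- unique(cohort$SUBJ)
  with_seed(seed, {
    rows <- list()
    ipar <- list()
    for (id in ids) {
      cv <- cohort[cohort$SUBJ == id, , drop = FALSE]
      rg <- regimens[regimens$SUBJ == id, , drop = FALSE]
      if (nrow(rg) != 1L)
        stop("exactly one regimen row needed per subject", call. = FALSE)
      tau <- rg$INTERVAL
      dur <- design$infusion_duration
      eta_cl <- stats::rnorm(1, 0, model$omega_cl)
      eta_vd <- stats::rnorm(1, 0, model$omega_vd)
      didx_delayed <- round(design$delayed_time / tau)
      dose_starts <- (seq_len(didx_delayed + 1L) - 1L) * tau
      reg <- regimen(rg$AMT, tau, length(dose_starts),
                     infusion_duration = dur)
      occ_dose <- c(early = (design$early_dose_index - 1L) * tau,
                    delayed = didx_delayed * tau)
      dose_rows <- data.frame(
        SUBJ = id,
        OCC = ifelse(dose_starts < 48, "early", "delayed"),
        TIME = dose_starts, EVID = 1L, AMT = rg$AMT, DUR = dur,
        DV = NA_real_)
      obs_rows <- list()
      for (occ in c("early", "delayed")) {
        cvo <- cv[cv$OCC == occ, , drop = FALSE]
        if (nrow(cvo) == 0L) next
        iov1 <- if (model$iov_cl > 0)
          stats::rnorm(1, 0, model$iov_cl) else 0
        iov2 <- if (model$iov_vd > 0)
          stats::rnorm(1, 0, model$iov_vd) else 0
        cl_i <- typical_cl(model, cvo$CLCR) * exp(eta_cl + iov1)
        vd_i <- model$vdp * exp(eta_vd + iov2)
        times <- occ_dose[[occ]] + dur +
          c(design$sample_offsets, tau - dur)
        f <- conc_profile(pk_params(cl_i, vd_i), reg, times)
        y <- f * (1 + stats::rnorm(length(f), 0, model$sigma_prop)) +
          stats::rnorm(length(f), 0, model$sigma_add)
        obs_rows[[occ]] <- data.frame(
          SUBJ = id, OCC = occ, TIME = times, EVID = 0L,
          AMT = NA_real_, DUR = NA_real_, DV = y)
        ipar[[length(ipar) + 1L]] <- data.frame(
          SUBJ = id, OCC = occ, CL = cl_i, VD = vd_i)
      }
      sub <- rbind(dose_rows, do.call(rbind, obs_rows))
      # attach the occasion's covariates to every row; dose rows use the
      # occasion active at their time
      covcols <- c("CLCR", "AGE", "SEX", "WT", "HT", "BILI", "FLUID",
                   "NOREPI", "FUROS", "SMOKE", "CVVHD")
      for (cc in covcols) sub[[cc]] <- NA
      for (occ in c("early", "delayed")) {
        cvo <- cv[cv$OCC == occ, , drop = FALSE]
        if (nrow(cvo) == 0L) next
        sel <- sub$OCC == occ
        for (cc in covcols) sub[[cc]][sel] <- cvo[[cc]]
      }
      rows[[length(rows) + 1L]] <- sub
    }
    out <- do.call(rbind, rows)
    out <- out[order(match(out$SUBJ, ids), out$TIME, -out$EVID), ]
    rownames(out) <- NULL
    attr(out, "individual_params") <- do.call(rbind, ipar)
    out
  })
}

#' Write / read the long-format dataset CSV
#'
#' One row per event; times with two decimals; missing values written as
#' `"."`.
#'
#' @param data Dataset from [simulate_dataset()] (or compatible).
#' @param path File path.
#' @return `write_pk_dataset` returns `path` invisibly;
#'   `read_pk_dataset` returns the dataset data.frame.
#' @export
write_pk_dataset <- function(data, path) {
  out <- data
  out$TIME <- sprintf("%.2f", out$TIME)
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.numeric(v) && nm != "TIME")
      out[[nm]] <- ifelse(is.na(v), ".", formatC(v, format = "g",
                                                 digits = 12))
    else out[[nm]][is.na(out[[nm]])] <- "."
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  raw[raw == "."] <- NA
  num <- setdiff(names(raw), c("OCC", "SMOKE"))
  for (nm in num) raw[[nm]] <- as.numeric(raw[[nm]])
  raw$EVID <- as.integer(raw$EVID)
  if ("SEX" %in% names(raw)) raw$SEX <- as.integer(raw$SEX)
  if ("CVVHD" %in% names(raw)) raw$CVVHD <- as.integer(raw$CVVHD)
  raw
}
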