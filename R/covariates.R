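# Renal-function and body-size covariates recorded per occasion in the
# study design this package emulates. Creatinine concentrations are in
# umol/L throughout; renal clearances are returned in mL/s (divide mL/min
# by 60).

#' Measured creatinine clearance
#'
#' Classical urine-collection clearance `CLcr = Ucr * V / Scr`.
#'
#' @param urine_creatinine Urine creatinine, umol/L.
#' @param urine_flow Urinary flow rate, mL/s.
#' @param serum_creatinine Serum creatinine, umol/L.
#' @return Creatinine clearance in mL/s.
#' @export
measured_clcr <- function(urine_creatinine, urine_flow, serum_creatinine) {
  if (any(urine_creatinine <= 0) || any(urine_flow <= 0))
    stop("urine creatinine and flow must be positive", call. = FALSE)
  if (any(serum_creatinine <= 0))
    stop("serum creatinine must be positive", call. = FALSE)
  urine_creatinine * urine_flow / serum_creatinine
}

#' Per-occasion patient covariates
#'
#' Light validation/normalization of a covariate record. Only the fields a
#' given computation needs must be present; missing required fields raise
#' an error naming the field at the point of use.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Years.
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @param serum_creatinine Serum creatinine, umol/L.
#' @param ... Further recorded covariates (bilirubin umol/L, fluid balance
#'   mL/day, norepinephrine and furosemide mg/day, smoker, cvvhd, clcr
#'   mL/s) kept as-is.
#' @return A named list of class `patient_covariates`.
#' @export
patient_covariates <- function(sex = NULL, age = NULL, weight = NULL,
                               height = NULL, serum_creatinine = NULL, ...) {
  if (!is.null(sex)) sex <- match.arg(sex, c("male", "female"))
  for (nm in c("age", "weight", "height", "serum_creatinine")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
  }
  structure(list(sex = sex, age = age, weight = weight, height = height,
                 serum_creatinine = serum_creatinine, ...),
            class = "patient_covariates")
}

need_cov <- function(cov, fields, formula) {
  for (f in fields) {
    v <- cov[[f]]
    if (is.null(v) || (is.atomic(v) && anyNA(v)))
      stop(sprintf("covariate `%s` is missing but required by the %s formula",
                   f, formula), call. = FALSE)
  }
  invisible(TRUE)
}

#' Estimated glomerular filtration rate
#'
#' Four standard creatinine-based estimates. CKD-EPI uses the 2009
#' creatinine equation without race coefficient; MDRD is the 4-variable
#' IDMS-traceable form; C-G is Cockcroft-Gault; L-M is the revised
#' Lund-Malmo equation. The BSA-indexed formulas (CKD-EPI, MDRD, L-M)
#' return mL/s per 1.73 m2 as-is (no de-indexing); C-G returns absolute
#' mL/s. All mL/min results are divided by 60.
#'
#' Every estimate is strictly decreasing in serum creatinine at fixed
#' other inputs, and CKD-EPI/L-M are continuous across their
#' sex-specific piecewise knots.
#'
#' @param formula One of `"ckd-epi"`, `"mdrd"`, `"cg"`, `"lund-malmo"`.
#' @param cov A [patient_covariates()] record (or plain named list) with at
#'   least `sex`, `age`, `serum_creatinine` (umol/L); C-G also needs
#'   `weight`.
#' @return Estimate in mL/s (indexed formulas: per 1.73 m2).
#' @export
egfr <- function(formula = c("ckd-epi", "mdrd", "cg", "lund-malmo"), cov) {
  formula <- match.arg(formula)
  need_cov(cov, c("sex", "age", "serum_creatinine"), formula)
  sex <- match.arg(cov$sex, c("male", "female"))
  age <- cov$age
  scr <- cov$serum_creatinine
  if (scr <= 0) stop("serum creatinine must be positive", call. = FALSE)
  scr_mgdl <- scr / 88.4
  ml_min <- switch(formula,
    "ckd-epi" = {
      kappa <- if (sex == "female") 0.7 else 0.9
      alpha <- if (sex == "female") -0.329 else -0.411
      141 * pmin(scr_mgdl / kappa, 1)^alpha *
        pmax(scr_mgdl / kappa, 1)^(-1.209) * 0.993^age *
        (if (sex == "female") 1.018 else 1)
    },
    "mdrd" = {
      175 * scr_mgdl^(-1.154) * age^(-0.203) *
        (if (sex == "female") 0.742 else 1)
    },
    "cg" = {
      need_cov(cov, "weight", "cg")
      (140 - age) * cov$weight / (0.814 * scr) *
        (if (sex == "female") 0.85 else 1)
    },
    "lund-malmo" = {
      x <- if (sex == "female") {
        if (scr < 150) 2.50 + 0.0121 * (150 - scr)
        else 2.50 - 0.926 * log(scr / 150)
      } else {
        if (scr < 180) 2.56 + 0.00968 * (180 - scr)
        else 2.56 - 0.926 * log(scr / 180)
      }
      exp(x - 0.0158 * age + 0.438 * log(age))
    })
  ml_min / 60
}

#' DuBois body surface area
#'
#' `BSA = 0.007184 * weight^0.425 * height^0.725`.
#'
#' @param weight kg. @param height cm.
#' @return BSA in m2.
#' @export
bsa_dubois <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  0.007184 * weight^0.425 * height^0.725
}

#' Boer lean body mass
#'
#' Male: `0.407 W + 0.267 H - 19.2`; female: `0.252 W + 0.473 H - 48.3`.
#'
#' @param weight kg. @param height cm. @param sex `"male"` or `"female"`.
#' @return Lean body mass in kg.
#' @export
lbm_boer <- function(weight, height, sex) {
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") 0.407 * weight + 0.267 * height - 19.2
  else 0.252 * weight + 0.473 * height - 48.3
}
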