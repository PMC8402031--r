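# Population model structure and the mixed-effects estimation engine.

test_that("typical clearance follows the covariate law", {
  m <- reference_model()
  expect_equal(typical_cl(m, 1.25), 21.5)
  expect_equal(typical_vd(m), 143)
  expect_equal(typical_cl(m, 0.5), 11.84, tolerance = 1e-12)
  # at the reference point the scaled covariate is 1: linear gives
  # CLp + theta, power gives CLp
  mp <- pop_model(21.5, 0.8, 143, 0.4, 0.3, 1, 0.05, covariate = "power")
  expect_equal(typical_cl(mp, 1.25), 21.5)
  expect_error(typical_cl(m, -1), "positive")
  # inadmissible extrapolation of a negative-slope law
  mneg <- pop_model(5, -10, 143, 0.4, 0.3, 1, 0.05, covariate = "linear")
  expect_error(typical_cl(mneg, 2), "non-positive")
})

test_that("model constructor validates variances and covariate use", {
  expect_error(pop_model(5.4, 16.1, 143, -0.1, 0.3, 1, 0.05),
               "nonnegative")
  expect_error(pop_model(5.4, 16.1, 143, 0.4, 0.3, 1, 0.05,
                         covariate = "none"), "theta")
})

test_that("compiled predictions agree with the R closed form", {
  d <- make_dataset(5, seed = 13)
  fl <- cipropk:::flatten_pkdata(d)
  set.seed(99)
  cl <- exp(rnorm(nrow(fl$obs), log(20), 0.3))
  vd <- exp(rnorm(nrow(fl$obs), log(140), 0.2))
  f_cpp <- cipropk:::cpp_pred(fl$obs_ptr, fl$obs_t, cl, vd, fl$dose_ptr,
                              fl$dose_t, fl$dose_rate, fl$dose_dur)
  subj <- rep(seq_along(fl$ids), diff(fl$obs_ptr))
  for (j in seq_along(f_cpp)) {
    i <- subj[j]
    dd <- (fl$dose_ptr[i] + 1):fl$dose_ptr[i + 1]
    reg <- regimen_from_events(lapply(dd, function(k)
      dose_event(fl$dose_t[k], fl$dose_rate[k] * fl$dose_dur[k],
                 fl$dose_dur[k])))
    expect_equal(f_cpp[j],
                 conc_profile(pk_params(cl[j], vd[j]), reg, fl$obs_t[j]),
                 tolerance = 1e-10)
  }
})

test_that("the OFV is invariant to subject relabeling and row order", {
  d <- make_dataset(10, seed = 29)
  m <- reference_model()
  ofv0 <- pop_ofv(d, m)
  # shuffle rows
  set.seed(1)
  d_shuf <- d[sample(nrow(d)), ]
  expect_equal(pop_ofv(d_shuf, m), ofv0, tolerance = 1e-10)
  # relabel subjects (reverse order)
  d_rel <- d
  d_rel$SUBJ <- max(d$SUBJ) + 1 - d$SUBJ
  expect_equal(pop_ofv(d_rel, m), ofv0, tolerance = 1e-10)
})

test_that("the OFV at the generating model dominates gross perturbations", {
  d <- make_dataset(30, seed = 31)
  m <- reference_model()
  ofv_truth <- pop_ofv(d, m)
  m2 <- pop_model(2 * 5.4, 2 * 16.1, 2 * 143, 0.449, 0.348, 0.981, 0.0478)
  expect_lt(ofv_truth, pop_ofv(d, m2))
})

test_that("without random effects the fit reduces to least squares", {
  # additive-error data from fixed typical parameters
  m0 <- pop_model(21.5, 0, 143, 0, 0, 0.4, 0, covariate = "none")
  coh <- sample_cohort(8, seed = 41)
  reg <- assign_regimen(8, "fixed", 400, 12)
  d <- simulate_dataset(coh, reg, model = m0, seed = 42)
  fit <- nlme_fit(d, fix = list(omega_cl = 0, omega_vd = 0,
                                sigma_prop = 0),
                  control = nlme_control(n_starts = 1, hessian = FALSE))
  # independent route: nonlinear least squares over (CLp, Vdp)
  obs <- d[d$EVID == 0, ]
  rg <- regimen(400, 12, 8)
  nls_obj <- function(p) {
    f <- conc_profile(pk_params(exp(p[1]), exp(p[2])), rg, obs$TIME)
    sum((obs$DV - f)^2)
  }
  opt <- optim(log(c(18, 130)), nls_obj,
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(coef(fit)["clp"]), exp(opt$par[1]), tolerance = 1e-3)
  expect_equal(unname(coef(fit)["vdp"]), exp(opt$par[2]), tolerance = 1e-3)
})

test_that("fits are deterministic given the data and control settings", {
  d <- make_dataset(12, seed = 61)
  ctrl <- nlme_control(n_starts = 1, hessian = FALSE)
  f1 <- nlme_fit(d, terms = clcr_term(), control = ctrl)
  f2 <- nlme_fit(d, terms = clcr_term(), control = ctrl)
  expect_identical(coef(f1), coef(f2))
})

test_that("standard errors are reported as relative standard errors", {
  d <- make_dataset(20, seed = 71)
  fit <- nlme_fit(d, terms = clcr_term(),
                  control = nlme_control(n_starts = 1, hessian = TRUE))
  est <- fit$estimates
  expect_true(all(is.finite(est$rse_pct)))
  expect_true(all(est$rse_pct > 0))
  # sparse 6-point-per-subject designs estimate the volume well
  expect_lt(est$rse_pct[est$parameter == "vdp"], 30)
})

test_that("covariate selection keeps a complete ledger", {
  d <- make_dataset(15, seed = 81)
  ctrl <- nlme_control(n_starts = 1, hessian = FALSE)
  st <- covariate_step(d, candidates = list(clcr_term(),
                                            cov_effect("CL", "AGE",
                                                       "linear", ref = 58)),
                       control = ctrl)
  expect_true(all(c("step", "param", "cov", "law", "ofv", "dofv",
                    "selected") %in% names(st$ledger)))
  expect_gte(nrow(st$ledger), 2)
  # empty candidate list returns the base model unchanged
  st0 <- covariate_step(d, candidates = list(), control = ctrl)
  expect_equal(st0$fit$ofv, st0$base_fit$ofv)
})
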