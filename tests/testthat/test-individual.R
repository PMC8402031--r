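# MAP-Bayesian individual estimation and its statistical second stage.

ref_times <- c(13.5, 16.5, 24)
ref_reg <- regimen(400, 12, 8)

test_that("noise-free data are recovered to 4 significant digits", {
  y <- conc_profile(pk_params(20, 150), ref_reg, ref_times)
  fit <- map_fit(ref_times, y, ref_reg, flat_prior())
  expect_equal(fit$pk$cl, 20, tolerance = 1e-4)
  expect_equal(fit$pk$vd, 150, tolerance = 1e-4)
  expect_lt(fit$wss, 1e-8)
  expect_equal(fit$rms, sqrt(fit$wss / 3))
})

test_that("the no-data limit returns the prior mode and 1 point errors", {
  f0 <- map_fit(numeric(0), numeric(0), ref_reg, default_prior())
  expect_equal(f0$pk$cl, 18.59)
  expect_equal(f0$pk$vd, 136.9)
  expect_equal(f0$wss, 0)
  expect_true(is.na(f0$rms))
  expect_error(map_fit(13.5, 3.1, ref_reg, default_prior()),
               "insufficient")
  expect_error(map_fit(numeric(0), numeric(0), ref_reg, flat_prior()),
               "informative")
})

test_that("flat-prior MAP equals weighted least squares", {
  set.seed(31)
  for (i in 1:5) {
    cl0 <- 20 * exp(rnorm(1, 0, 0.3))
    vd0 <- 140 * exp(rnorm(1, 0, 0.25))
    y <- conc_profile(pk_params(cl0, vd0), ref_reg, ref_times) *
      (1 + rnorm(3, 0, 0.08)) + rnorm(3, 0, 0.03)
    y <- abs(y)
    fit <- map_fit(ref_times, y, ref_reg, flat_prior())
    # independent route: direct Nelder-Mead on the WLS criterion
    wls <- function(p) {
      f <- conc_profile(pk_params(exp(p[1]), exp(p[2])), ref_reg, ref_times)
      sum((y - f)^2 / ((0.1 * f)^2 + 0.05^2))
    }
    opt <- optim(log(c(20, 140)), wls, control = list(reltol = 1e-14,
                                                      maxit = 5000))
    expect_equal(fit$wss, opt$value, tolerance = 1e-3)
    expect_equal(log(fit$pk$cl), opt$par[1], tolerance = 1e-3)
  }
})

test_that("the MAP objective trace is monotone and beats the prior point", {
  set.seed(55)
  for (i in 1:5) {
    cl0 <- 18.59 * exp(rnorm(1, 0, 0.4))
    vd0 <- 136.9 * exp(rnorm(1, 0, 0.3))
    y <- conc_profile(pk_params(cl0, vd0), ref_reg, ref_times) *
      (1 + rnorm(3, 0, 0.1))
    y <- abs(y)
    fit <- map_fit(ref_times, y, ref_reg, default_prior())
    expect_true(all(diff(fit$trace) <= 1e-12))
    # WSS at the optimum cannot exceed WSS at the prior central values
    f_prior <- conc_profile(pk_params(18.59, 136.9), ref_reg, ref_times)
    wss_prior <- sum((y - f_prior)^2 / ((0.1 * f_prior)^2 + 0.05^2))
    expect_lte(fit$wss, wss_prior + 1e-9)
  }
})

test_that("MAP recovers simulated individual clearances on a cohort", {
  set.seed(77)
  n <- 60
  ratios <- numeric(n)
  for (i in 1:n) {
    cl_i <- 21.5 * exp(rnorm(1, 0, truth$omega_cl))
    vd_i <- 143 * exp(rnorm(1, 0, truth$omega_vd))
    y <- conc_profile(pk_params(cl_i, vd_i), ref_reg, ref_times) *
      (1 + rnorm(3, 0, 0.10))
    fit <- map_fit(ref_times, abs(y), ref_reg, flat_prior())
    ratios[i] <- fit$pk$cl / cl_i
  }
  expect_equal(median(ratios), 1, tolerance = 0.05)
})

test_that("Mann-Whitney U follows the documented exact/approximate policy", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # exact: 2/choose(6,3) * 1
  # identical samples: U = n^2/2 by symmetry, p in the no-evidence region
  mw2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$U, 9 / 2)
  expect_gt(mw2$p, 0.9)
  # rank statistics are invariant to adding a constant to both samples
  a <- c(2.3, 5.1, 7.7, 4.2); b <- c(3.3, 8.8, 1.2, 9.9, 6.6)
  expect_equal(mann_whitney(a + 17, b + 17), mann_whitney(a, b))
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("regression screen recovers exact and noisy linear relations", {
  x <- c(1, 2, 3, 4, 5)
  r <- suppressWarnings(ols_regression(x, 2 * x))  # perfect fit
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  # jointly permuting pairs changes nothing
  set.seed(8)
  x2 <- rnorm(20); y2 <- 3 * x2 + rnorm(20)
  perm <- sample(20)
  expect_equal(ols_regression(x2[perm], y2[perm], covariate = "c"),
               ols_regression(x2, y2, covariate = "c"))
  expect_error(ols_regression(rep(1, 5), rnorm(5)), "constant")
  expect_error(ols_regression(1:2, 1:2), "at least 3")
})

test_that("the headline clearance-renal function relation is recoverable", {
  # generate CL from the linear relation with noise tuned to r2 ~ 0.63
  set.seed(2021)
  slopes <- replicate(20, {
    clcr <- exp(rnorm(29, log(1.16), 0.6))
    signal_sd <- 18.54 * sd(clcr)
    noise_sd <- signal_sd * sqrt((1 - 0.6275) / 0.6275)
    cl <- 18.54 * clcr + 3.261 + rnorm(29, 0, noise_sd)
    ols_regression(clcr, cl)$slope
  })
  expect_equal(median(slopes), 18.54, tolerance = 0.15)
})

test_that("two-stage summary handles degenerate and missing-pair input", {
  fits <- data.frame(SUBJ = rep(1:4, each = 2),
                     OCC = rep(c("early", "delayed"), 4),
                     CL = 20, VD = 140, THALF = 4.85, WSS = 1, RMS = 0.6,
                     WT = 90, CLCR = 1.2)
  ts <- two_stage_summary(fits, continuous = "CLCR", categorical = NULL)
  expect_equal(unname(ts$cv), c(0, 0, 0))
  expect_true(all(ts$comparisons$p == 1))
  # no subject with both occasions: explicit empty comparison
  fits2 <- fits[fits$OCC == "early", ]
  ts2 <- two_stage_summary(fits2, continuous = "CLCR", categorical = NULL)
  expect_true(ts2$no_paired_subjects)
  expect_equal(nrow(ts2$comparisons), 0)
})

test_that("the two-stage screen has power for CLcr and nominal type I error", {
  # power: CL generated from the renal-function relation at n = 29
  set.seed(404)
  hits <- replicate(20, {
    clcr <- exp(rnorm(29, log(1.16), 0.6))
    noise_sd <- 18.54 * sd(clcr) * sqrt((1 - 0.6275) / 0.6275)
    cl <- 18.54 * clcr + 3.261 + rnorm(29, 0, noise_sd)
    ols_regression(clcr, cl)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
  # null calibration of the early-vs-delayed comparison through the
  # two-stage path (simulated individual parameters, no occasion effect)
  set.seed(505)
  rej <- replicate(200, {
    fits <- data.frame(
      SUBJ = rep(1:14, each = 2), OCC = rep(c("early", "delayed"), 14),
      CL = 21.5 * exp(rnorm(28, 0, 0.449)),
      VD = 143 * exp(rnorm(28, 0, 0.348)),
      THALF = NA, WSS = 1, RMS = 1, WT = 90, CLCR = 1.2)
    fits$THALF <- log(2) * fits$VD / fits$CL
    ts <- two_stage_summary(fits, continuous = NULL, categorical = NULL)
    ts$comparisons$p[ts$comparisons$parameter == "CL_KG"] < 0.05
  })
  expect_gte(mean(rej), 0.015)
  expect_lte(mean(rej), 0.095)
})
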