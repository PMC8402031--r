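# Probability of target attainment and the dosing nomogram.

test_that("closed-form PTA matches its analytic special cases", {
  m <- reference_model()
  # median symmetry: 50% exactly when the critical clearance equals the
  # typical clearance
  tcl <- typical_cl(m, 1.0)
  mic_star <- 1200 / (125 * tcl)
  expect_equal(pta_closed_form(m, 1200, 1.0, mic_star), 50)
  # log-normal formula value
  expect_equal(pta_closed_form(m, 800, 0.5, 0.25),
               100 * pnorm(log(25.6 / 11.84) / 0.449), tolerance = 1e-10)
  expect_equal(pta_closed_form(m, 800, 0.5, 0.25), 95.7, tolerance = 1e-3)
  # strictly decreasing in MIC
  mics <- seq(0.05, 2, by = 0.05)
  expect_true(all(diff(pta_closed_form(m, 800, 1, mics)) < 0))
  # zero-variability model gives a 0/100 step at the critical MIC
  m0 <- pop_model(5.4, 16.1, 143, 0, 0.3, 1, 0.05)
  step_mic <- 800 / (125 * typical_cl(m0, 1))
  expect_equal(pta_closed_form(m0, 800, 1, step_mic * 0.999), 100)
  expect_equal(pta_closed_form(m0, 800, 1, step_mic * 1.001), 0)
})

test_that("Monte Carlo PTA agrees with the closed form", {
  m <- reference_model()
  # tight agreement at large n
  p_mc <- pta_curve(m, 800, 0.5, mic_grid = 0.25, n_sim = 1e5, seed = 1)
  expect_lt(abs(p_mc$pta - pta_closed_form(m, 800, 0.5, 0.25)), 0.5)
  # 3-sigma binomial agreement across a dose x CLcr x MIC grid at the
  # standard simulation size
  grid <- pta_curve(m, c(800, 1200), c(0.5, 1, 1.5), n_sim = 1000,
                    seed = 2)
  for (i in seq_len(nrow(grid))) {
    p_cf <- pta_closed_form(m, grid$daily_dose[i], grid$clcr[i],
                            grid$mic[i])
    se <- 100 * sqrt(pmax(p_cf / 100 * (1 - p_cf / 100), 1e-6) / 1000)
    expect_lt(abs(grid$pta[i] - p_cf), max(3 * se, 0.5))
  }
})

test_that("PTA is monotone in MIC, renal function, and dose", {
  m <- reference_model()
  g <- pta_curve(m, c(800, 1200), c(0.5, 1, 1.5), n_sim = 4000, seed = 3)
  for (dd in unique(g$daily_dose)) for (cc in unique(g$clcr)) {
    sub <- g[g$daily_dose == dd & g$clcr == cc, ]
    expect_true(all(diff(sub$pta[order(sub$mic)]) <= 0))
  }
  # higher clearance -> lower exposure -> lower attainment
  cf <- function(clcr) pta_closed_form(m, 800, clcr, 0.25)
  expect_true(all(diff(sapply(c(0.5, 1, 1.5, 2), cf)) < 0))
  expect_true(all(pta_closed_form(m, 1200, 1, c(0.125, 0.25, 0.5)) >=
                  pta_closed_form(m, 800, 1, c(0.125, 0.25, 0.5))))
})

test_that("nomogram boundary reproduces the attainability arithmetic", {
  nb <- nomogram_boundary(1200)
  expect_equal(nb$clcr_max(0.5), 0.8597, tolerance = 1e-3)
  expect_equal(nb$mic_max(1.16), 0.3876, tolerance = 1e-3)
  # at typical renal function the target is unattainable at MIC >= 0.5
  expect_lt(nb$mic_max(1.16), 0.5)
  # unattainable at any renal function when the critical clearance is
  # below the intercept
  nb800 <- nomogram_boundary(800)
  expect_true(is.na(nb800$clcr_max(3)))
  # doubling the daily dose doubles MIC_max at every CLcr
  nb2 <- nomogram_boundary(2400)
  clcr <- seq(0.2, 3, by = 0.2)
  expect_equal(nb2$mic_max(clcr), 2 * nb$mic_max(clcr), tolerance = 1e-12)
  # boundary is continuous (increments shrink with the grid step) and
  # strictly decreasing in CLcr
  tab <- nb$table(seq(0.1, 3.5, by = 0.01))
  expect_true(all(diff(tab$mic_max) < 0))
  tab_fine <- nb$table(seq(0.1, 3.5, by = 0.005))
  expect_equal(max(abs(diff(tab_fine$mic_max))) /
                 max(abs(diff(tab$mic_max))), 0.5, tolerance = 0.02)
})

test_that("nomogram and zero-variability PTA step locate the same boundary", {
  # express the nomogram's clearance law as a population model with
  # omega = 0; attainment flips exactly at MIC_max(CLcr)
  m0 <- pop_model(clp = 3.261, theta_clcr = 18.54 * 1.25, vdp = 143,
                  omega_cl = 0, omega_vd = 0, sigma_add = 0,
                  sigma_prop = 0)
  nb <- nomogram_boundary(1200)
  for (clcr in c(0.5, 1, 1.5, 2.5)) {
    expect_equal(typical_cl(m0, clcr), 18.54 * clcr + 3.261,
                 tolerance = 1e-12)
    mm <- nb$mic_max(clcr)
    expect_equal(pta_closed_form(m0, 1200, clcr, mm * 0.999), 100)
    expect_equal(pta_closed_form(m0, 1200, clcr, mm * 1.001), 0)
  }
})
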