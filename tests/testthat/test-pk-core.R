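# One-compartment infusion kinetics: closed form, superposition,
# exposure identities.

test_that("elimination constants follow from CL and Vd", {
  ep <- elimination_params(pk_params(21.5, 143))
  expect_equal(ep$ke, 21.5 / 143, tolerance = 1e-12)
  expect_equal(ep$ke, 0.15035, tolerance = 1e-4)
  expect_equal(ep$t_half, 4.610, tolerance = 1e-3)

  ep2 <- elimination_params(pk_params(7.3, 7.3))
  expect_equal(ep2$ke, 1)
  expect_equal(ep2$t_half, log(2))

  # cohort-median parameters give the half-life implied by the identity,
  # not the cohort-median half-life (medians do not commute)
  ep3 <- elimination_params(pk_params(18.59, 136.9))
  expect_equal(ep3$t_half, 5.10, tolerance = 1e-2)

  expect_error(pk_params(-1, 100), "positive")
  expect_error(pk_params(10, 0), "positive")
})

test_that("single-infusion concentration matches the closed form", {
  pk <- pk_params(21.5, 143)
  ev <- dose_event(0, 400, 0.5)
  expect_equal(conc_single_infusion(pk, ev, 0.5), 2.695, tolerance = 1e-3)
  expect_equal(conc_single_infusion(pk, ev, 0), 0)
  expect_error(conc_single_infusion(pk, ev, -0.1), "after")
})

test_that("concentration is continuous at end of infusion", {
  set.seed(11)
  for (i in 1:25) {
    pk <- pk_params(exp(runif(1, 1, 4)), exp(runif(1, 3, 6)))
    ev <- dose_event(0, runif(1, 100, 800), runif(1, 0.2, 2))
    eps <- 1e-9
    lo <- conc_single_infusion(pk, ev, ev$infusion_duration - eps)
    hi <- conc_single_infusion(pk, ev, ev$infusion_duration + eps)
    expect_equal(lo, hi, tolerance = 1e-6)
    expect_true(all(conc_single_infusion(pk, ev, seq(0, 24, 0.5)) >= 0))
  }
})

test_that("short-infusion limit approaches the bolus solution", {
  pk <- pk_params(20, 150)
  ke <- 20 / 150
  t <- 5
  ev <- dose_event(0, 400, 1e-6)
  expect_equal(conc_single_infusion(pk, ev, t),
               400 / 150 * exp(-ke * t), tolerance = 1e-5)
})

test_that("profiles superpose linearly over dose events", {
  pk <- pk_params(21.5, 143)
  times <- seq(0, 40, by = 0.25)
  reg1 <- regimen(400, 12, 1)
  # single event profile equals the single-infusion solution
  expect_identical(conc_profile(pk, reg1, times),
                   conc_single_infusion(pk, dose_event(0, 400), times))
  # two doses equal the sum of two shifted single-dose profiles, exactly
  reg2 <- regimen(400, 12, 2)
  ev2 <- dose_event(12, 400)
  manual <- conc_single_infusion(pk, dose_event(0, 400), times) +
    ifelse(times >= 12, conc_single_infusion(pk, ev2, pmax(times, 12)), 0)
  expect_equal(conc_profile(pk, reg2, times), manual, tolerance = 1e-12)
  # doubling every amount doubles every concentration
  reg2x <- regimen(800, 12, 2)
  expect_equal(conc_profile(pk, reg2x, times),
               2 * conc_profile(pk, reg2, times), tolerance = 1e-12)
  expect_error(regimen_from_events(list()), "at least one dose")
})

test_that("within an interval the peak sits at the end of the infusion", {
  pk <- pk_params(15, 120)
  reg <- regimen(400, 12, 10)
  tgrid <- seq(96, 108, by = 0.01)
  conc <- conc_profile(pk, reg, tgrid)
  expect_equal(tgrid[which.max(conc)], 96.5, tolerance = 0.011)
})

test_that("steady-state AUC24 equals daily dose over clearance", {
  pk <- pk_params(21.5, 143)
  expect_equal(auc_steady_state(pk, 1200), 55.81, tolerance = 1e-3)
  expect_equal(auc_steady_state(pk_params(400, 100), 400), 1)

  # trapezoid integration over one steady-state interval agrees within
  # 1% once >= 10 half-lives have elapsed, independent of Vd
  for (vd in c(80, 143, 250)) {
    pkv <- pk_params(21.5, vd)
    t_half <- elimination_params(pkv)$t_half
    t0 <- 12 * ceiling(10 * t_half / 12)
    tgrid <- seq(t0, t0 + 12, by = 0.005)
    reg <- regimen(400, 12, ceiling((t0 + 12) / 12))
    conc <- conc_profile(pkv, reg, tgrid)
    auc_num <- sum(diff(tgrid) * (head(conc, -1) + tail(conc, -1)) / 2)
    expect_equal(2 * auc_num, auc_steady_state(pkv, 800), tolerance = 0.01)
  }
})
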