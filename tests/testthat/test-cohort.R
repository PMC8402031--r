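# Virtual cohort generator and dataset simulator.

test_that("cohort sampling is reproducible and validates its inputs", {
  c1 <- sample_cohort(20, seed = 42)
  c2 <- sample_cohort(20, seed = 42)
  expect_identical(c1, c2)
  c3 <- sample_cohort(20, seed = 43)
  expect_false(identical(c1, c3))
  expect_error(sample_cohort(0), "positive")
  expect_error(cohort_config(clcr_range = c(3, 1)), "min >= max")
  expect_error(cohort_config(fluid_range = c(100, -100)), "min >= max")
})

test_that("sampled renal function is calibrated to the target median", {
  coh <- sample_cohort(1000, seed = 7)
  med <- median(coh$CLCR[coh$OCC == "early"])
  expect_gt(med, 0.9)
  expect_lt(med, 1.5)
  # delayed-occasion spread is narrower than early
  expect_lt(sd(log(coh$CLCR[coh$OCC == "delayed"])),
            sd(log(coh$CLCR[coh$OCC == "early"])))
})

test_that("regimen assignment covers the allowed regimens only", {
  expect_equal(unique(assign_regimen(5, "fixed", 400, 12)$DAILY), 800)
  expect_equal(unique(assign_regimen(5, "fixed", 600, 12)$DAILY), 1200)
  expect_equal(unique(assign_regimen(5, "fixed", 400, 8)$DAILY), 1200)
  expect_error(assign_regimen(5, "fixed", 600, 8), "allowed")
  expect_error(assign_regimen(5, "whatever"))
  r1 <- assign_regimen(50, "random-mix", seed = 3)
  expect_identical(r1, assign_regimen(50, "random-mix", seed = 3))
  expect_true(all(r1$DAILY %in% c(800, 1200)))
})

test_that("noise-free simulation reproduces the typical profiles exactly", {
  m0 <- pop_model(5.4, 16.1, 143, 0, 0, 0, 0)
  coh <- sample_cohort(4, seed = 1)
  reg <- assign_regimen(4, policy = "fixed", amount = 400, interval = 12)
  d <- simulate_dataset(coh, reg, model = m0, seed = 2)
  obs <- d[d$EVID == 0, ]
  for (i in seq_len(nrow(obs))) {
    pk <- pk_params(typical_cl(m0, obs$CLCR[i]), 143)
    expect_equal(obs$DV[i], conc_profile(pk, regimen(400, 12, 8), obs$TIME[i]),
                 tolerance = 1e-12)
  }
})

test_that("study-scale simulation has the designed size and structure", {
  d <- make_dataset(30, seed = 3)
  obs <- d[d$EVID == 0, ]
  expect_equal(nrow(obs), 30 * 2 * 3)
  expect_true(all(table(obs$SUBJ) == 6))
  # every observation preceded by at least one dose
  for (id in unique(d$SUBJ)) {
    sub <- d[d$SUBJ == id, ]
    expect_true(min(sub$TIME[sub$EVID == 0]) > min(sub$TIME[sub$EVID == 1]))
  }
  # byte-identical under the same seed
  expect_identical(make_dataset(30, seed = 3), d)
})

test_that("simulated clearances follow the generating log-normal law", {
  coh <- sample_cohort(10000, seed = 21)
  reg <- assign_regimen(10000, seed = 22)
  d <- simulate_dataset(coh, reg, seed = 23)
  ip <- attr(d, "individual_params")
  ipe <- ip[ip$OCC == "early", ]
  cohe <- coh[coh$OCC == "early", ]
  ratio <- ipe$CL / typical_cl(reference_model(), cohe$CLCR)
  # CV of CL at fixed CLcr ~ omega (log-normal moments)
  expect_equal(sd(log(ratio)), 0.449, tolerance = 0.03)
  # median individual CL at the reference CLcr converges to CLp + theta
  expect_equal(median(ratio), 1, tolerance = 0.02)
})

test_that("dataset round-trips through the CSV writer and reader", {
  d <- make_dataset(6, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(d, path)
  d2 <- read_pk_dataset(path)
  expect_equal(nrow(d2), nrow(d))
  expect_equal(d2$TIME, d$TIME, tolerance = 1e-9)
  expect_equal(d2$DV, d$DV, tolerance = 1e-9)
  expect_equal(d2$CLCR, d$CLCR, tolerance = 1e-9)
  expect_identical(d2$EVID, d$EVID)
  expect_identical(is.na(d2$DV), is.na(d$DV))
  expect_identical(d2$SMOKE, d$SMOKE)
  unlink(path)
})
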