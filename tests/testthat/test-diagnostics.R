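# Bootstrap, VPC and NPDE diagnostics.

test_that("bootstrap is seed-reproducible and collapses on cloned subjects", {
  base <- make_dataset(8, seed = 1)
  one <- base[base$SUBJ == 1, ]
  clones <- do.call(rbind, lapply(1:8, function(k) {
    s <- one; s$SUBJ <- k; s
  }))
  b <- suppressWarnings(
    bootstrap_ci(clones, terms = clcr_term(), n_boot = 6, seed = 9))
  # all resamples of identical subjects give identical refits
  expect_lt(max(apply(b$estimates, 2, function(x) diff(range(x)))), 1e-6)
  b2 <- suppressWarnings(
    bootstrap_ci(clones, terms = clcr_term(), n_boot = 6, seed = 9))
  expect_identical(b$indices, b2$indices)
  expect_equal(b$summary, b2$summary)
  # CIs withheld below the minimum replicate count
  expect_true(all(is.na(b$summary$ci_lo)))
})

test_that("VPC covers self-simulated data and collapses without noise", {
  m <- reference_model()
  d <- make_dataset(25, seed = 7)
  v <- vpc(d, m, n_sim = 150, seed = 8)
  expect_named(v$bands, c("bin", "n_obs", "obs_p10", "sim_p10_med",
                          "sim_p10_lo", "sim_p10_hi", "obs_p50",
                          "sim_p50_med", "sim_p50_lo", "sim_p50_hi",
                          "obs_p90", "sim_p90_med", "sim_p90_lo",
                          "sim_p90_hi", "median_inside"),
               ignore.order = TRUE)
  expect_gte(v$prop_median_inside, 2 / 3)
  # deterministic under a fixed seed
  v2 <- vpc(d, m, n_sim = 150, seed = 8)
  expect_equal(v$bands, v2$bands)
  # zero variability: bands collapse onto the typical profile
  m0 <- pop_model(5.4, 16.1, 143, 0, 0, 0, 0)
  d0 <- simulate_dataset(sample_cohort(10, seed = 3),
                         assign_regimen(10, "fixed", 400, 12),
                         model = m0, seed = 4)
  v0 <- vpc(d0, m0, n_sim = 50, seed = 5)
  expect_true(all(v0$bands$median_inside))
  expect_equal(v0$bands$sim_p50_lo, v0$bands$sim_p50_hi, tolerance = 1e-12)
  expect_equal(v0$bands$obs_p50, v0$bands$sim_p50_med, tolerance = 1e-12)
})

test_that("NPDE is standard normal under the generating model", {
  m <- reference_model()
  d <- make_dataset(30, seed = 17)
  np <- npde(d, m, K = 300, seed = 18)
  expect_equal(np$n, 180)
  expect_lt(abs(np$mean), 3 * np$se_mean)
  expect_lt(abs(np$var - 1), 3 * np$se_var)
  expect_true(all(is.finite(np$npde)))
  expect_error(npde(d, m, K = 50), "at least 200")
})

test_that("NPDE values do not depend on subject order in the file", {
  m <- reference_model()
  d <- make_dataset(8, seed = 21)
  np1 <- npde(d, m, K = 250, seed = 22)
  # reverse the subject blocks
  ids <- unique(d$SUBJ)
  d2 <- do.call(rbind, lapply(rev(ids), function(i) d[d$SUBJ == i, ]))
  np2 <- npde(d2, m, K = 250, seed = 22)
  obs1 <- d[d$EVID == 0, ]
  obs2 <- d2[d2$EVID == 0, ]
  key1 <- paste(obs1$SUBJ, obs1$TIME)
  key2 <- paste(obs2$SUBJ, obs2$TIME)
  expect_equal(np2$npde[match(key1, key2)], np1$npde, tolerance = 1e-12)
})

test_that("both diagnostics flag a grossly misspecified model", {
  d <- make_dataset(30, seed = 27)
  bad_cl <- pop_model(2 * 5.4, 2 * 16.1, 143, 0.449, 0.348, 0.981, 0.0478)
  np_bad <- npde(d, bad_cl, K = 300, seed = 28)
  expect_lt(np_bad$p_mean, 0.01)
  bad_vd <- pop_model(5.4, 16.1, 2 * 143, 0.449, 0.348, 0.981, 0.0478)
  v_bad <- vpc(d, bad_vd, n_sim = 150, seed = 29)
  expect_lt(v_bad$prop_median_inside, 1)
})
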