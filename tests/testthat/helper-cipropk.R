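# Shared fixtures (built in code, no stored data).

truth <- list(clp = 5.4, theta = 16.1, vdp = 143,
              omega_cl = 0.449, omega_vd = 0.348,
              sigma_add = 0.981, sigma_prop = 0.0478)

# Null (no covariate) model with the same typical CL at the reference
# renal function and the same variability structure.
null_model <- function() {
  pop_model(clp = 21.5, theta_clcr = 0, vdp = truth$vdp,
            omega_cl = truth$omega_cl, omega_vd = truth$omega_vd,
            sigma_add = truth$sigma_add, sigma_prop = truth$sigma_prop,
            covariate = "none")
}

# A study-design dataset: n subjects, two occasions, mixed regimens.
make_dataset <- function(n = 30, seed = 1, model = reference_model()) {
  coh <- sample_cohort(n, seed = seed)
  reg <- assign_regimen(n, seed = seed + 5000L)
  simulate_dataset(coh, reg, model = model, seed = seed + 9000L)
}

clcr_term <- function() cov_effect("CL", "CLCR", "linear", ref = 1.25)

# Simulate-and-refit replicates shared by the acceptance tests: for each
# replicate, data are simulated from `model` under the study design and
# both the base (no-covariate) and CLcr-covariate models are fitted via
# the stepwise selection machinery. Cached per (model kind, nrep) so the
# recovery, selection and shrinkage criteria reuse the same fits.
.acc_cache <- new.env(parent = emptyenv())

replicate_fits <- function(nrep, base_seed, model, quiet = TRUE) {
  key <- sprintf("%s_%d_%d", model$covariate, nrep, base_seed)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  ctrl <- nlme_control(n_starts = 1, hessian = FALSE)
  out <- lapply(seq_len(nrep), function(r) {
    d <- make_dataset(30, seed = base_seed + 17L * r, model = model)
    st <- covariate_step(d, candidates = list(clcr_term()),
                         threshold = 3.84, control = ctrl)
    list(base = coef(st$base_fit),
         cov = coef(st$fit),
         dofv = st$ledger$dofv[1],
         selected = st$ledger$selected[1])
  })
  .acc_cache[[key]] <- out
  out
}
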