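# Simulation-based model diagnostics: nonparametric bootstrap of the
# population fit, visual predictive check (VPC) and normalized
# prediction distribution errors (NPDE).

# Per-observation typical values under a pop_model for a flattened
# dataset (clearance may depend on the observation's occasion CLcr).
model_tv <- function(obs, model) {
  tvcl <- if (model$covariate == "none") rep(model$clp, nrow(obs))
          else typical_cl(model, obs$CLCR)
  list(CL = tvcl, Vd = rep(model$vdp, nrow(obs)))
}

# One simulated replicate of the observation vector for a flattened
# dataset: fresh between-subject effects, same design, combined residual
# error (uncensored, matching the estimation model and the simulator).
sim_replicate <- function(fl, model, tv, subj_of_obs) {
  S <- length(fl$ids)
  e1 <- stats::rnorm(S, 0, model$omega_cl)
  e2 <- stats::rnorm(S, 0, model$omega_vd)
  cl <- tv$CL * exp(e1[subj_of_obs])
  vd <- tv$Vd * exp(e2[subj_of_obs])
  f <- cpp_pred(fl$obs_ptr, fl$obs_t, cl, vd,
                fl$dose_ptr, fl$dose_t, fl$dose_rate, fl$dose_dur)
  f * (1 + stats::rnorm(length(f), 0, model$sigma_prop)) +
    stats::rnorm(length(f), 0, model$sigma_add)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits the model on each
#' replicate, and summarizes the parameter estimates by their median and
#' 2.5/97.5 percentiles. Non-converged or failing replicates are counted
#' and excluded; a failure rate above 20% triggers a warning status.
#'
#' @param data Long-format dataset.
#' @param terms Covariate terms as for [nlme_fit()].
#' @param n_boot Number of bootstrap replicates; percentile CIs are
#'   reported only for `n_boot >= 100`.
#' @param seed RNG seed for the resampling.
#' @param control Fit control; defaults to a single start without
#'   standard errors for speed.
#' @return List of class `bootstrap_result`: `summary` (data.frame
#'   parameter, median, ci_lo, ci_hi), `estimates` (replicate x
#'   parameter matrix), `n_failed`, `fail_rate`, `warning_status`,
#'   `indices` (resampled subject ids per replicate).
#' @export
bootstrap_ci <- function(data, terms = list(), n_boot = 1000, seed = NULL,
                         control = nlme_control(n_starts = 1,
                                                hessian = FALSE,
                                                maxit = 4000)) {
  ids <- unique(data$SUBJ)
  S <- length(ids)
  idx <- with_seed(seed, lapply(seq_len(n_boot), function(b)
    sample(ids, S, replace = TRUE)))
  est <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    boot <- do.call(rbind, lapply(seq_len(S), function(k) {
      sub <- data[data$SUBJ == idx[[b]][k], , drop = FALSE]
      sub$SUBJ <- sprintf("B%03d", k)
      sub
    }))
    fit <- tryCatch(nlme_fit(boot, terms = terms, control = control),
                    error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0) {
      n_failed <- n_failed + 1L
    } else {
      est[[length(est) + 1L]] <- coef(fit)
    }
  }
  if (length(est) == 0L)
    stop("all bootstrap replicates failed", call. = FALSE)
  em <- do.call(rbind, est)
  summary <- data.frame(
    parameter = colnames(em),
    median = apply(em, 2, stats::median),
    ci_lo = if (n_boot >= 100) apply(em, 2, stats::quantile, 0.025)
            else NA_real_,
    ci_hi = if (n_boot >= 100) apply(em, 2, stats::quantile, 0.975)
            else NA_real_,
    row.names = NULL)
  fail_rate <- n_failed / n_boot
  if (fail_rate > 0.2)
    warning(sprintf("%.0f%% of bootstrap replicates failed", 100 * fail_rate))
  structure(list(summary = summary, estimates = em, n_failed = n_failed,
                 fail_rate = fail_rate,
                 warning_status = fail_rate > 0.2, indices = idx),
            class = "bootstrap_result")
}

# Nominal sample-offset bin for each observation: time after the end of
# the most recent infusion, mapped to the design's nominal samples
# (1 h, 4 h, trough).
nominal_bins <- function(fl) {
  n <- length(fl$obs_t)
  subj_of_obs <- rep(seq_along(fl$ids), diff(fl$obs_ptr))
  off <- numeric(n)
  for (j in seq_len(n)) {
    i <- subj_of_obs[j]
    d0 <- fl$dose_ptr[i] + 1L; d1 <- fl$dose_ptr[i + 1L]
    starts <- fl$dose_t[d0:d1]
    durs <- fl$dose_dur[d0:d1]
    k <- max(which(starts <= fl$obs_t[j]))
    off[j] <- fl$obs_t[j] - (starts[k] + durs[k])
  }
  bin <- ifelse(abs(off - 1) < 1.5, "1h",
                ifelse(abs(off - 4) < 2, "4h", "trough"))
  factor(bin, levels = c("1h", "4h", "trough"))
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset at its own design under
#' the model, bins observations by nominal sample offset (1 h, 4 h,
#' trough after end of infusion), and compares the observed 10th/50th/
#' 90th concentration percentiles per bin with the 95% confidence bands
#' of the same percentiles across simulations. Bins with fewer than 5
#' observations are merged into their neighbor (with a message).
#'
#' @param data Long-format dataset.
#' @param model A [pop_model()].
#' @param n_sim Number of simulated replicates (default 1000).
#' @param seed RNG seed.
#' @return List of class `vpc_result` with `bands` (data.frame: bin,
#'   n_obs, obs/sim percentiles and CI bounds, `median_inside`) and
#'   `prop_median_inside`.
#' @export
vpc <- function(data, model, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(model, "pop_model"))
  fl <- flatten_pkdata(data)
  tv <- model_tv(fl$obs, model)
  subj_of_obs <- rep(seq_along(fl$ids), diff(fl$obs_ptr))
  bins <- nominal_bins(fl)
  tb <- table(bins)
  if (any(tb < 5)) {
    small <- names(tb)[tb < 5]
    message("merging sparse VPC bin(s) into neighbor: ",
            paste(small, collapse = ", "))
    lv <- levels(bins)
    for (s in small) {
      pos <- match(s, lv)
      nb <- lv[if (pos == 1) 2 else pos - 1]
      bins[bins == s] <- nb
    }
    bins <- droplevels(bins)
  }
  probs <- c(0.1, 0.5, 0.9)
  pct <- function(y) vapply(split(y, bins), stats::quantile,
                            numeric(3), probs = probs, names = FALSE)
  obs_p <- pct(fl$obs_y)           # 3 x nbin
  sims <- with_seed(seed, replicate(n_sim,
    pct(sim_replicate(fl, model, tv, subj_of_obs))))  # 3 x nbin x n_sim
  bands <- do.call(rbind, lapply(seq_along(levels(bins)), function(bi) {
    row <- data.frame(bin = levels(bins)[bi], n_obs = sum(bins == levels(bins)[bi]))
    for (pi in 1:3) {
      lab <- c("p10", "p50", "p90")[pi]
      sv <- sims[pi, bi, ]
      row[[paste0("obs_", lab)]] <- obs_p[pi, bi]
      row[[paste0("sim_", lab, "_med")]] <- stats::median(sv)
      row[[paste0("sim_", lab, "_lo")]] <- stats::quantile(sv, 0.025,
                                                           names = FALSE)
      row[[paste0("sim_", lab, "_hi")]] <- stats::quantile(sv, 0.975,
                                                           names = FALSE)
    }
    row$median_inside <- row$obs_p50 >= row$sim_p50_lo &
      row$obs_p50 <= row$sim_p50_hi
    row
  }))
  structure(list(bands = bands,
                 prop_median_inside = mean(bands$median_inside),
                 n_sim = n_sim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC (%d simulations): observed median inside its 95%% band in %.0f%% of bins\n",
              x$n_sim, 100 * x$prop_median_inside))
  print(x$bands[, c("bin", "n_obs", "obs_p50", "sim_p50_lo",
                    "sim_p50_hi", "median_inside")], row.names = FALSE)
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates `K` replicate observation vectors under
#' the model, decorrelates the observed and simulated vectors with the
#' simulated mean and the Cholesky factor of the simulated covariance,
#' and converts the rank of each decorrelated observation among its
#' simulations into a standard-normal score `NPDE = qnorm(pd)` (`pd`
#' kept off 0 and 1 by a half-count correction). Under a correct model
#' the NPDE are approximately N(0, 1); the mean is tested against 0
#' (t-test) and the variance against 1 (chi-square test), each with its
#' standard error. Singular simulated covariances get a small ridge
#' (logged via message). Results are invariant to subject ordering:
#' simulation streams are keyed to sorted subject ids.
#'
#' @param data Long-format dataset.
#' @param model A [pop_model()].
#' @param K Simulated replicates per subject (default 1000, minimum
#'   200).
#' @param seed RNG seed.
#' @return List of class `npde_result`: `npde` (per observation, dataset
#'   order), `mean`, `se_mean`, `p_mean`, `var`, `se_var`, `p_var`, `n`.
#' @export
npde <- function(data, model, K = 1000, seed = NULL) {
  stopifnot(inherits(model, "pop_model"))
  if (K < 200) stop("K must be at least 200", call. = FALSE)
  fl <- flatten_pkdata(data)
  tv <- model_tv(fl$obs, model)
  S <- length(fl$ids)
  ord <- order(as.character(fl$ids))
  subj_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, S))
  npde_all <- numeric(length(fl$obs_y))
  for (si in seq_len(S)) {
    i <- ord[si]
    o0 <- fl$obs_ptr[i] + 1L; o1 <- fl$obs_ptr[i + 1L]
    nj <- o1 - o0 + 1L
    d0 <- fl$dose_ptr[i] + 1L; d1 <- fl$dose_ptr[i + 1L]
    ptr_i <- as.integer(c(0, nj))
    dptr_i <- as.integer(c(0, d1 - d0 + 1L))
    tvcl <- tv$CL[o0:o1]; tvvd <- tv$Vd[o0:o1]
    y <- fl$obs_y[o0:o1]
    sims <- with_seed(subj_seeds[si], {
      e1 <- stats::rnorm(K, 0, model$omega_cl)
      e2 <- stats::rnorm(K, 0, model$omega_vd)
      out <- matrix(0, K, nj)
      for (k in seq_len(K)) {
        f <- cpp_pred(ptr_i, fl$obs_t[o0:o1], tvcl * exp(e1[k]),
                      tvvd * exp(e2[k]), dptr_i, fl$dose_t[d0:d1],
                      fl$dose_rate[d0:d1], fl$dose_dur[d0:d1])
        out[k, ] <- f * (1 + stats::rnorm(nj, 0, model$sigma_prop)) +
          stats::rnorm(nj, 0, model$sigma_add)
      }
      out
    })
    m <- colMeans(sims)
    V <- stats::cov(sims)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      message("singular simulated covariance for subject ", fl$ids[i],
              "; adding ridge")
      L <- chol(V + diag(1e-8 * mean(diag(V)) + 1e-12, nj))
    }
    ystar <- backsolve(L, y - m, transpose = TRUE)
    sstar <- backsolve(L, t(sims) - m, transpose = TRUE)  # nj x K
    pd <- (rowSums(sstar < ystar)) / K
    pd <- pmin(pmax(pd, 1 / (2 * K)), 1 - 1 / (2 * K))
    npde_all[o0:o1] <- stats::qnorm(pd)
  }
  n <- length(npde_all)
  mu <- mean(npde_all)
  s2 <- stats::var(npde_all)
  se_mean <- sqrt(s2 / n)
  se_var <- s2 * sqrt(2 / (n - 1))
  p_mean <- stats::t.test(npde_all, mu = 0)$p.value
  q <- (n - 1) * s2
  p_var <- 2 * min(stats::pchisq(q, n - 1),
                   stats::pchisq(q, n - 1, lower.tail = FALSE))
  structure(list(npde = npde_all, mean = mu, se_mean = se_mean,
                 p_mean = p_mean, var = s2, se_var = se_var,
                 p_var = min(p_var, 1), n = n, K = K),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (K = %d):\n", x$n, x$K))
  cat(sprintf("  mean = %.3f (SE %.3f), p[mean=0] = %.3g\n",
              x$mean, x$se_mean, x$p_mean))
  cat(sprintf("  variance = %.3f (SE %.3f), p[var=1] = %.3g\n",
              x$var, x$se_var, x$p_var))
  invisible(x)
}
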