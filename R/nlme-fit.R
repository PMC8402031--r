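# Nonlinear mixed-effects estimation for the one-compartment infusion
# model. The marginal likelihood is approximated by a Laplace expansion
# around per-subject conditional modes with a Gauss-Newton Hessian and
# residual variance evaluated at the mode (FOCE-I-type interaction); the
# inner problem runs in compiled code (src/ofv.cpp), the outer profile
# is optimized here with Nelder-Mead multi-start.

#' A covariate effect term for the population model
#'
#' @param param `"CL"` or `"Vd"` — the structural parameter the covariate
#'   acts on.
#' @param cov Name of the dataset column holding the covariate (e.g.
#'   `"CLCR"`).
#' @param law `"linear"` (parameter + theta * x), `"power"`
#'   (parameter * x^theta) or `"fraction"` (parameter * theta^x for a 0/1
#'   category).
#' @param ref Reference value scaling continuous covariates, `x =
#'   cov/ref`; ignored for `"fraction"`.
#' @return A term descriptor used by [nlme_fit()] and [covariate_step()].
#' @export
cov_effect <- function(param = c("CL", "Vd"), cov, law = c("linear", "power",
                       "fraction"), ref = 1) {
  param <- match.arg(param)
  law <- match.arg(law)
  stopifnot(is.character(cov), length(cov) == 1L, ref > 0)
  structure(list(param = param, cov = cov, law = law, ref = ref),
            class = "cov_effect")
}

#' Control options for the population fit
#'
#' @param n_starts Number of deterministic jittered starting points
#'   (default 3); the best final objective wins.
#' @param maxit,reltol Passed to `optim`'s Nelder-Mead.
#' @param hessian Compute the observed-information standard errors.
#' @param nq Number of adaptive Gauss-Hermite quadrature nodes per
#'   random-effect dimension (1 = pure Laplace; 5 or 7 refine the
#'   marginal-likelihood approximation around the conditional mode;
#'   default 5).
#' @return A list of options.
#' @export
nlme_control <- function(n_starts = 3, maxit = 1200, reltol = 1e-9,
                         hessian = TRUE, nq = 5) {
  stopifnot(nq %in% c(1, 5, 7))
  list(n_starts = n_starts, maxit = maxit, reltol = reltol,
       hessian = hessian, nq = nq)
}

# Flatten a long-format dataset into the vectors the compiled objective
# consumes. Subjects keep first-appearance order; rows are sorted by time
# within subject, so the objective is invariant to row permutations.
flatten_pkdata <- function(data) {
  need <- c("SUBJ", "TIME", "EVID", "AMT", "DUR", "DV")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- data[order(match(data$SUBJ, unique(data$SUBJ)), data$TIME,
                     -data$EVID), , drop = FALSE]
  ids <- unique(data$SUBJ)
  obs <- data[data$EVID == 0, , drop = FALSE]
  dos <- data[data$EVID == 1, , drop = FALSE]
  if (nrow(dos) == 0L) stop("dataset contains no dose events", call. = FALSE)
  n_obs <- vapply(ids, function(s) sum(obs$SUBJ == s), integer(1))
  n_dos <- vapply(ids, function(s) sum(dos$SUBJ == s), integer(1))
  if (any(n_dos == 0L))
    stop("every subject needs at least one dose event", call. = FALSE)
  list(ids = ids,
       obs = obs,
       obs_ptr = as.integer(c(0, cumsum(n_obs))),
       obs_t = as.numeric(obs$TIME),
       obs_y = as.numeric(obs$DV),
       dose_ptr = as.integer(c(0, cumsum(n_dos))),
       dose_t = as.numeric(dos$TIME),
       dose_rate = as.numeric(dos$AMT) / as.numeric(dos$DUR),
       dose_dur = as.numeric(dos$DUR))
}

# Typical-value vectors per observation for a term list.
build_tv <- function(obs, terms, clp, vdp, thetas) {
  tv <- list(CL = rep(clp, nrow(obs)), Vd = rep(vdp, nrow(obs)))
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    val <- obs[[tm$cov]]
    if (is.null(val))
      stop("covariate column `", tm$cov, "` not in dataset", call. = FALSE)
    th <- thetas[[k]]
    x <- as.numeric(val)
    if (tm$law == "fraction") {
      if (!all(x %in% c(0, 1)))
        stop("fraction-law covariate `", tm$cov, "` must be coded 0/1",
             call. = FALSE)
      tv[[tm$param]] <- tv[[tm$param]] * th^x
    } else {
      x <- x / tm$ref
      if (tm$law == "linear") tv[[tm$param]] <- tv[[tm$param]] + th * x
      else tv[[tm$param]] <- tv[[tm$param]] * x^th
    }
  }
  tv
}

theta_name <- function(tm) sprintf("theta_%s_%s", tm$cov, tolower(tm$param))

# Parameter packing: log scale for positive parameters, identity for
# linear/power covariate coefficients (so nested no-effect models sit in
# the interior and likelihood-ratio tests keep their nominal chi-square
# behaviour).
make_pack <- function(terms, start, fix) {
  entries <- list(list(name = "clp", trans = "log", init = start$clp))
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    tr <- if (tm$law == "fraction") "log" else "id"
    entries[[length(entries) + 1L]] <-
      list(name = theta_name(tm), trans = tr, init = start$thetas[[k]])
  }
  entries[[length(entries) + 1L]] <- list(name = "vdp", trans = "log",
                                          init = start$vdp)
  for (nm in c("omega_cl", "omega_vd", "sigma_add", "sigma_prop"))
    entries[[length(entries) + 1L]] <- list(name = nm, trans = "log",
                                            init = start[[nm]])
  nms <- vapply(entries, `[[`, character(1), "name")
  free <- !(nms %in% names(fix))
  list(entries = entries, names = nms, free = free, fix = fix)
}

pack_init <- function(pack) {
  p <- vapply(pack$entries[pack$free], function(e)
    if (e$trans == "log") log(e$init) else e$init, numeric(1))
  names(p) <- pack$names[pack$free]
  p
}

unpack_params <- function(pack, p) {
  out <- list()
  j <- 0L
  for (k in seq_along(pack$entries)) {
    e <- pack$entries[[k]]
    if (pack$free[k]) {
      j <- j + 1L
      out[[e$name]] <- if (e$trans == "log") exp(p[[j]]) else p[[j]]
    } else {
      out[[e$name]] <- pack$fix[[e$name]]
    }
  }
  out
}

default_start <- function(terms, obs) {
  has_cl_cov <- any(vapply(terms, function(t)
    t$param == "CL" && t$law == "linear", logical(1)))
  thetas <- lapply(terms, function(tm) {
    if (tm$law == "fraction") return(1.0)
    if (tm$law == "power") return(0.75)
    # linear: half the typical parameter spread over the scaled covariate
    base <- if (tm$param == "CL") 18.59 else 136.9
    xbar <- mean(as.numeric(obs[[tm$cov]])) / tm$ref
    0.5 * base / max(xbar, 0.1)
  })
  list(clp = if (has_cl_cov) 18.59 / 2 else 18.59,
       vdp = 136.9, thetas = thetas,
       omega_cl = 0.3, omega_vd = 0.3,
       sigma_add = 0.5, sigma_prop = 0.1)
}

jitter_start <- function(start, k) {
  if (k == 1L) return(start)
  f <- if (k == 2L) list(clp = 1.6, vdp = 0.7, om = 0.6, sa = 2.0,
                         sp = 1.0, th = 0.6)
       else         list(clp = 0.5, vdp = 1.5, om = 1.8, sa = 0.7,
                         sp = 2.0, th = 1.5)
  start$clp <- start$clp * f$clp
  start$vdp <- start$vdp * f$vdp
  start$omega_cl <- start$omega_cl * f$om
  start$omega_vd <- start$omega_vd * f$om
  start$sigma_add <- start$sigma_add * f$sa
  start$sigma_prop <- start$sigma_prop * f$sp
  start$thetas <- lapply(start$thetas, `*`, f$th)
  start
}

#' Fit the population model by approximate marginal likelihood
#'
#' Maximizes an approximate marginal likelihood of the one-compartment
#' infusion model with log-normal between-subject effects on CL and Vd
#' and a combined residual error. The approximation expands around
#' per-subject conditional modes (Laplace/FOCE-I-type, with the residual
#' variance evaluated at the mode) and, by default, refines the
#' integral with adaptive Gauss-Hermite quadrature (see
#' [nlme_control()]'s `nq`).
#' The objective function value (OFV) is -2 log approximate marginal
#' likelihood including all constants; only OFV differences between
#' nested models on the same data are interpretable.
#'
#' @param data Long-format dataset (see [simulate_dataset()] /
#'   [read_pk_dataset()]): columns SUBJ, TIME, EVID, AMT, DUR, DV plus any
#'   covariate columns named by `terms`.
#' @param terms List of [cov_effect()] covariate terms; empty list (the
#'   default) fits the base model without covariates.
#' @param start Optional named list overriding default starting values
#'   (`clp`, `vdp`, `thetas`, `omega_cl`, `omega_vd`, `sigma_add`,
#'   `sigma_prop`).
#' @param fix Named list of parameters to hold fixed (e.g.
#'   `list(omega_cl = 0, omega_vd = 0)` for the no-random-effects limit,
#'   where the fit reduces to extended least squares).
#' @param control See [nlme_control()].
#' @return An object of class `pop_fit` with elements `estimates`
#'   (data.frame of parameter, estimate, rse_pct), `ofv`, `model` (a
#'   [pop_model()] when the term structure maps onto one), `eta`
#'   (empirical Bayes modes), `ipred`, `convergence` (0 = converged) and
#'   bookkeeping fields.
#' @export
nlme_fit <- function(data, terms = list(), start = NULL, fix = NULL,
                     control = nlme_control()) {
  if (inherits(terms, "cov_effect")) terms <- list(terms)
  fl <- flatten_pkdata(data)
  n_subj <- length(fl$ids)
  n_per <- diff(fl$obs_ptr)
  if (n_subj < 6)
    stop("population fit needs at least 6 subjects", call. = FALSE)
  if (any(n_per < 2))
    stop("every subject needs at least 2 observations", call. = FALSE)

  st0 <- default_start(terms, fl$obs)
  if (!is.null(start)) st0[names(start)] <- start
  fix <- if (is.null(fix)) list() else fix
  pack <- make_pack(terms, st0, fix)

  eta_env <- new.env(parent = emptyenv())
  eta_env$eta <- matrix(0.0, 2, n_subj)
  objective <- function(p) {
    th <- unpack_params(pack, p)
    thetas <- lapply(terms, function(tm) th[[theta_name(tm)]])
    tv <- build_tv(fl$obs, terms, th$clp, th$vdp, thetas)
    if (any(!is.finite(tv$CL)) || any(tv$CL <= 1e-8) ||
        any(!is.finite(tv$Vd)) || any(tv$Vd <= 1e-8))
      return(1e10)
    res <- cpp_ofv(fl$obs_ptr, fl$obs_t, fl$obs_y, tv$CL, tv$Vd,
                   fl$dose_ptr, fl$dose_t, fl$dose_rate, fl$dose_dur,
                   th$omega_cl, th$omega_vd, th$sigma_add, th$sigma_prop,
                   eta_env$eta, control$nq)
    if (!is.finite(res$ofv)) return(1e10)
    eta_env$eta <- res$eta
    eta_env$ipred <- res$ipred
    res$ofv
  }

  best <- NULL
  for (k in seq_len(control$n_starts)) {
    stk <- jitter_start(st0, k)
    packk <- make_pack(terms, stk, fix)
    p0 <- pack_init(packk)
    eta_env$eta <- matrix(0.0, 2, n_subj)
    opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    # restart Nelder-Mead once from its own optimum (escapes collapse of
    # the simplex on ridged surfaces)
    opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  ofv <- objective(best$par)  # refresh eta/ipred cache at the optimum
  th <- unpack_params(pack, best$par)

  rse <- rep(NA_real_, sum(pack$free))
  if (isTRUE(control$hessian)) {
    H <- num_hessian(function(p) 0.5 * objective(p), best$par)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      se_t <- sqrt(diag(V))
      trans <- vapply(pack$entries[pack$free], `[[`, character(1), "trans")
      est_t <- best$par
      rse <- ifelse(trans == "log", 100 * se_t,
                    100 * se_t / pmax(abs(est_t), 1e-12))
    }
    ofv <- objective(best$par)
  }

  est <- data.frame(parameter = pack$names, estimate = unlist(th[pack$names]),
                    rse_pct = NA_real_, row.names = NULL,
                    stringsAsFactors = FALSE)
  est$rse_pct[match(pack$names[pack$free], est$parameter)] <- rse

  fit <- structure(list(estimates = est, ofv = ofv, terms = terms,
                        fix = fix, params = th,
                        eta = eta_env$eta, ipred = eta_env$ipred,
                        ids = fl$ids, n_subj = n_subj,
                        n_obs = length(fl$obs_y),
                        convergence = best$convergence,
                        model = NULL),
                   class = "pop_fit")
  fit$model <- as_pop_model(fit)
  fit
}

# Map a fitted term structure back onto a pop_model when it is one of the
# standard clearance laws; NULL otherwise.
as_pop_model <- function(fit) {
  th <- fit$params
  terms <- fit$terms
  mk <- function(covariate, theta, ref) {
    pop_model(clp = th$clp, theta_clcr = theta, vdp = th$vdp,
              omega_cl = th$omega_cl, omega_vd = th$omega_vd,
              sigma_add = th$sigma_add, sigma_prop = th$sigma_prop,
              covariate = covariate, clcr_ref = ref)
  }
  if (length(terms) == 0L) return(mk("none", 0, 1.25))
  if (length(terms) == 1L && terms[[1L]]$param == "CL" &&
      terms[[1L]]$law %in% c("linear", "power")) {
    tm <- terms[[1L]]
    return(tryCatch(mk(tm$law, th[[theta_name(tm)]], tm$ref),
                    error = function(e) NULL))
  }
  NULL
}

#' @export
print.pop_fit <- function(x, ...) {
  cat(sprintf("Population fit: %d subjects, %d observations\n",
              x$n_subj, x$n_obs))
  cat(sprintf("OFV = %.3f (convergence code %d)\n", x$ofv, x$convergence))
  est <- x$estimates
  est$estimate <- signif(est$estimate, 4)
  est$rse_pct <- signif(est$rse_pct, 3)
  print(est, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pop_fit <- function(object, ...) {
  stats::setNames(object$estimates$estimate, object$estimates$parameter)
}

#' Objective function value of a dataset under a fixed population model
#'
#' Evaluates the approximate -2 log marginal likelihood (same objective
#' as [nlme_fit()]) at the parameters of a given [pop_model()], without
#' any estimation. Useful for likelihood-dominance checks and for
#' comparing candidate parameter sets on the same data.
#'
#' @param data Long-format dataset.
#' @param model A [pop_model()].
#' @param nq Quadrature nodes per dimension (see [nlme_control()]).
#' @return The OFV (scalar).
#' @export
pop_ofv <- function(data, model, nq = 5) {
  stopifnot(inherits(model, "pop_model"))
  fl <- flatten_pkdata(data)
  tv <- model_tv(fl$obs, model)
  res <- cpp_ofv(fl$obs_ptr, fl$obs_t, fl$obs_y, tv$CL, tv$Vd,
                 fl$dose_ptr, fl$dose_t, fl$dose_rate, fl$dose_dur,
                 model$omega_cl, model$omega_vd, model$sigma_add,
                 model$sigma_prop, matrix(0, 2, length(fl$ids)), nq)
  res$ofv
}

#' Stepwise forward covariate selection
#'
#' Starting from a base model, repeatedly adds the candidate covariate
#' term with the largest drop in objective function value, as long as
#' that drop exceeds `threshold` (default 3.84, the 5% point of the
#' chi-square distribution with 1 degree of freedom for one added
#' parameter). Every tested pair is recorded in a ledger together with
#' its OFV drop, and the between-subject CV% of CL and Vd is tracked
#' before and after each inclusion.
#'
#' @param data Long-format dataset as for [nlme_fit()].
#' @param candidates List of [cov_effect()] candidate terms.
#' @param base_terms Terms already in the base model (default none).
#' @param threshold OFV-drop threshold for inclusion.
#' @param control See [nlme_control()].
#' @return List with `fit` (final [nlme_fit()] result), `selected`
#'   (list of included terms), `ledger` (data.frame: step, param, cov,
#'   law, ofv, dofv, selected), `base_fit`, and `iiv_path` (CV% of CL/Vd
#'   after each accepted step).
#' @export
covariate_step <- function(data, candidates, base_terms = list(),
                           threshold = 3.84, control = nlme_control()) {
  base_fit <- nlme_fit(data, terms = base_terms, control = control)
  if (length(candidates) == 0L)
    return(list(fit = base_fit, selected = list(),
                ledger = data.frame(), base_fit = base_fit,
                iiv_path = data.frame(
                  step = 0L, cv_cl = 100 * base_fit$params$omega_cl,
                  cv_vd = 100 * base_fit$params$omega_vd)))
  selected <- base_terms
  current <- base_fit
  remaining <- candidates
  ledger <- list()
  iiv <- list(data.frame(step = 0L,
                         cv_cl = 100 * base_fit$params$omega_cl,
                         cv_vd = 100 * base_fit$params$omega_vd))
  step <- 0L
  repeat {
    step <- step + 1L
    fits <- vector("list", length(remaining))
    dofv <- rep(-Inf, length(remaining))
    for (k in seq_along(remaining)) {
      fk <- tryCatch(nlme_fit(data, terms = c(selected, remaining[k]),
                              control = control),
                     error = function(e) NULL)
      fits[[k]] <- fk
      if (!is.null(fk)) dofv[k] <- current$ofv - fk$ofv
      tm <- remaining[[k]]
      ledger[[length(ledger) + 1L]] <- data.frame(
        step = step, param = tm$param, cov = tm$cov, law = tm$law,
        ofv = if (is.null(fk)) NA_real_ else fk$ofv, dofv = dofv[k],
        selected = FALSE, stringsAsFactors = FALSE)
    }
    k_best <- which.max(dofv)
    if (!length(k_best) || dofv[k_best] <= threshold) break
    ledger[[length(ledger)]]$selected <- FALSE  # keep shape
    idx <- length(ledger) - length(remaining) + k_best
    ledger[[idx]]$selected <- TRUE
    selected <- c(selected, remaining[k_best])
    current <- fits[[k_best]]
    remaining <- remaining[-k_best]
    iiv[[length(iiv) + 1L]] <- data.frame(
      step = step, cv_cl = 100 * current$params$omega_cl,
      cv_vd = 100 * current$params$omega_vd)
    if (length(remaining) == 0L) break
  }
  list(fit = current, selected = selected,
       ledger = do.call(rbind, ledger), base_fit = base_fit,
       iiv_path = do.call(rbind, iiv))
}
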