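# Second stage of the individual analysis: nonparametric comparisons and
# univariate linear-regression screens of MAP parameter estimates
# against covariates.

#' Mann-Whitney U test (two-sided)
#'
#' Thin surface over `stats::wilcox.test` with the policy used here:
#' exact enumeration when both samples are tie-free and the smaller has
#' at most 8 values, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `U` (statistic for `a`) and `p` (two-sided).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Univariate least-squares regression screen
#'
#' Ordinary least squares of a PK parameter on one continuous covariate,
#' with the two-sided t-test p-value for the slope.
#'
#' @param x Covariate values (not constant; n >= 3).
#' @param y PK parameter values.
#' @param covariate Label for the covariate.
#' @return List of class `association_result`: `covariate`, `kind`,
#'   `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
ols_regression <- function(x, y, covariate = deparse(substitute(x))) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("regression needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate design: covariate is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(covariate = covariate, kind = "continuous",
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2, 4], n = length(x)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: slope %.4g, intercept %.4g, r2 = %.4f, p = %.4g (n=%d)\n",
              x$covariate, x$slope, x$intercept, x$r_squared, x$p, x$n))
  invisible(x)
}

#' Two-stage summary of individual fits
#'
#' The classical second stage: (i) between-subject CV% of the
#' body-weight-normalized parameters (and half-life) in the early phase;
#' (ii) early-vs-delayed comparison of Vd/kg, CL/kg, t1/2 and measured
#' CLcr restricted to subjects with both complete profiles — compared,
#' deliberately, with the unpaired Mann-Whitney test, mirroring common
#' practice in individual TDM analyses even for paired subjects; (iii)
#' univariate screens of CL and Vd against each continuous covariate
#' (linear regression) and each categorical covariate (Mann-Whitney).
#'
#' @param fits data.frame from [fit_individuals()].
#' @param continuous,categorical Covariate column names to screen.
#' @param alpha Significance level (default 0.05).
#' @return List of class `two_stage_summary`: `cv` (named CV% vector,
#'   early phase), `comparisons` (data.frame parameter/p/n_paired; has
#'   zero rows and `no_paired_subjects = TRUE` when no subject has both
#'   occasions), `associations` (data.frame), `n_subjects`, `n_paired`.
#' @export
two_stage_summary <- function(fits,
                              continuous = c("CLCR", "AGE", "WT", "HT",
                                             "BILI", "FLUID", "NOREPI",
                                             "FUROS"),
                              categorical = c("SEX", "SMOKE", "CVVHD"),
                              alpha = 0.05) {
  if (length(unique(fits$SUBJ)) < 2)
    stop("two-stage summary needs at least 2 subjects", call. = FALSE)
  early <- fits[fits$OCC == "early", , drop = FALSE]
  delayed <- fits[fits$OCC == "delayed", , drop = FALSE]

  norm <- function(df) data.frame(
    SUBJ = df$SUBJ,
    VD_KG = df$VD / df$WT, CL_KG = df$CL / df$WT, THALF = df$THALF,
    CLCR = if ("CLCR" %in% names(df)) df$CLCR else NA_real_)
  ne <- norm(early); nd <- norm(delayed)

  cv <- c(VD_KG = cv_pct(ne$VD_KG), CL_KG = cv_pct(ne$CL_KG),
          THALF = cv_pct(ne$THALF))

  paired_ids <- intersect(ne$SUBJ, nd$SUBJ)
  n_paired <- length(paired_ids)
  if (n_paired > 0) {
    pe <- ne[ne$SUBJ %in% paired_ids, ]
    pd <- nd[nd$SUBJ %in% paired_ids, ]
    comparisons <- do.call(rbind, lapply(
      c("VD_KG", "CL_KG", "THALF", "CLCR"), function(par) {
        if (all(is.na(pe[[par]]))) return(NULL)
        if (stats::sd(c(pe[[par]], pd[[par]])) == 0)
          return(data.frame(parameter = par, p = 1, n_paired = n_paired))
        mw <- mann_whitney(pe[[par]], pd[[par]])
        data.frame(parameter = par, p = mw$p, n_paired = n_paired)
      }))
    no_paired <- FALSE
  } else {
    comparisons <- data.frame(parameter = character(0), p = numeric(0),
                              n_paired = integer(0))
    no_paired <- TRUE
  }

  assoc <- list()
  for (par in c("CL", "VD")) {
    y <- early[[par]]
    for (cc in intersect(continuous, names(early))) {
      x <- as.numeric(early[[cc]])
      if (sum(is.finite(x) & is.finite(y)) < 3 ||
          stats::sd(x[is.finite(x)]) == 0) next
      ar <- ols_regression(x, y, covariate = cc)
      assoc[[length(assoc) + 1L]] <- data.frame(
        parameter = par, covariate = cc, kind = "continuous",
        statistic = ar$slope, r_squared = ar$r_squared, p = ar$p,
        significant = ar$p < alpha)
    }
    for (cc in intersect(categorical, names(early))) {
      gr <- early[[cc]]
      lev <- unique(stats::na.omit(gr))
      if (length(lev) != 2) next
      g1 <- y[!is.na(gr) & gr == lev[1]]
      g2 <- y[!is.na(gr) & gr == lev[2]]
      if (length(g1) == 0 || length(g2) == 0) next
      mw <- mann_whitney(g1, g2)
      assoc[[length(assoc) + 1L]] <- data.frame(
        parameter = par, covariate = cc, kind = "categorical",
        statistic = mw$U, r_squared = NA_real_, p = mw$p,
        significant = mw$p < alpha)
    }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame()

  structure(list(cv = cv, comparisons = comparisons,
                 associations = associations,
                 no_paired_subjects = no_paired,
                 n_subjects = length(unique(fits$SUBJ)),
                 n_paired = n_paired, alpha = alpha),
            class = "two_stage_summary")
}

#' @export
print.two_stage_summary <- function(x, ...) {
  cat(sprintf("Two-stage summary: %d subjects (%d with both occasions)\n",
              x$n_subjects, x$n_paired))
  cat("Early-phase CV% (weight-normalized):\n")
  print(round(x$cv, 1))
  if (nrow(x$comparisons)) {
    cat("Early vs delayed (unpaired Mann-Whitney):\n")
    print(x$comparisons, row.names = FALSE)
  } else cat("No subjects with both occasions; comparison empty.\n")
  if (nrow(x$associations)) {
    cat("Covariate screens (early phase):\n")
    print(x$associations, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
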