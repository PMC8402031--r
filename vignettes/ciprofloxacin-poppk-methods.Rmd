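---
title: "Methods: population and individual pharmacokinetics of ciprofloxacin in critically ill adults"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population and individual pharmacokinetics of ciprofloxacin in critically ill adults}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipropk)
```

## The problem

Ciprofloxacin efficacy tracks the ratio of the 24-hour area under the
concentration-time curve to the pathogen's minimum inhibitory
concentration; AUC~24~/MIC ≥ 125 is the usual efficacy target. In
intensive-care patients, renal function — and with it ciprofloxacin
clearance — is both highly variable between patients and potentially
unstable within a patient over the first days of treatment. This
package implements the full analysis chain used to study that problem:
structural PK model, individual (two-stage) analysis, population
(nonlinear mixed-effects) analysis with covariate selection,
simulation-based model validation, and the translation of the fitted
models into dosing guidance (probability of target attainment and a
renal-function/MIC nomogram). Because no patient-level data ship with
the package, a first-class synthetic-cohort module generates datasets
with the same design and statistical structure, and every downstream
method is exercised and tested on those.

## Structural model

Drug input is a zero-order infusion (rate $R_0 = \text{dose}/T_{inf}$,
$T_{inf}$ = 0.5 h by default) into a single compartment with
first-order elimination ($k_e = CL/V_d$). For one infusion starting at
time 0,

$$C(t) = \frac{R_0}{CL}\left(1 - e^{-k_e \min(t, T_{inf})}\right)
         e^{-k_e \max(t - T_{inf},\, 0)},$$

and multiple doses superpose linearly. Steady-state daily exposure is
$AUC_{24} = \text{daily dose}/CL$, independent of $V_d$. The internal
clock starts at the first infusion; nominal sampling times recorded as
"hours after end of infusion" are converted by adding the infusion
duration, so a "1 h post-infusion" sample after a dose starting at 12 h
lives at $t = 13.5$ h. A two-compartment structure is deliberately out
of scope: with no samples in the first hour after dosing, the sparse
design cannot inform a distribution phase.

## Population model

For subject $i$ with occasion-specific measured creatinine clearance
$CLcr$ (mL/s),

$$CL_{i} = \left(CL_p + \theta_{CLcr}\frac{CLcr}{1.25}\right)
           e^{\eta_{CL,i}}, \qquad
  V_{d,i} = V_{dp}\, e^{\eta_{Vd,i}},$$

with $\eta \sim N(0, \omega^2)$ independent between parameters and
subjects. $\omega$ is the SD of the log effect and is reported as
CV% $= 100\,\omega$. The residual model is combined:
$y = f(1 + \varepsilon_{prop}) + \varepsilon_{add}$ with
$\varepsilon_{prop} \sim N(0, \sigma_{prop}^2)$,
$\varepsilon_{add} \sim N(0, \sigma_{add}^2)$.

The package ships `reference_model()` as its default simulation truth:
$CL_p = 5.4$ L/h, $\theta_{CLcr} = 16.1$ L/h per scaled unit,
$V_{dp} = 143$ L, $\omega_{CL} = 44.9\%$, $\omega_{Vd} = 34.8\%$,
$\sigma_{add} = 0.981$ mg/L, $\sigma_{prop} = 4.78\%$ — so a typical
patient with $CLcr = 1.25$ mL/s has $CL = 21.5$ L/h. The scaled form
$CLcr/1.25$ makes the coefficient interpretable at the typical renal
function; the additive residual component is a concentration SD in
mg/L, not a percentage, and the proportional component is a CV
fraction.

Occasion covariates are handled with one deliberate simplification: an
observation's prediction uses its own occasion's $CLcr$-derived
clearance across the whole dose history. Elimination memory decays
within about five half-lives (roughly a day), long before the delayed
profile at 72–96 h, so the error from ignoring mid-history clearance
changes is negligible — and simulator and estimator use the same
convention, so simulation-estimation experiments are internally exact.

## Estimation

The marginal likelihood integrates the conditional density over the
two random effects per subject. `nlme_fit()` finds each subject's
conditional mode by a damped Newton method with a Gauss-Newton
Hessian (residual variance evaluated at the mode, i.e. with
η–ε interaction, as in FOCE-I) and then approximates the integral by
adaptive Gauss–Hermite quadrature centered and scaled at that mode
(`nq = 5` nodes per dimension by default; `nq = 1` gives the pure
Laplace approximation). The objective is OFV = −2 log approximate
marginal likelihood including constants; only OFV differences between
nested models on the same data are meaningful. We make no claim of
numerical identity with any specific reference software — the
approximation, not the brand, is the method — and validate by
simulation-based parameter recovery instead. In internal checks the
quadrature refinement mattered: pure Laplace on this sparse design
(three samples per occasion) biased the clearance intercept upward by
roughly 20% and inflated the proportional error; at `nq = 5` the
median recovered fixed effects sit within 10–15% of the generating
values.

The outer problem optimizes positive parameters on the log scale, but
the covariate coefficients of linear and power laws on the identity
scale. That choice is load-bearing for covariate selection: with
$\theta$ unconstrained, the no-effect null is an interior point and the
likelihood-ratio statistic for one added parameter keeps its nominal
$\chi^2_1$ behaviour; a positivity constraint would halve the type-I
error rate. Admissibility ($CL > 0$ over the data's covariate range) is
enforced by a penalty. The outer optimizer is Nelder–Mead with one
restart, run from `n_starts = 3` deterministically jittered starting
points (best final OFV wins); starting values center on the
individual-analysis cohort medians (CL 18.59 L/h, Vd 136.9 L), with
30% CV random-effect starts. Standard errors come from the
central-difference Hessian of OFV/2 at the optimum; for log-scale
parameters the SE of the log is itself the relative standard error.

Stepwise covariate modeling (`covariate_step()`) is forward selection:
every candidate (covariate × law × parameter) is fitted, the best
OFV drop is accepted while it exceeds 3.84 points (the 5% point of
$\chi^2_1$; the threshold is configurable), and every tested pair is
recorded in a ledger together with the between-subject CV% of CL and
Vd before and after each inclusion.

## Individual (two-stage) analysis

`map_fit()` estimates one patient-occasion's $(CL, V_d)$ as the
posterior mode combining the observed concentrations with a log-normal
prior:

$$J = \sum_j \left(\frac{y_j - f_j}{\sigma_j}\right)^2
    + \sum_p \left(\frac{\ln\theta_p - \ln\theta_{prior,p}}
                        {\omega_{prior,p}}\right)^2,
  \qquad \sigma_j^2 = (0.10 f_j)^2 + 0.05^2,$$

reported with the weighted sum of squares (the data term at the
optimum) and RMS $=\sqrt{WSS/n}$. The error weights (10% proportional
with a 0.05 mg/L additive floor) are a package default, configurable
per call, since TDM software rarely documents its weighting polynomial.
The prior ships as a YAML config (`inst/extdata/prior_default.yaml`)
centered on the cohort medians with 50% CV rather than hard-coding any
literature prior; users reproducing a specific TDM configuration
supply their own file. Optimization is damped Gauss–Newton in log
space from a 5×5 multi-start grid (±1.1 log units around the prior),
tie-broken by lowest objective then lowest CL; the line search accepts
only decreases, so the recorded objective trace is monotone. With zero
observations the prior mode is returned (a documented utility path);
a single observation is refused.

The second stage mirrors classical practice: between-subject CV% of
weight-normalized parameters, unpaired Mann–Whitney comparisons of the
early versus delayed occasion restricted to subjects with both
profiles (the unpaired test is kept deliberately, mirroring how such
analyses are usually run, although a paired test would be more
powerful), univariate regression screens for continuous covariates and
Mann–Whitney for categorical ones, all at α = 0.05 with no
multiple-testing adjustment — the screens are descriptive, and the
confirmatory covariate decision belongs to the population analysis.

## Synthetic cohort: what it emulates, and what not

`sample_cohort()` draws covariates from marginals calibrated to the
study population: log-normals for positive covariates with the median
as geometric mean and spread set so the reported range is roughly a
95% interval (e.g. early CLcr: median 1.16 mL/s, range 0.12–3.32); a
normal for the signed fluid balance; zero-inflated log-normals for
norepinephrine and furosemide doses; categorical sex (21:8 M:F),
smoking and CVVHD. The delayed-occasion CLcr is redrawn with a
narrower spread (median 1.36, range 0.66–2.49), reproducing the higher
early-phase spread of renal function. The early profile follows dose
2 (within 36 h for both intervals); the delayed profile follows the
dose nearest 84 h. Regimens mix 400 mg q12h, 400 mg q8h and 600 mg
q12h in equal thirds under the random-mix policy, since the clinical
mix was at prescriber discretion and unreported.

Limitations to keep in mind when interpreting passing tests: covariate
marginals are independent by default (an optional log-scale
age–CLcr correlation is supported but uncalibrated, as no joint
distribution is reported); serum creatinine is drawn independently of
the measured CLcr, so the renal-estimation formulas are exercised
structurally, not jointly calibrated; there is no assay
quantification limit, dropout, or sampling-time deviation. Simulated
concentrations are deliberately **not** truncated at zero: with an
additive residual SD near 1 mg/L, troughs sit within one SD of zero,
and censoring or re-drawing would put a sizable probability mass at
the boundary that the Gaussian estimation model does not describe,
visibly biasing the residual-error partition and, through it, the
fixed effects. Real assays would report such samples as small
positive values or below-quantification; modeling that would require
a censored likelihood, which is out of scope. Consequently the tests
demonstrate correctness of the estimation machinery under its own
assumptions, not robustness to assay censoring.

Inter-occasion variability is supported in the simulator (`iov_cl`,
`iov_vd`) but defaults to zero, matching the finding that occasion
effects were not significant; the knob exists for power studies of
that negative result.

## Diagnostics

The bootstrap resamples subjects with replacement and refits
(non-converged replicates are counted and excluded; >20% failures is
flagged). The VPC simulates the dataset at its own design (1000
replicates by default), bins observations by nominal sample offset —
1 h, 4 h, trough — because the design is sparse and nominal, and
compares observed 10th/50th/90th percentiles with the 95% bands of
the simulated percentiles; bins under 5 observations merge into a
neighbor. NPDE simulates each subject's observation vector (K = 1000
by default), decorrelates observed and simulated vectors with the
simulated mean and covariance Cholesky factor, maps ranks through
$\Phi^{-1}$ (kept off 0/1 by a half-count), and tests mean 0 (t-test)
and variance 1 (two-sided $\chi^2$). Simulation streams are keyed to
sorted subject identifiers, so NPDE values do not depend on row order;
singular simulated covariances receive a logged ridge.

## Dosing decision

`pta_curve()` draws only clearance variability, because at steady
state $AUC_{24} = \text{dose}/CL$ is free of $V_d$; volume affects the
shape of the profile, not the daily exposure, so including
$\omega_{Vd}$ would change nothing but the Monte Carlo noise.
`pta_closed_form()` is the analytic counterpart
($PTA = \Phi[\ln(\text{dose}/(125\,\text{MIC}\,CL_{typ}))/\omega_{CL}]$),
exact under the generative model, and serves as the oracle in tests.
The printed success criterion in the source literature for this kind
of analysis ("PTA > 100%") is not satisfiable as written; the package
treats success as PTA ≥ a configurable threshold, default 100% (the
strictest reading), with 90% as the conventional alternative. The
nomogram converts the individual-analysis regression
$CL = 18.54\,CLcr + 3.261$ and $AUC = \text{dose}/CL$ into the
attainability boundary $MIC_{max}(CLcr) = \text{dose}/(125\,(a\,CLcr + b))$
with inverse $CLcr_{max}(MIC)$; a negative inverse is reported as
"unattainable at any renal function". MIC grids default to the
doubling dilutions 0.0625–1 mg/L.

## Numerical choices and problem sizes

Inner Newton: at most 60 damped steps, gradient tolerance $10^{-8}$,
steps capped at 2 log units, effects clamped to ±10; warm starts carry
conditional modes across outer iterations. Outer Nelder-Mead: relative
tolerance $10^{-9}$, 1200 iterations, one restart. Quadrature weights
below machine range are handled in log space (log-sum-exp). Ties in
the MAP multi-start are broken toward lower clearance for
reproducibility. Degenerate inputs error early and explicitly: empty
regimens, non-positive parameters, constant covariates in regression,
single observations in MAP fitting.

The shipped tests and the acceptance script size their simulations to
what the statistical check needs: 20 simulate-refit replicates of the
30-subject × 2-occasion design for recovery and power (medians over
replicates are the estimand, so replicate count enters at rate
$\sqrt{n}$ and 20 is ample for 20% tolerances), 100 replicates for the
null selection-rate check (binomial SE ≈ 2.2 percentage points at a 5%
rate), $10^5$ Monte Carlo patients per PTA cell against a 0.5
percentage-point oracle tolerance, and K = 200–300 simulation
replicates for the diagnostics' self-consistency checks.

## Known limitations

- The estimator is an approximate-likelihood method; variance
  components on the boundary (ω → 0) are reported as 0 without a
  boundary-corrected test.
- No covariance between $\eta_{CL}$ and $\eta_{Vd}$ (none is reported
  for this model family), no censored-data likelihood, no
  two-compartment option.
- The proportional residual component is weakly identified by the
  three-point design when the additive component dominates; its
  estimate is noisy (this is visible in simulation and does not affect
  the covariate conclusions).
- `egfr()` returns BSA-indexed estimates (CKD-EPI, MDRD, Lund-Malmö)
  per 1.73 m² as published, without de-indexing; Cockcroft-Gault is
  absolute. Mixing the two conventions in one regression is the
  caller's responsibility.
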