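# Small internal helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Central-difference Hessian of a scalar function; used for the
# observed-information standard errors of the population fit.
num_hessian <- function(fn, p, h = NULL) {
  n <- length(p)
  if (is.null(h)) h <- 1e-4 * (1 + abs(p))
  H <- matrix(NA_real_, n, n)
  f0 <- fn(p)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    fpp <- fn(p + ei); fmm <- fn(p - ei)
    H[i, i] <- (fpp - 2 * f0 + fmm) / h[i]^2
    if (i < n) for (j in seq((i + 1), n)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(p + ei + ej) - fn(p + ei - ej) -
         fn(p - ei + ej) + fn(p - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

# Coefficient of variation in percent.
cv_pct <- function(x) 100 * stats::sd(x) / mean(x)
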