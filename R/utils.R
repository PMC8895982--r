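# Internal numerical helpers shared across the samplers.

# Vectorised truncated-normal draw by inverse-CDF; bounds may be -Inf/Inf.
# Probabilities are clamped away from 0/1 so qnorm never returns +-Inf even
# when the truncation interval sits far in a tail.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qnorm(u, mean, sd)
}

# Scaled-inverse-chi-square draw: df0*scale0 acts as prior sum of squares.
rscinvchisq <- function(df, ss) {
  ss / rchisq(1L, df)
}

# Effective sample size from the initial positive sequence of autocorrelations.
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_arg(name, " must be TRUE or FALSE")
  x
}
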