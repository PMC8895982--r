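# Shared fixtures (built in code, once per test run) and independent
# oracles used across the test files.

# Small population reused by several files: genotypes + G / GxG kernels.
make_population <- function(n_lines = 40, n_markers = 300, seed = 101, ...) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers, seed = seed, ...)
  geno <- filter_and_impute(simulate_magic_genotypes(cfg))
  G <- eigendecompose(vanraden_g(geno))
  list(cfg = cfg, geno = geno,
       kernels = list(G = G, GxG = eigendecompose(epistatic_kernel(G))))
}

POP <- make_population()

# Direct mixed-model-equations solve: the independent oracle for the
# Gibbs samplers' Gaussian limit. Solves the ridge system in the
# eigen-loading parametrization u = B delta, delta ~ N(0, s2 I), which is
# the exact posterior mean for fixed variance components and a flat prior
# on the fixed effects.
mme_effects <- function(y, line, repl = NULL, G = NULL, GxG = NULL,
                        include_L = TRUE, s2_L = NULL, s2_g = NULL,
                        s2_gA = NULL, s2_e = 1) {
  lines <- unique(line)
  n <- length(lines)
  li <- match(line, lines)
  X <- if (is.null(repl)) matrix(1, length(y), 1) else
    model.matrix(~ 0 + factor(repl))
  blocks <- list()
  ridge <- rep(0, ncol(X))
  W <- X
  if (include_L) {
    ZL <- diag(n)[li, , drop = FALSE]
    W <- cbind(W, ZL)
    ridge <- c(ridge, rep(s2_e / s2_L, n))
    blocks$L <- ncol(X) + seq_len(n)
  }
  loading <- function(K) {
    e <- eigen(K$matrix, symmetric = TRUE)
    pos <- e$values > 1e-10
    e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  }
  if (!is.null(G)) {
    B <- loading(G)
    W <- cbind(W, B[li, , drop = FALSE])
    blocks$g <- ncol(W) - ncol(B) + seq_len(ncol(B))
    ridge <- c(ridge, rep(s2_e / s2_g, ncol(B)))
    blocks$g_B <- B
  }
  if (!is.null(GxG)) {
    B2 <- loading(GxG)
    W <- cbind(W, B2[li, , drop = FALSE])
    blocks$gA <- ncol(W) - ncol(B2) + seq_len(ncol(B2))
    ridge <- c(ridge, rep(s2_e / s2_gA, ncol(B2)))
    blocks$gA_B <- B2
  }
  sol <- solve(crossprod(W) + diag(ridge), crossprod(W, y))
  out <- list(beta = sol[seq_len(ncol(X))])
  if (include_L) out$L <- as.numeric(sol[blocks$L])
  if (!is.null(G)) out$g <- as.numeric(blocks$g_B %*% sol[blocks$g])
  if (!is.null(GxG)) out$gA <- as.numeric(blocks$gA_B %*% sol[blocks$gA])
  out
}

# Settings small enough for module-level tests.
quick_settings <- function(seed = 1, n_iter = 2000, burn_in = 500, thin = 2)
  mcmc_settings(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed)

variance_fraction <- function(fit, component) {
  v <- setNames(fit$variances$mean, fit$variances$component)
  unname(v[component] / sum(v))
}
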