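test_that("every generator is deterministic given config and seed", {
  cfg <- sim_config(n_lines = 15, n_markers = 80, n_replicates = 3, seed = 7)
  g1 <- simulate_magic_genotypes(cfg)
  g2 <- simulate_magic_genotypes(cfg)
  expect_identical(g1, g2)
  kern <- local({
    G <- eigendecompose(vanraden_g(filter_and_impute(g1)))
    list(G = G, GxG = eigendecompose(epistatic_kernel(G)))
  })
  geno <- filter_and_impute(g1)
  expect_identical(simulate_ordinal_trait(geno, kern, cfg),
                   simulate_ordinal_trait(geno, kern, cfg))
  expect_identical(simulate_count_trait(geno, kern, cfg),
                   simulate_count_trait(geno, kern, cfg))
  expect_identical(simulate_censored_trait(geno, kern, cfg, obs_sd = 0.2),
                   simulate_censored_trait(geno, kern, cfg, obs_sd = 0.2))
  expect_identical(simulate_tr_vpd_curves(n_lines = 10, seed = 3),
                   simulate_tr_vpd_curves(n_lines = 10, seed = 3))
})

test_that("genotypes are inbred mosaics with the expected allele frequencies", {
  cfg <- sim_config(n_lines = 20, n_markers = 100, seed = 2)
  geno <- simulate_magic_genotypes(cfg)
  expect_true(all(geno %in% c(0, 2)))

  # a single founder leaves every marker monomorphic
  mono <- simulate_magic_genotypes(sim_config(n_lines = 10, n_markers = 50,
                                              n_founders = 1, seed = 5))
  expect_true(all(apply(mono, 2, function(x) length(unique(x)) == 1)))

  # line allele frequencies track the founder-panel mixture frequency
  big <- sim_config(n_lines = 500, n_markers = 400, seed = 13,
                    maf_range = c(0.1, 0.5))
  geno_big <- simulate_magic_genotypes(big)
  q <- colMeans(attr(geno_big, "founder_alleles"))  # founder mixture freq
  obs <- colMeans(unclass(geno_big)) / 2
  se <- sqrt(pmax(q * (1 - q), 1e-12) / 500)
  inside <- abs(obs - q) < 3 * se | se == 0
  expect_gt(mean(inside), 0.97)

  expect_error(sim_config(n_lines = 0), "positive")
})

test_that("ordinal liabilities map to categories through the thresholds", {
  # two categories split at 0 with no signal: Phi(0) = 1/2
  cfg <- sim_config(n_lines = 400, n_markers = 60, n_replicates = 4, seed = 21,
                    thresholds = 0, category_labels = 1:2, fixed_effects = 0,
                    variance_components = list(sigma2_L = 0, sigma2_g = 0,
                                               sigma2_gA = 0, sigma2_e = 1))
  pop <- make_population(400, 60, seed = 21)
  sim <- simulate_ordinal_trait(pop$geno, pop$kernels, cfg)
  n_obs <- nrow(sim$data)
  p1 <- mean(sim$data$category == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / n_obs))

  # no line-level variance: replicate liabilities are iid across replicates
  icc <- local({
    liab <- matrix(sim$truth$liabilities, nrow = 400)
    m <- rowMeans(liab)
    vb <- var(m) - var(as.vector(liab)) / ncol(liab)
    vb / var(as.vector(liab))
  })
  expect_lt(abs(icc), 0.05)

  # 7 categories with known thresholds: frequencies match Phi differences
  gam <- c(-1.5, -0.8, -0.25, 0.25, 0.8, 1.5)
  cfg7 <- sim_config(n_lines = 400, n_markers = 60, n_replicates = 3,
                     seed = 22, thresholds = gam, category_labels = 2:8,
                     fixed_effects = 0,
                     variance_components = list(sigma2_L = 0, sigma2_g = 0,
                                                sigma2_gA = 0, sigma2_e = 1))
  sim7 <- simulate_ordinal_trait(pop$geno, pop$kernels, cfg7)
  expect_true(all(sim7$data$category %in% 2:8))
  p_true <- diff(c(0, pnorm(gam), 1))
  n7 <- nrow(sim7$data)
  p_obs <- as.numeric(table(factor(sim7$data$category, levels = 2:8))) / n7
  se <- sqrt(p_true * (1 - p_true) / n7)
  expect_true(all(abs(p_obs - p_true) < 3.5 * se))

  expect_error(simulate_ordinal_trait(pop$geno, pop$kernels,
    sim_config(n_lines = 400, n_markers = 60, thresholds = c(1, 1))),
    "increasing")
})

test_that("count generator inverts the log(y+1) link exactly", {
  cfg <- sim_config(n_lines = 12, n_markers = 60, n_replicates = 2, seed = 31,
                    fixed_effects = log(6),
                    variance_components = list(sigma2_L = 0, sigma2_g = 0,
                                               sigma2_gA = 0, sigma2_e = 0))
  pop <- make_population(12, 60, seed = 31)
  sim <- simulate_count_trait(pop$geno, pop$kernels, cfg)
  expect_true(all(sim$data$count == 5))

  cfg0 <- sim_config(n_lines = 12, n_markers = 60, n_replicates = 2, seed = 32,
                     fixed_effects = log(1),
                     variance_components = list(sigma2_L = 0, sigma2_g = 0,
                                                sigma2_gA = 0, sigma2_e = 0))
  sim0 <- simulate_count_trait(pop$geno, pop$kernels, cfg0)
  expect_true(all(sim0$data$count == 0))
})

test_that("count trait carries the specified genetic variance fraction", {
  pop <- make_population(400, 300, seed = 41)
  s2g <- 0.25
  cfg <- sim_config(n_lines = 400, n_markers = 300, n_replicates = 8,
                    seed = 41, fixed_effects = 3,
                    variance_components = list(sigma2_L = 0, sigma2_g = s2g,
                                               sigma2_gA = 0, sigma2_e = 0.25))
  sim <- simulate_count_trait(pop$geno, pop$kernels, cfg)
  z <- log(sim$data$count + 1)
  zm <- tapply(z, sim$data$line, mean)
  within <- mean(tapply(z, sim$data$line, var))
  between <- var(zm) - within / 8
  # genetic variance on the G scale: sigma2_g * mean(diag(G))
  target <- s2g * mean(diag(pop$kernels$G$matrix))
  expect_lt(abs(between - target) / target, 0.2)
})

test_that("censoring intervals bracket the trait with the requested width", {
  pop <- make_population(30, 100, seed = 51)
  sim0 <- simulate_censored_trait(pop$geno, pop$kernels, pop$cfg, obs_sd = 0)
  expect_equal(sim0$data$a, sim0$data$y)
  expect_equal(sim0$data$b, sim0$data$y)
  sim <- simulate_censored_trait(pop$geno, pop$kernels, pop$cfg, obs_sd = 0.3)
  expect_true(all(sim$data$a < sim$data$b))
  expect_equal(sim$data$b - sim$data$a, rep(4 * 0.3, 30))
  expect_error(simulate_censored_trait(pop$geno, pop$kernels, pop$cfg,
                                       obs_sd = -1), "obs_sd")

  # law of total variance at n = 1000
  pop_big <- make_population(1000, 200, seed = 52)
  vc <- list(sigma2_L = 0.3, sigma2_g = 0.5, sigma2_gA = 0.2, sigma2_e = 0.4)
  cfg <- sim_config(n_lines = 1000, n_markers = 200, seed = 52,
                    variance_components = vc)
  simv <- simulate_censored_trait(pop_big$geno, pop_big$kernels, cfg)
  expected <- vc$sigma2_L +
    vc$sigma2_g * mean(diag(pop_big$kernels$G$matrix)) +
    vc$sigma2_gA * mean(diag(pop_big$kernels$GxG$matrix)) + vc$sigma2_e
  expect_lt(abs(var(simv$data$y) - expected) / expected, 0.15)
})

test_that("TR curves are linear or continuous two-segment responses", {
  lin <- simulate_tr_vpd_curves(n_lines = 5, fraction_linear = 1,
                                noise_sd = 0, seed = 61)
  for (id in unique(lin$curves$line)) {
    cv <- lin$curves[lin$curves$line == id, ]
    f <- fit_tr_linear(cv)
    expect_equal(f$slope1, lin$truth$slope1[lin$truth$line == id],
                 tolerance = 1e-10)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
  }
  seg <- simulate_tr_vpd_curves(n_lines = 5, fraction_linear = 0,
                                breakpoint_range = c(2.4, 2.4),
                                noise_sd = 0, seed = 62)
  tr_at_bp <- function(cv, tru, eps) {
    tru$intercept + tru$slope1 * pmin(2.4 + eps, 2.4) +
      tru$slope2 * pmax(0, 2.4 + eps - 2.4)
  }
  tru <- seg$truth[1, ]
  expect_equal(tr_at_bp(NULL, tru, -1e-9), tr_at_bp(NULL, tru, 1e-9),
               tolerance = 1e-6)
  expect_error(simulate_tr_vpd_curves(breakpoint_range = c(0.1, 0.3)),
               "inside")
})
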