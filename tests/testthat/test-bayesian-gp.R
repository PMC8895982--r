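test_that("a constant response collapses to the constant", {
  y <- setNames(rep(3.2, nrow(POP$geno)), rownames(POP$geno))
  fit <- suppressWarnings(fit_gaussian(y, model_spec(2), POP$kernels,
                                       quick_settings(1)))
  expect_lt(max(abs(fit$fitted - 3.2)), 0.05)
  v <- setNames(fit$variances$mean, fit$variances$component)
  expect_lt(v["sigma2_e"], 1e-4)
})

test_that("log-normal counts are the Gaussian fit of log(y+1), draw for draw", {
  cfg <- sim_config(n_lines = 40, n_markers = 300, n_replicates = 3,
                    seed = 101, fixed_effects = 1.6,
                    variance_components = list(sigma2_L = 0, sigma2_g = 0.2,
                                               sigma2_gA = 0, sigma2_e = 0.2))
  sim <- simulate_count_trait(POP$geno, POP$kernels, cfg)
  st <- quick_settings(5)
  f1 <- suppressWarnings(fit_lognormal_count(sim$data, model_spec(2),
                                             POP$kernels, st))
  gobs <- data.frame(line = sim$data$line, replicate = sim$data$replicate,
                     value = log(sim$data$count + 1))
  f2 <- suppressWarnings(fit_gaussian(gobs, model_spec(2), POP$kernels, st))
  expect_identical(f1$draws$variances, f2$draws$variances)
  expect_identical(f1$effects$g$mean, f2$effects$g$mean)
  expect_equal(f1$fitted_count, exp(f2$fitted) - 1)

  allfive <- data.frame(line = rownames(POP$geno), replicate = 1, count = 5)
  f5 <- suppressWarnings(fit_lognormal_count(allfive, model_spec(2),
                                             POP$kernels, quick_settings(2)))
  expect_lt(max(abs(f5$fitted_count - 5)), 0.05)
  bad <- allfive; bad$count[1] <- -2
  expect_error(fit_lognormal_count(bad, model_spec(2), POP$kernels),
               "non-negative")
})

test_that("degenerate censoring intervals reproduce the Gaussian fit exactly", {
  cfg <- sim_config(n_lines = 40, n_markers = 300, seed = 102,
                    variance_components = list(sigma2_L = 0, sigma2_g = 0.6,
                                               sigma2_gA = 0, sigma2_e = 0.4))
  sim <- simulate_censored_trait(POP$geno, POP$kernels, cfg, obs_sd = 0)
  st <- quick_settings(6)
  fc <- suppressWarnings(fit_censored(sim$data, model_spec(2), POP$kernels, st))
  fg <- suppressWarnings(fit_gaussian(setNames(sim$data$y, sim$data$line),
                                      model_spec(2), POP$kernels, st))
  expect_identical(fc$draws$variances, fg$draws$variances)
  expect_equal(fc$effects$g$mean, fg$effects$g$mean)
})

test_that("an uninformative interval reverts to its linear predictor", {
  cfg <- sim_config(n_lines = 40, n_markers = 300, seed = 103,
                    variance_components = list(sigma2_L = 0, sigma2_g = 1,
                                               sigma2_gA = 0, sigma2_e = 0.2))
  sim <- simulate_censored_trait(POP$geno, POP$kernels, cfg, obs_sd = 0)
  d <- sim$data
  d$y[1] <- NA; d$a[1] <- -1e6; d$b[1] <- 1e6
  fit <- suppressWarnings(fit_censored(d, model_spec(2), POP$kernels,
                                       quick_settings(7, n_iter = 4000,
                                                      burn_in = 1000)))
  eta1 <- magicGP:::fitted_eta_for_line(fit, d$line[1])
  expect_lt(abs(fit$latent_mean[1] - eta1), 0.25)
  bad <- sim$data; bad$a[2] <- bad$b[2] + 1
  expect_error(fit_censored(bad, model_spec(2), POP$kernels), "a <= b")
})

test_that("ordinal probabilities normalize and thresholds stay ordered", {
  cfg <- sim_config(n_lines = 40, n_markers = 300, n_replicates = 4,
                    seed = 104, thresholds = c(-1, 0, 1),
                    category_labels = 1:4,
                    variance_components = list(sigma2_L = 0.2, sigma2_g = 0.5,
                                               sigma2_gA = 0, sigma2_e = 1))
  sim <- simulate_ordinal_trait(POP$geno, POP$kernels, cfg)
  fit <- suppressWarnings(fit_ordinal_threshold(sim$data, model_spec(5),
                                                POP$kernels,
                                                quick_settings(8)))
  expect_lt(max(abs(rowSums(fit$probs) - 1)), 1e-8)
  expect_true(all(apply(fit$draws$gamma, 1, function(g) all(diff(g) > 0))))
  expect_true(all(fit$variances$mean >= 0))
  expect_true(all(fit$variances$ci_low <= fit$variances$mean &
                    fit$variances$mean <= fit$variances$ci_high))

  one_cat <- data.frame(line = rownames(POP$geno), replicate = 1, category = 4)
  expect_error(fit_ordinal_threshold(one_cat, model_spec(2), POP$kernels),
               "degenerate ordinal")

  gap <- sim$data
  gap$category[gap$category == 2] <- 1   # empty an intermediate category
  if (!any(gap$category == 2)) {
    w <- capture_warnings(fit_ordinal_threshold(gap, model_spec(2),
                                                POP$kernels,
                                                quick_settings(9, n_iter = 600,
                                                               burn_in = 100)))
    expect_true(any(grepl("weakly identified", w)))
  }
})

test_that("chains are reproducible given a seed", {
  cfg <- sim_config(n_lines = 25, n_markers = 150, seed = 105,
                    variance_components = list(sigma2_L = 0.2, sigma2_g = 0.5,
                                               sigma2_gA = 0, sigma2_e = 0.5))
  pop <- make_population(25, 150, seed = 105)
  sim <- simulate_censored_trait(pop$geno, pop$kernels, cfg, obs_sd = 0.1)
  st <- quick_settings(11, n_iter = 800, burn_in = 200)
  f1 <- suppressWarnings(fit_censored(sim$data, model_spec(4), pop$kernels, st))
  f2 <- suppressWarnings(fit_censored(sim$data, model_spec(4), pop$kernels, st))
  expect_identical(f1$variances, f2$variances)
  expect_identical(f1$effects, f2$effects)
})

test_that("adding predictors does not inflate the residual variance", {
  cfg <- sim_config(n_lines = 60, n_markers = 300, seed = 106,
                    variance_components = list(sigma2_L = 0.3, sigma2_g = 0.7,
                                               sigma2_gA = 0.3, sigma2_e = 0.5))
  pop <- make_population(60, 300, seed = 106)
  sim <- simulate_censored_trait(pop$geno, pop$kernels, cfg, obs_sd = 0)
  y <- setNames(sim$data$y, sim$data$line)
  st <- quick_settings(12, n_iter = 4000, burn_in = 1000)
  res <- sapply(c(2, 5), function(m) {
    f <- suppressWarnings(fit_gaussian(y, model_spec(m), pop$kernels, st))
    v <- f$draws$variances[, "sigma2_e"]
    c(mean(v), sd(v) / sqrt(magicGP:::ess(v)))
  })
  expect_lte(res[1, 2], res[1, 1] + 3 * (res[2, 1] + res[2, 2]))
})

test_that("kernel prediction generalizes to held-out lines", {
  cfg <- sim_config(n_lines = 200, n_markers = 400, seed = 107,
                    variance_components = list(sigma2_L = 0, sigma2_g = 0.8,
                                               sigma2_gA = 0, sigma2_e = 0.2))
  pop <- make_population(200, 400, seed = 107)
  sim <- simulate_censored_trait(pop$geno, pop$kernels, cfg, obs_sd = 0)
  train <- rownames(pop$geno)[1:150]
  test <- setdiff(rownames(pop$geno), train)
  y <- setNames(sim$data$y, sim$data$line)[train]
  fit <- suppressWarnings(fit_gaussian(y, model_spec(2), pop$kernels,
                                       quick_settings(13, n_iter = 3000,
                                                      burn_in = 600)))
  pred <- predict_new_lines(fit, list(g = pop$kernels$G$matrix[test, train]))
  truth_g <- sim$truth$g[match(test, rownames(pop$geno))]
  expect_gt(cor(pred$pred, truth_g), 0.5)

  # a duplicated kernel row gives an identical genomic prediction
  dup <- predict_new_lines(fit,
    list(g = pop$kernels$G$matrix[c(train[1], train[1]), train]))
  expect_equal(dup$pred[1], dup$pred[2])

  # identity cross-rows reproduce fitted values for training lines
  idrows <- predict_new_lines(fit, list(g = pop$kernels$G$matrix[train, train]))
  eta_fit <- vapply(train, function(l) magicGP:::fitted_eta_for_line(fit, l),
                    numeric(1))
  expect_lt(max(abs(idrows$pred - eta_fit)), 1e-8)
})
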