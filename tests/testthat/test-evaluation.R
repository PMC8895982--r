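test_that("Brier score hits its closed-form values", {
  onehot <- function(idx, C) {
    m <- matrix(0, length(idx), C, dimnames = list(NULL, seq_len(C)))
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  obs <- c(1, 3, 2, 2)
  expect_equal(brier_score(onehot(obs, 3), obs), 0)
  wrong <- onehot(c(2, 1, 3, 3), 3)
  expect_equal(brier_score(wrong, obs), 1)
  unif7 <- matrix(1 / 7, 5, 7, dimnames = list(NULL, 2:8))
  expect_equal(brier_score(unif7, c(2, 4, 5, 8, 6)), 3 / 7, tolerance = 1e-12)

  badrow <- unif7; badrow[1, 1] <- 0.5
  expect_error(brier_score(badrow, c(2, 4, 5, 8, 6)), "sum to 1")
  expect_error(brier_score(unif7, c(1, 4, 5, 8, 6)), "outside")
})

test_that("PCCC counts modal hits with the lower-label tie-break", {
  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.2, 0.3, 0.5),
             c(0.6, 0.3, 0.1))
  colnames(p) <- 4:6
  expect_equal(pccc(p, c(4, 5, 6, 4)), 1)
  expect_equal(pccc(p, c(5, 4, 6, 4)), 0.5)

  tie <- matrix(c(0.1, 0.45, 0.45), 1, dimnames = list(NULL, 3:5))
  expect_equal(pccc(tie, 5), 0)    # tie 4 vs 5 resolves to 4
  expect_equal(pccc(tie, 4), 1)
})

test_that("predictive ability is the Pearson correlation", {
  x <- c(1.2, 3.1, 0.4, 5.5, 2.2)
  expect_equal(predictive_ability_r(x, x), 1)
  expect_equal(predictive_ability_r(x, -x), -1)
  y <- c(2.0, 2.9, 1.1, 4.8, 2.4)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(predictive_ability_r(x, y), r_direct, tolerance = 1e-12)
  expect_error(predictive_ability_r(rep(1, 5), y), "undefined correlation")
  expect_error(predictive_ability_r(x, y[1:3]), "equal-length")
})

test_that("variance table reports percentages of the summed total", {
  fake <- structure(list(variances = data.frame(
    component = c("sigma2_g", "sigma2_e"), mean = c(1, 1))), class = "gp_fit")
  vt <- variance_component_table(list(m = fake))
  expect_equal(vt$percent, c(50, 50))
  expect_equal(sum(vt$percent), 100, tolerance = 1e-9)

  cfg <- sim_config(n_lines = 40, n_markers = 300, n_replicates = 3,
                    seed = 111, thresholds = c(-0.8, 0.8),
                    category_labels = 1:3)
  sim <- simulate_ordinal_trait(POP$geno, POP$kernels, cfg)
  fit <- suppressWarnings(fit_ordinal_threshold(sim$data, model_spec(2),
                                                POP$kernels,
                                                quick_settings(14,
                                                               n_iter = 800,
                                                               burn_in = 200)))
  vt2 <- variance_component_table(list(model2 = fit))
  expect_equal(vt2$estimate[vt2$component == "sigma2_e"], 1)  # probit residual
  expect_equal(sum(vt2$percent), 100, tolerance = 1e-9)
})

test_that("LOO produces one fold per unit and sensible aggregates", {
  cfg <- sim_config(n_lines = 20, n_markers = 150, seed = 112,
                    variance_components = list(sigma2_L = 0, sigma2_g = 0.8,
                                               sigma2_gA = 0, sigma2_e = 0.2))
  pop <- make_population(20, 150, seed = 112)
  sim <- simulate_censored_trait(pop$geno, pop$kernels, cfg, obs_sd = 0)
  st <- quick_settings(15, n_iter = 600, burn_in = 150)
  cv <- loo_cross_validate(sim$data, model_spec(2), "censored", pop$kernels,
                           st, unit = "line")
  expect_equal(cv$n_folds, 20)
  expect_setequal(cv$per_fold$line, rownames(pop$geno))
  expect_true(abs(cv$predictive_ability) <= 1)

  expect_error(loo_cross_validate(sim$data[1:2, ], model_spec(2), "censored",
                                  pop$kernels, st, unit = "line"),
               "at least 3")
  expect_error(loo_cross_validate(sim$data, model_spec(2), "gaussian",
                                  pop$kernels, st, retain_bounds = TRUE),
               "censored family")
})

test_that("no genetic signal means no predictive ability", {
  cfg <- sim_config(n_lines = 60, n_markers = 200, seed = 113,
                    variance_components = list(sigma2_L = 0, sigma2_g = 0,
                                               sigma2_gA = 0, sigma2_e = 1))
  pop <- make_population(60, 200, seed = 113)
  sim <- simulate_censored_trait(pop$geno, pop$kernels, cfg, obs_sd = 0)
  st <- quick_settings(16, n_iter = 500, burn_in = 100)
  cv <- suppressWarnings(
    loo_cross_validate(setNames(sim$data$y, sim$data$line), model_spec(2),
                       "gaussian", pop$kernels, st, unit = "line"))
  expect_lt(abs(cv$predictive_ability), 2 / sqrt(60))
})

test_that("higher heritability yields higher predictive ability", {
  pop <- make_population(50, 200, seed = 114)
  st <- quick_settings(17, n_iter = 500, burn_in = 100)
  r_of <- function(h2, seed) {
    cfg <- sim_config(n_lines = 50, n_markers = 200, seed = seed,
                      variance_components = list(sigma2_L = 0, sigma2_g = h2,
                                                 sigma2_gA = 0,
                                                 sigma2_e = 1 - h2))
    sim <- simulate_censored_trait(pop$geno, pop$kernels, cfg, obs_sd = 0)
    suppressWarnings(
      loo_cross_validate(setNames(sim$data$y, sim$data$line), model_spec(2),
                         "gaussian", pop$kernels, st,
                         unit = "line"))$predictive_ability
  }
  expect_gt(r_of(0.8, 301), r_of(0.2, 301))
})

test_that("observation-level LOO of an ordinal trait scores each record once", {
  cfg <- sim_config(n_lines = 15, n_markers = 150, n_replicates = 3,
                    seed = 115, thresholds = c(-0.8, 0.8),
                    category_labels = 1:3,
                    variance_components = list(sigma2_L = 0.4, sigma2_g = 0.4,
                                               sigma2_gA = 0, sigma2_e = 1))
  pop <- make_population(15, 150, seed = 115)
  sim <- simulate_ordinal_trait(pop$geno, pop$kernels, cfg)
  st <- quick_settings(18, n_iter = 400, burn_in = 100)
  cv <- suppressWarnings(
    loo_cross_validate(sim$data, model_spec(4), "ordinal", pop$kernels, st))
  expect_identical(cv$unit, "observation")
  expect_equal(cv$n_folds, nrow(sim$data))
  expect_true(cv$brier >= 0 && cv$brier <= 1)
  expect_true(cv$pccc >= 0 && cv$pccc <= 1)
  expect_lt(max(abs(rowSums(cv$probs) - 1)), 1e-8)
})
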