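# The Gibbs-sampler core shared by the four response families.
#
# All models share the linear predictor
#   eta_ik = beta_{r(ik)} + L_i + g_i + gA_i
# with L ~ N(0, I s2_L), g ~ N(0, G s2_g), gA ~ N(0, GxG s2_gA). Kernel
# effects are sampled in the eigenbasis of their kernel (u = B d with
# B = V sqrt(Lambda), d ~ N(0, s2 I)), which makes the full conditional of
# d diagonal whenever the design is balanced across lines; unbalanced
# designs fall back to a dense Cholesky solve on the (small) q x q system.
# Variance components have scaled-inverse-chi-square full conditionals.
#
# Families differ only in their working response:
#   gaussian   y_work = y, fixed
#   censored   interval records re-sample a latent y each iteration from
#              N(eta, s2_e) truncated to (a, b)
#   ordinal    liabilities from truncated normals given the category's
#              threshold interval (residual variance fixed at 1);
#              thresholds from their uniform full conditionals
#   lognormal  log(count + 1) then the gaussian path

build_terms <- function(spec, kernels, lines) {
  terms <- list()
  if (spec$line)
    terms$L <- list(type = "iid", B = NULL, q = length(lines))
  if (spec$markers) {
    if (is.null(kernels$G)) stop_arg("spec includes markers but no G kernel given")
    B <- kernel_loadings(kernel_subset(kernels$G, lines))
    terms$g <- list(type = "kernel", B = B, q = ncol(B))
  }
  if (spec$epistasis) {
    if (is.null(kernels$GxG))
      stop_arg("spec includes epistasis but no GxG kernel given")
    B <- kernel_loadings(kernel_subset(kernels$GxG, lines))
    terms$gA <- list(type = "kernel", B = B, q = ncol(B))
  }
  terms
}

var_name <- function(term) paste0("sigma2_", term)

# Core sampler. y_work-handling arguments:
#   bounds: list(lower, upper, free) for censored (free = records with a<b)
#   ordinal: list(cat = 1..C integer per obs, C, labels)
gp_gibbs <- function(y_init, line, repl, spec, kernels, settings,
                     family = c("gaussian", "censored", "ordinal"),
                     bounds = NULL, ordinal = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(spec, "predictor_spec"), inherits(settings, "mcmc_settings"))
  if (!is.null(settings$seed)) set.seed(settings$seed)

  lines <- unique(line)
  n_lines <- length(lines)
  line_idx <- match(line, lines)
  n_obs <- length(y_init)
  n_per_line <- tabulate(line_idx, n_lines)

  repl <- if (spec$replicate && !is.null(repl)) factor(repl) else
    factor(rep(1L, n_obs))
  fix_levels <- levels(repl)
  fix_idx <- as.integer(repl)
  p <- length(fix_levels)
  n_per_cell <- tabulate(fix_idx, p)
  if (any(n_per_cell == 0L)) stop_arg("empty replicate cell")

  terms <- build_terms(spec, kernels, lines)
  term_names <- names(terms)

  # per-term precomputation: M = B' diag(n_i) B (iid: diag(n_i))
  for (t in term_names) {
    tm <- terms[[t]]
    if (tm$type == "iid") {
      tm$mdiag <- n_per_line
      tm$diagonal <- TRUE
    } else {
      M <- crossprod(tm$B, tm$B * n_per_line)
      offdiag <- max(abs(M - diag(diag(M), nrow(M))))
      tm$diagonal <- offdiag < 1e-8 * max(diag(M), 1)
      if (tm$diagonal) tm$mdiag <- diag(M) else tm$M <- M
    }
    terms[[t]] <- tm
  }

  # priors: scale so the prior mode hits an equal split of prior_r2*var(y)
  df0 <- settings$prior_df
  var_y <- if (family == "ordinal") 1 else max(var(y_init), 1e-6)
  n_rand <- length(term_names)
  mode_t <- settings$prior_r2 * var_y / max(n_rand, 1)
  S0 <- mode_t * (df0 + 2) / df0           # prior scale, random terms
  Se0 <- (1 - settings$prior_r2) * var_y * (df0 + 2) / df0
  fixv <- settings$fix_variances %||% list()

  # state
  y_work <- y_init
  beta <- as.numeric(rowsum(y_work, fix_idx) / n_per_cell)
  s2 <- setNames(rep(mode_t, n_rand), term_names)
  for (t in term_names)
    if (!is.null(fixv[[var_name(t)]])) s2[t] <- fixv[[var_name(t)]]
  s2_e <- if (family == "ordinal") 1
          else fixv$sigma2_e %||% ((1 - settings$prior_r2) * var_y)
  delta <- lapply(terms, function(tm) numeric(tm$q))
  u_line <- lapply(terms, function(tm) numeric(n_lines))
  eta <- beta[fix_idx]

  if (family == "ordinal") {
    C <- ordinal$C
    cat_obs <- ordinal$cat
    # start thresholds at the inverse-normal cumulative category frequencies
    freq <- tabulate(cat_obs, C)
    cum <- cumsum(freq)[-C] / n_obs
    gamma <- qnorm(pmin(pmax(cum, 1 / (2 * n_obs)), 1 - 1 / (2 * n_obs)))
    gamma <- gamma + cumsum(c(0, pmax(0, 1e-6 - diff(gamma))))  # enforce increase
    gamma_ext <- c(-Inf, gamma, Inf)
    y_work <- pmin(pmax(gamma_ext[cat_obs] + 0.5, -3), 3)
    y_work[!is.finite(y_work)] <- 0
    empty_mid <- which(freq[-c(1L, C)] == 0L) + 1L
    if (length(empty_mid))
      warning("empty intermediate ordinal categories: thresholds weakly identified",
              call. = FALSE)
  }
  if (family == "censored") {
    lower <- bounds$lower
    upper <- bounds$upper
    free <- bounds$free
  }

  n_keep <- (settings$n_iter - settings$burn_in) %/% settings$thin
  var_draws <- matrix(NA_real_, n_keep, n_rand + 1,
                      dimnames = list(NULL, c(paste0("sigma2_", term_names),
                                              "sigma2_e")))
  beta_draws <- matrix(NA_real_, n_keep, p)
  gamma_draws <- if (family == "ordinal")
    matrix(NA_real_, n_keep, ordinal$C - 1L) else NULL
  eff_sum <- lapply(terms, function(tm) numeric(n_lines))
  eff_sumsq <- lapply(terms, function(tm) numeric(n_lines))
  gebv_sum <- numeric(n_lines)
  eta_sum <- numeric(n_obs)
  ywork_sum <- numeric(n_obs)
  prob_sum <- if (family == "ordinal") matrix(0, n_obs, ordinal$C) else NULL
  kept <- 0L

  for (iter in seq_len(settings$n_iter)) {
    ## latent working response
    if (family == "ordinal") {
      gamma_ext <- c(-Inf, gamma, Inf)
      y_work <- rtruncnorm(n_obs, eta, 1, gamma_ext[cat_obs],
                           gamma_ext[cat_obs + 1L])
      # Albert-Chib uniform threshold conditionals (clamped for empty tails)
      for (c in seq_len(C - 1L)) {
        in_c <- y_work[cat_obs == c]
        in_c1 <- y_work[cat_obs == c + 1L]
        lo <- if (length(in_c)) max(in_c) else if (c > 1L) gamma[c - 1L] else -15
        hi <- if (length(in_c1)) min(in_c1) else if (c < C - 1L) gamma[c + 1L] else 15
        lo <- max(lo, if (c > 1L) gamma[c - 1L] else -15)
        hi <- min(hi, if (c < C - 1L) gamma[c + 1L] else 15)
        gamma[c] <- runif(1L, lo, hi)
      }
    } else if (family == "censored" && any(free)) {
      y_work[free] <- rtruncnorm(sum(free), eta[free], sqrt(s2_e),
                                 lower[free], upper[free])
    }

    ## fixed effects (flat prior; disjoint indicator design)
    r <- y_work - eta + beta[fix_idx]
    cell_mean <- as.numeric(rowsum(r, fix_idx)) / n_per_cell
    beta <- cell_mean + rnorm(p) * sqrt(s2_e / n_per_cell)
    eta <- beta[fix_idx]
    for (t in term_names) eta <- eta + u_line[[t]][line_idx]

    ## random terms
    for (t in term_names) {
      tm <- terms[[t]]
      r_obs <- y_work - eta + u_line[[t]][line_idx]
      r_line <- as.numeric(rowsum(r_obs, line_idx))
      rhs <- if (tm$type == "iid") r_line else crossprod(tm$B, r_line)
      rhs <- rhs / s2_e
      if (tm$diagonal) {
        prec <- tm$mdiag / s2_e + 1 / s2[t]
        d <- as.numeric(rhs) / prec + rnorm(tm$q) / sqrt(prec)
      } else {
        Cmat <- tm$M / s2_e + diag(1 / s2[t], tm$q)
        R <- chol(Cmat)
        mu <- backsolve(R, forwardsolve(t(R), rhs))
        d <- as.numeric(mu + backsolve(R, rnorm(tm$q)))
      }
      u_new <- if (tm$type == "iid") d else as.numeric(tm$B %*% d)
      eta <- eta + (u_new - u_line[[t]])[line_idx]
      delta[[t]] <- d
      u_line[[t]] <- u_new
      if (is.null(fixv[[var_name(t)]]))
        s2[t] <- rscinvchisq(df0 + tm$q, df0 * S0 + sum(d^2))
    }

    ## residual variance
    if (family != "ordinal" && is.null(fixv$sigma2_e)) {
      sse <- sum((y_work - eta)^2)
      s2_e <- rscinvchisq(df0 + n_obs, df0 * Se0 + sse)
    }

    ## record
    if (iter > settings$burn_in &&
        (iter - settings$burn_in) %% settings$thin == 0L) {
      kept <- kept + 1L
      var_draws[kept, ] <- c(s2, s2_e)
      beta_draws[kept, ] <- beta
      if (family == "ordinal") gamma_draws[kept, ] <- gamma
      g_tot <- numeric(n_lines)
      for (t in term_names) {
        eff_sum[[t]] <- eff_sum[[t]] + u_line[[t]]
        eff_sumsq[[t]] <- eff_sumsq[[t]] + u_line[[t]]^2
        g_tot <- g_tot + u_line[[t]]
      }
      gebv_sum <- gebv_sum + g_tot
      eta_sum <- eta_sum + eta
      ywork_sum <- ywork_sum + y_work
      if (family == "ordinal") {
        cum <- pnorm(matrix(gamma, n_obs, C - 1L, byrow = TRUE) - eta)
        prob_sum <- prob_sum + (cbind(cum, 1) - cbind(0, cum))
      }
    }
  }

  ## summaries
  qlo <- function(x) quantile(x, 0.025, names = FALSE)
  qhi <- function(x) quantile(x, 0.975, names = FALSE)
  variances <- data.frame(
    component = colnames(var_draws),
    mean = colMeans(var_draws),
    ci_low = apply(var_draws, 2, qlo),
    ci_high = apply(var_draws, 2, qhi),
    ess = apply(var_draws, 2, ess),
    fixed = c(vapply(term_names, function(t)
      !is.null(fixv[[var_name(t)]]), logical(1)),
      family == "ordinal" || !is.null(fixv$sigma2_e)),
    row.names = NULL, stringsAsFactors = FALSE)
  low_ess <- variances$component[!variances$fixed &
                                   variances$ess < settings$ess_warn]
  if (length(low_ess))
    warning("low effective sample size for ", paste(low_ess, collapse = ", "),
            call. = FALSE)

  effects <- list()
  alpha <- list()
  for (t in term_names) {
    m <- eff_sum[[t]] / kept
    sdv <- sqrt(pmax(eff_sumsq[[t]] / kept - m^2, 0))
    effects[[t]] <- data.frame(line = lines, mean = m, sd = sdv,
                               ci_low = m - 1.96 * sdv,
                               ci_high = m + 1.96 * sdv,
                               stringsAsFactors = FALSE)
    alpha[[t]] <- if (terms[[t]]$type == "iid") m else
      as.numeric(kernel_pinv_mult(kernel_subset(
        kernels[[if (t == "g") "G" else "GxG"]], lines), m))
  }

  beta_df <- data.frame(level = fix_levels, mean = colMeans(beta_draws),
                        ci_low = apply(beta_draws, 2, qlo),
                        ci_high = apply(beta_draws, 2, qhi),
                        stringsAsFactors = FALSE)

  fit <- list(family = family, spec = spec, settings = settings,
              lines = lines, n_obs = n_obs,
              fix_levels = fix_levels,
              beta = beta_df,
              variances = variances,
              effects = effects,
              alpha = alpha,
              gebv = data.frame(line = lines, gebv = gebv_sum / kept,
                                stringsAsFactors = FALSE),
              fitted = eta_sum / kept,
              latent_mean = ywork_sum / kept,
              line_idx = line_idx, fix_idx = fix_idx,
              n_draws = kept)
  if (family == "ordinal") {
    fit$gamma <- data.frame(threshold = paste0("gamma", seq_len(C - 1L)),
                            mean = colMeans(gamma_draws),
                            ci_low = apply(gamma_draws, 2, qlo),
                            ci_high = apply(gamma_draws, 2, qhi),
                            stringsAsFactors = FALSE)
    fit$probs <- prob_sum / kept
    colnames(fit$probs) <- as.character(ordinal$labels)
    fit$categories <- ordinal$labels
  }
  if (settings$keep_draws) {
    fit$draws <- list(variances = var_draws, beta = beta_draws,
                      gamma = gamma_draws)
  }
  class(fit) <- "gp_fit"
  fit
}

#' @export
print.gp_fit <- function(x, ...) {
  on <- c("R"[x$spec$replicate], "L"[x$spec$line], "G"[x$spec$markers],
          "GxG"[x$spec$epistasis])
  cat("gp_fit (", x$family, "): ", paste(on, collapse = " + "), ", ",
      length(x$lines), " lines, ", x$n_obs, " observations, ",
      x$n_draws, " retained draws\n", sep = "")
  print(x$variances[, c("component", "mean", "ci_low", "ci_high")],
        row.names = FALSE)
  invisible(x)
}

normalize_long <- function(obs, value_col) {
  if (is.numeric(obs)) {
    if (is.null(names(obs))) stop_arg("a per-line vector must be named by line")
    obs <- data.frame(line = names(obs), replicate = 1L, value = as.numeric(obs),
                      stringsAsFactors = FALSE)
    names(obs)[3] <- value_col
  }
  need <- c("line", value_col)
  if (!all(need %in% names(obs)))
    stop_arg("observations need columns ", paste(need, collapse = ", "))
  if (is.null(obs$replicate)) obs$replicate <- 1L
  obs
}

#' Fit a Gaussian GP model
#'
#' Gibbs sampling with conjugate updates for a continuous trait; see the
#' package overview for the shared linear-predictor structure.
#'
#' @param y Named per-line numeric vector, or a data.frame with columns
#'   \code{line}, \code{value} and optionally \code{replicate}.
#' @param spec A \code{\link{predictor_spec}} (or \code{\link{model_spec}}).
#' @param kernels List with \code{G} and/or \code{GxG}
#'   \code{gp_kernel} objects covering all lines in \code{y}.
#' @param settings A \code{\link{mcmc_settings}}.
#' @return A \code{gp_fit}: posterior means and 95% credible intervals for
#'   fixed effects, variance components and random-effect vectors; fitted
#'   values; per-line genomic values (\code{gebv}); prediction
#'   coefficients used by \code{\link{predict_new_lines}}.
#' @export
fit_gaussian <- function(y, spec, kernels = NULL, settings = mcmc_settings()) {
  obs <- normalize_long(y, "value")
  if (!all(is.finite(obs$value))) stop_arg("trait values must be finite")
  if (anyDuplicated(obs[c("line", "replicate")]))
    stop_arg("duplicated (line, replicate) records")
  gp_gibbs(obs$value, obs$line, obs$replicate, spec, kernels, settings,
           family = "gaussian")
}

#' Fit an interval-censored Gaussian GP model
#'
#' Identical to \code{\link{fit_gaussian}} except that every record whose
#' censoring interval is non-degenerate has its latent trait value
#' re-sampled each iteration from a normal truncated to (a, b). Records
#' with \code{a = y = b} behave as exact observations; records with
#' unknown \code{y} but finite bounds are allowed.
#'
#' @param obs data.frame with columns \code{line}, \code{y} (may be NA for
#'   interval-only records), \code{a}, \code{b}.
#' @inheritParams fit_gaussian
#' @return A \code{gp_fit}; \code{latent_mean} holds the posterior mean of
#'   each record's latent trait value.
#' @export
fit_censored <- function(obs, spec, kernels = NULL, settings = mcmc_settings()) {
  need <- c("line", "a", "b")
  if (!all(need %in% names(obs)))
    stop_arg("censored observations need columns line, y, a, b")
  if (is.null(obs$y)) obs$y <- NA_real_
  if (any(obs$a > obs$b)) stop_arg("censoring bounds must satisfy a <= b")
  degen <- obs$a == obs$b
  if (any(degen & is.na(obs$y))) obs$y[degen & is.na(obs$y)] <- obs$a[degen & is.na(obs$y)]
  if (any(!degen & !is.na(obs$y) & (obs$y <= obs$a | obs$y >= obs$b)))
    stop_arg("point values must lie inside their censoring interval")
  free <- obs$a < obs$b
  init <- ifelse(is.na(obs$y),
                 ifelse(is.finite(obs$a) & is.finite(obs$b),
                        (obs$a + obs$b) / 2,
                        ifelse(is.finite(obs$a), obs$a + 1,
                               ifelse(is.finite(obs$b), obs$b - 1, 0))),
                 obs$y)
  gp_gibbs(init, obs$line, obs$replicate, spec, kernels, settings,
           family = "censored",
           bounds = list(lower = obs$a, upper = obs$b, free = free))
}

#' Fit a threshold (ordinal probit) GP model
#'
#' Gibbs sampling with data augmentation: each observation's latent
#' liability is drawn from a normal (residual variance fixed at 1 for
#' probit identification) truncated to its category's threshold interval;
#' thresholds are drawn from their uniform full conditionals between the
#' largest liability of one category and the smallest of the next. Because
#' a location shift can trade between fixed effects and thresholds, both
#' raw and anchored (minus mean fixed effect) estimates are exposed via
#' \code{\link{anchored_parameters}}.
#'
#' @param obs data.frame with columns \code{line}, \code{replicate},
#'   \code{category} (integer labels; at least 2 observed categories).
#' @inheritParams fit_gaussian
#' @return A \code{gp_fit} with additional fields \code{gamma} (threshold
#'   summaries), \code{probs} (per-observation posterior category
#'   probabilities, rows summing to 1) and \code{categories} (labels).
#' @export
fit_ordinal_threshold <- function(obs, spec, kernels = NULL,
                                  settings = mcmc_settings()) {
  need <- c("line", "category")
  if (!all(need %in% names(obs)))
    stop_arg("ordinal observations need columns line, replicate, category")
  labels <- sort(unique(obs$category))
  if (length(labels) < 2L) stop_arg("degenerate ordinal response: single observed category")
  if (is.numeric(labels) && all(labels == round(labels)))
    labels <- seq(min(labels), max(labels))   # keep empty middle categories
  cat_obs <- match(obs$category, labels)
  if (anyNA(cat_obs)) stop_arg("categories outside the label set")
  gp_gibbs(numeric(nrow(obs)), obs$line, obs$replicate, spec, kernels,
           settings, family = "ordinal",
           ordinal = list(cat = cat_obs, C = length(labels), labels = labels))
}

#' Fit a log-normal GP model to count data
#'
#' Transforms counts with log(y + 1) and delegates to the Gaussian sampler
#' at observation level; with the same seed and settings the two routes
#' are identical draw for draw. Fitted counts are reported back on the
#' count scale as exp(fitted) - 1.
#'
#' @param obs data.frame with columns \code{line}, \code{replicate},
#'   \code{count} (non-negative integers).
#' @inheritParams fit_gaussian
#' @return A \code{gp_fit} with an extra element \code{fitted_count}.
#' @export
fit_lognormal_count <- function(obs, spec, kernels = NULL,
                                settings = mcmc_settings()) {
  if (!all(c("line", "count") %in% names(obs)))
    stop_arg("count observations need columns line, replicate, count")
  if (any(obs$count < 0) || any(obs$count != round(obs$count)))
    stop_arg("counts must be non-negative integers")
  obs$value <- log(obs$count + 1)
  fit <- fit_gaussian(obs[c("line", "replicate", "value")], spec, kernels,
                      settings)
  fit$family <- "lognormal"
  fit$fitted_count <- exp(fit$fitted) - 1
  fit
}

#' Anchored fixed effects and thresholds of an ordinal fit
#'
#' In the threshold model a constant can shift between the fixed effects
#' and the thresholds without changing the likelihood. Anchored
#' parameters subtract the mean fixed effect from both vectors, making
#' fits (and recovery against generating values) comparable.
#'
#' @param fit A \code{gp_fit} from \code{\link{fit_ordinal_threshold}}.
#' @return List with \code{beta} and \code{gamma} anchored posterior means.
#' @export
anchored_parameters <- function(fit) {
  stopifnot(inherits(fit, "gp_fit"))
  if (is.null(fit$gamma)) stop_arg("anchoring applies to ordinal fits")
  mb <- mean(fit$beta$mean)
  list(beta = fit$beta$mean - mb, gamma = fit$gamma$mean - mb)
}
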