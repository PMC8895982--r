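# Model-definition objects: which linear predictors enter a fit, and the
# MCMC chain settings with their priors.

#' Linear-predictor specification
#'
#' Selects which terms enter a genomic-prediction model: replicate fixed
#' effects (R), iid line effects (L), genomic effects with the G kernel
#' (G), and first-order additive-by-additive epistatic effects with the
#' Hadamard square of G (GxG). The five canonical predictor sets used
#' throughout this package are available via \code{model_spec()}.
#'
#' @param replicate Include replicate fixed effects (a full dummy set; for
#'   single-record traits this collapses to a global intercept).
#' @param line Include iid line effects L ~ N(0, I sigma2_L).
#' @param markers Include genomic effects g ~ N(0, G sigma2_g).
#' @param epistasis Include epistatic effects gA ~ N(0, GxG sigma2_gA);
#'   requires \code{markers}' kernel to exist.
#' @return An object of class \code{predictor_spec}.
#' @export
predictor_spec <- function(replicate = TRUE, line = FALSE, markers = FALSE,
                           epistasis = FALSE) {
  for (nm in c("replicate", "line", "markers", "epistasis"))
    check_flag(get(nm), nm)
  if (!line && !markers)
    stop_arg("at least one of line or markers must be included")
  if (epistasis && !markers)
    stop_arg("epistasis requires the marker kernel (G) to be included")
  structure(list(replicate = replicate, line = line, markers = markers,
                 epistasis = epistasis),
            class = "predictor_spec")
}

#' The five canonical predictor sets
#'
#' Model 1: R + L; Model 2: R + G; Model 3: R + G + GxG;
#' Model 4: R + L + G; Model 5: R + L + G + GxG.
#'
#' @param model Integer 1-5.
#' @return A \code{predictor_spec}.
#' @export
model_spec <- function(model) {
  stopifnot(length(model) == 1L, model %in% 1:5)
  switch(model,
         predictor_spec(line = TRUE),
         predictor_spec(markers = TRUE),
         predictor_spec(markers = TRUE, epistasis = TRUE),
         predictor_spec(line = TRUE, markers = TRUE),
         predictor_spec(line = TRUE, markers = TRUE, epistasis = TRUE))
}

#' @export
print.predictor_spec <- function(x, ...) {
  on <- c("R"[x$replicate], "L"[x$line], "G"[x$markers], "GxG"[x$epistasis])
  cat("predictor_spec:", paste(on, collapse = " + "), "\n")
  invisible(x)
}

#' MCMC settings and priors for the Gibbs samplers
#'
#' Each variance component carries a scaled-inverse-chi-square prior with
#' \code{prior_df} degrees of freedom; the prior scale is set so the prior
#' mode equals \code{prior_r2 * var(response)} split equally among the
#' included random terms, and \code{(1 - prior_r2) * var(response)} for
#' the residual.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Discarded initial iterations (must be < n_iter).
#' @param thin Keep every \code{thin}-th post-burn-in draw.
#' @param seed Integer seed (NULL = use the current RNG state).
#' @param prior_df Prior degrees of freedom for every variance component.
#' @param prior_r2 Prior fraction of the response variance attributed to
#'   the random terms jointly.
#' @param fix_variances Optional named list (e.g. \code{list(sigma2_g = 1,
#'   sigma2_e = 1)}); named components are held fixed instead of sampled.
#' @param keep_draws Store retained draws of scalar parameters (needed for
#'   credible intervals from quantiles; effect-vector intervals always use
#'   a running normal approximation).
#' @param ess_warn Warn when a variance component's effective sample size
#'   falls below this.
#' @return An object of class \code{mcmc_settings}.
#' @export
mcmc_settings <- function(n_iter = 30000, burn_in = 5000, thin = 5,
                          seed = NULL, prior_df = 5, prior_r2 = 0.5,
                          fix_variances = NULL, keep_draws = TRUE,
                          ess_warn = 100) {
  if (burn_in >= n_iter) stop_arg("burn_in must be smaller than n_iter")
  if (thin < 1) stop_arg("thin must be >= 1")
  if (prior_df <= 0) stop_arg("prior_df must be positive")
  if (prior_r2 <= 0 || prior_r2 >= 1) stop_arg("prior_r2 must be in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 prior_df = prior_df, prior_r2 = prior_r2,
                 fix_variances = fix_variances,
                 keep_draws = isTRUE(keep_draws), ess_warn = ess_warn),
            class = "mcmc_settings")
}
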