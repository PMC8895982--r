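# Phenotype generators: ordinal (threshold liability), count (log-normal),
# interval-censored continuous, and transpiration-response curves.

# Draw the per-line random effects of the generating model:
# L ~ N(0, I sigma2_L), g ~ N(0, G sigma2_g), gA ~ N(0, GxG sigma2_gA).
draw_line_effects <- function(kernels, config) {
  n <- config$n_lines
  vc <- config$variance_components
  draw_kernel <- function(k, s2) {
    if (s2 == 0) return(numeric(n))
    k <- eigendecompose(k)
    lam <- pmax(k$values, 0)
    as.numeric(k$vectors %*% (sqrt(lam * s2) * rnorm(length(lam))))
  }
  L <- rnorm(n, 0, sqrt(vc$sigma2_L))
  g <- draw_kernel(kernels$G, vc$sigma2_g)
  gA <- draw_kernel(kernels$GxG, vc$sigma2_gA)
  list(L = L, g = g, gA = gA)
}

check_sim_inputs <- function(geno, kernels, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(geno) != config$n_lines)
    stop_arg("genotype matrix and config disagree on n_lines")
  for (nm in c("G", "GxG")) {
    k <- kernels[[nm]]
    if (is.null(k)) stop_arg("kernels must contain elements 'G' and 'GxG'")
    if (!identical(k$line_ids, rownames(geno)))
      stop_arg("kernel ", nm, " is not indexed like the genotype matrix")
  }
}

#' Simulate a replicated ordinal trait through a threshold liability model
#'
#' Per observation (line i, replicate k) the liability is
#' \code{l_ik = beta_k + L_i + g_i + gA_i + e_ik} with standard-normal
#' residual (probit identification). The observed category is the interval
#' of the threshold vector the liability falls in; categories carry the
#' labels in \code{config$category_labels} (2..8 for the default 7-category
#' seminal-root-number design).
#'
#' @param geno A \code{genotype_matrix} (used for dimension checks and id
#'   alignment).
#' @param kernels List with \code{G} and \code{GxG} \code{gp_kernel}
#'   objects indexed like \code{geno}.
#' @param config A \code{\link{sim_config}}; \code{thresholds} must be
#'   strictly increasing.
#' @return List with \code{data} (data.frame line, replicate, category)
#'   and \code{truth} (realized effects, liabilities, generating
#'   parameters) for parameter-recovery tests.
#' @export
simulate_ordinal_trait <- function(geno, kernels, config) {
  check_sim_inputs(geno, kernels, config)
  if (length(config$thresholds) < 1L)
    stop_arg("ordinal simulation needs at least one threshold")
  if (any(diff(config$thresholds) <= 0))
    stop_arg("thresholds must be strictly increasing")
  set.seed(config$seed + 1L)
  eff <- draw_line_effects(kernels, config)
  n <- config$n_lines
  r <- config$n_replicates
  line <- rep(rownames(geno), times = r)
  repl <- rep(seq_len(r), each = n)
  eta <- config$fixed_effects[repl] +
    (eff$L + eff$g + eff$gA)[rep(seq_len(n), times = r)]
  liab <- eta + rnorm(n * r)
  cat_idx <- findInterval(liab, config$thresholds) + 1L
  data <- data.frame(line = line, replicate = repl,
                     category = config$category_labels[cat_idx],
                     stringsAsFactors = FALSE)
  list(data = data,
       truth = c(eff, list(beta = config$fixed_effects,
                           thresholds = config$thresholds,
                           liabilities = liab,
                           variance_components = config$variance_components)))
}

#' Simulate a replicated count trait via a log-normal latent scale
#'
#' The latent value is \code{eta_ik = beta_k + L_i + g_i + gA_i + eps_ik}
#' with \code{eps ~ N(0, sigma2_e)}; the count is the exact inverse of the
#' log(y + 1) analysis link: \code{y = max(0, round(exp(eta) - 1))}.
#'
#' @inheritParams simulate_ordinal_trait
#' @return List with \code{data} (line, replicate, count) and \code{truth}.
#' @export
simulate_count_trait <- function(geno, kernels, config) {
  check_sim_inputs(geno, kernels, config)
  set.seed(config$seed + 2L)
  eff <- draw_line_effects(kernels, config)
  n <- config$n_lines
  r <- config$n_replicates
  line <- rep(rownames(geno), times = r)
  repl <- rep(seq_len(r), each = n)
  eta <- config$fixed_effects[repl] +
    (eff$L + eff$g + eff$gA)[rep(seq_len(n), times = r)] +
    rnorm(n * r, 0, sqrt(config$variance_components$sigma2_e))
  count <- pmax(0, round(exp(eta) - 1))
  data <- data.frame(line = line, replicate = repl, count = count,
                     stringsAsFactors = FALSE)
  list(data = data,
       truth = c(eff, list(beta = config$fixed_effects, eta = eta,
                           variance_components = config$variance_components)))
}

#' Simulate a per-line continuous trait with censoring intervals
#'
#' One record per line: \code{y_i = L_i + g_i + gA_i + eps_i}. Each value
#' is emitted together with the interval (\code{a_i = y_i - 2 obs_sd_i},
#' \code{b_i = y_i + 2 obs_sd_i}) mimicking an adjusted mean carried with
#' plus/minus two standard errors, the form consumed by
#' \code{\link{fit_censored}}.
#'
#' @inheritParams simulate_ordinal_trait
#' @param obs_sd Per-line observation standard error (scalar recycled).
#' @return List with \code{data} (line, y, a, b) and \code{truth}.
#' @export
simulate_censored_trait <- function(geno, kernels, config, obs_sd = 0) {
  check_sim_inputs(geno, kernels, config)
  if (any(obs_sd < 0)) stop_arg("obs_sd must be >= 0")
  set.seed(config$seed + 3L)
  eff <- draw_line_effects(kernels, config)
  n <- config$n_lines
  obs_sd <- rep_len(obs_sd, n)
  y <- eff$L + eff$g + eff$gA +
    rnorm(n, 0, sqrt(config$variance_components$sigma2_e))
  data <- data.frame(line = rownames(geno), y = y,
                     a = y - 2 * obs_sd, b = y + 2 * obs_sd,
                     stringsAsFactors = FALSE)
  list(data = data,
       truth = c(eff, list(obs_sd = obs_sd,
                           variance_components = config$variance_components)))
}

#' Simulate transpiration-rate response curves over a VPD gradient
#'
#' Emulates whole-plant transpiration rate (TR, mg H2O m-2 s-1) measured
#' under rising vapor pressure deficit (VPD, kPa). A fraction of lines
#' respond linearly; the rest follow a continuous two-segment response
#' whose slope drops after a breakpoint (default breakpoints 2.3–2.5 kPa,
#' inside the 0.4–5.4 kPa measurement range).
#'
#' @param n_lines Number of lines.
#' @param vpd_grid Strictly increasing VPD measurement grid (kPa).
#' @param fraction_linear Fraction of lines with a purely linear response.
#' @param breakpoint_range Interval (kPa) for segmented-line breakpoints;
#'   must lie strictly inside the VPD grid.
#' @param slope_range Interval for the initial TR-vs-VPD slope.
#' @param slope2_frac_range Interval for the post-breakpoint slope as a
#'   fraction of the initial slope.
#' @param intercept_range Interval for the TR intercept.
#' @param noise_sd Gaussian measurement noise SD (TR units).
#' @param seed Integer seed.
#' @return List with \code{curves} (data.frame line, vpd, tr) and
#'   \code{truth} (per line: kind, intercept, slope1, slope2, breakpoint).
#' @export
simulate_tr_vpd_curves <- function(n_lines = 90,
                                   vpd_grid = seq(0.4, 5.4, by = 0.25),
                                   fraction_linear = 28 / 90,
                                   breakpoint_range = c(2.3, 2.5),
                                   slope_range = c(1.5, 4.5),
                                   slope2_frac_range = c(0.1, 0.5),
                                   intercept_range = c(0.5, 2),
                                   noise_sd = 0.1,
                                   seed = 1L) {
  if (any(diff(vpd_grid) <= 0)) stop_arg("vpd_grid must be strictly increasing")
  if (breakpoint_range[1] <= min(vpd_grid) ||
      breakpoint_range[2] >= max(vpd_grid))
    stop_arg("breakpoint_range must lie strictly inside the vpd_grid")
  if (fraction_linear < 0 || fraction_linear > 1)
    stop_arg("fraction_linear must be in [0, 1]")
  set.seed(seed)
  ids <- sprintf("L%03d", seq_len(n_lines))
  n_lin <- round(fraction_linear * n_lines)
  kind <- sample(rep(c("linear", "segmented"),
                     c(n_lin, n_lines - n_lin)))
  b0 <- runif(n_lines, intercept_range[1], intercept_range[2])
  b1 <- runif(n_lines, slope_range[1], slope_range[2])
  bp <- runif(n_lines, breakpoint_range[1], breakpoint_range[2])
  b2 <- b1 * runif(n_lines, slope2_frac_range[1], slope2_frac_range[2])
  bp[kind == "linear"] <- NA_real_
  b2[kind == "linear"] <- NA_real_

  curves <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    mu <- if (kind[i] == "linear") {
      b0[i] + b1[i] * vpd_grid
    } else {
      b0[i] + b1[i] * pmin(vpd_grid, bp[i]) +
        b2[i] * pmax(0, vpd_grid - bp[i])
    }
    data.frame(line = ids[i], vpd = vpd_grid,
               tr = mu + rnorm(length(vpd_grid), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  truth <- data.frame(line = ids, kind = kind, intercept = b0,
                      slope1 = b1, slope2 = b2, breakpoint = bp,
                      stringsAsFactors = FALSE)
  list(curves = curves, truth = truth)
}
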