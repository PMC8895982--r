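# End-to-end orchestration: descriptives -> correlations -> kernels ->
# model fits -> leave-one-out cross-validation, with every artifact
# written as plain text (CSV/TSV/JSON).

#' Pipeline configuration
#'
#' Inputs are file paths or the directive \code{"synthetic"}; synthetic
#' stages draw from \code{sim} (a \code{\link{sim_config}}, whose seed
#' drives all randomness).
#'
#' @param genotypes Path to a genotype CSV or \code{"synthetic"}.
#' @param ordinal Path to a long-format ordinal phenotype CSV
#'   (line, replicate, category as value), \code{"synthetic"}, or NULL to
#'   skip the ordinal stage.
#' @param censored \code{"synthetic"}, a means-format CSV path, or NULL.
#' @param tr \code{"synthetic"}, a TR-format CSV path, or NULL.
#' @param sim \code{\link{sim_config}} used for synthetic stages.
#' @param models Canonical predictor sets to fit (integers 1-5, see
#'   \code{\link{model_spec}}).
#' @param settings \code{\link{mcmc_settings}} for the full fits.
#' @param cv_settings \code{\link{mcmc_settings}} for per-fold CV chains.
#' @param run_cv Run leave-one-out cross-validation.
#' @param retain_bounds Bounds-retention flag for censored-trait CV.
#' @param obs_sd Per-line SE used when simulating the censored trait.
#' @param out_dir Output directory (created if absent).
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(genotypes = "synthetic",
                            ordinal = "synthetic",
                            censored = "synthetic",
                            tr = "synthetic",
                            sim = sim_config(n_lines = 40, n_markers = 400,
                                             n_replicates = 6, seed = 1),
                            models = c(2, 5),
                            settings = mcmc_settings(n_iter = 4000,
                                                     burn_in = 1000),
                            cv_settings = mcmc_settings(n_iter = 1500,
                                                        burn_in = 300,
                                                        thin = 2),
                            run_cv = TRUE,
                            retain_bounds = FALSE,
                            obs_sd = 0.1,
                            out_dir = tempfile("magicgp_run_")) {
  stopifnot(inherits(sim, "sim_config"), all(models %in% 1:5))
  structure(list(genotypes = genotypes, ordinal = ordinal,
                 censored = censored, tr = tr, sim = sim,
                 models = models, settings = settings,
                 cv_settings = cv_settings, run_cv = run_cv,
                 retain_bounds = retain_bounds, obs_sd = obs_sd,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates, in order: genotype input (or simulation), marker
#' filtering and kernel construction, phenotype input (or simulation),
#' descriptive statistics and trait correlations, TR curve fitting, GP
#' model fits for every requested predictor set and available family, and
#' leave-one-out cross-validation. Deterministic given the config (all
#' randomness flows from the config seeds). Every artifact is written
#' under \code{config$out_dir} and is re-readable by the package's own
#' readers; a manifest JSON records inputs and settings.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return (Invisibly) a list with the in-memory results: kernels, trait
#'   tables, fits, CV results, correlation matrix and file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list()

  ## genotypes + kernels
  geno <- stage("genotypes", {
    if (identical(config$genotypes, "synthetic"))
      simulate_magic_genotypes(config$sim)
    else read_genotype_csv(config$genotypes)
  })
  geno <- stage("filter", filter_and_impute(geno))
  paths$genotypes <- file.path(out, "genotypes.csv")
  write_genotype_csv(geno, paths$genotypes)
  kernels <- stage("kernels", {
    G <- eigendecompose(vanraden_g(geno))
    list(G = G, GxG = eigendecompose(epistatic_kernel(G)))
  })
  kern_summary <- data.frame(
    kernel = c("G", "GxG"),
    mean_diag = c(mean(diag(kernels$G$matrix)), mean(diag(kernels$GxG$matrix))),
    min_eigenvalue = c(min(kernels$G$values), min(kernels$GxG$values)),
    rank = c(sum(kernels$G$values > 0), sum(kernels$GxG$values > 0)))
  paths$kernels <- file.path(out, "kernel_summary.tsv")
  write.table(kern_summary, paths$kernels, sep = "\t", row.names = FALSE,
              quote = FALSE)

  traits <- list()
  truth <- list()

  ## ordinal trait
  if (!is.null(config$ordinal)) {
    if (identical(config$ordinal, "synthetic")) {
      sim <- stage("ordinal input",
                   simulate_ordinal_trait(geno, kernels, config$sim))
      truth$ordinal <- sim$truth
      traits$ordinal <- sim$data
    } else {
      df <- stage("ordinal input", read_phenotype_csv(config$ordinal, "long"))
      traits$ordinal <- data.frame(line = df$line, replicate = df$replicate,
                                   category = df$value,
                                   stringsAsFactors = FALSE)
    }
  }

  ## censored trait (per-line adjusted means with bounds)
  if (!is.null(config$censored)) {
    if (identical(config$censored, "synthetic")) {
      sim <- stage("censored input",
                   simulate_censored_trait(geno, kernels, config$sim,
                                           obs_sd = config$obs_sd))
      truth$censored <- sim$truth
      traits$censored <- sim$data
    } else {
      df <- stage("censored input", read_phenotype_csv(config$censored, "means"))
      traits$censored <- data.frame(line = df$line, y = df$blue,
                                    a = df$blue - 2 * df$se,
                                    b = df$blue + 2 * df$se,
                                    stringsAsFactors = FALSE)
    }
  }

  ## TR curves -> per-line value at 2.7 kPa
  tr_values <- NULL
  if (!is.null(config$tr)) {
    curves <- stage("tr input", {
      if (identical(config$tr, "synthetic")) {
        sim <- simulate_tr_vpd_curves(n_lines = config$sim$n_lines,
                                      seed = config$sim$seed)
        sim$curves
      } else read_phenotype_csv(config$tr, "tr")
    })
    tr_values <- stage("tr fits", prepare_tr_values(curves))
    paths$tr_fits <- file.path(out, "tr_fits.csv")
    write_phenotype_csv(tr_values, paths$tr_fits)
  }

  ## descriptives + correlations
  desc <- list()
  cont <- list()
  if (!is.null(traits$censored)) {
    desc$censored <- descriptive_stats(traits$censored$y)
    cont$censored <- setNames(traits$censored$y, traits$censored$line)
  }
  if (!is.null(tr_values)) {
    desc$tr <- descriptive_stats(tr_values$tr_at)
    cont$tr <- setNames(tr_values$tr_at, tr_values$line)
  }
  ord_mean <- NULL
  if (!is.null(traits$ordinal)) {
    desc$ordinal <- descriptive_stats(traits$ordinal$category)
    ord_mode <- vapply(split(traits$ordinal$category, traits$ordinal$line),
                       function(v) as.numeric(names(which.max(table(v)))),
                       numeric(1))
    ord_mean <- ord_mode
  }
  if (length(desc)) {
    desc_df <- data.frame(trait = names(desc), do.call(rbind, desc))
    paths$descriptives <- file.path(out, "descriptives.csv")
    write.csv(desc_df, paths$descriptives, row.names = FALSE)
  }
  corr <- NULL
  if (length(cont) >= 2 || (length(cont) >= 1 && !is.null(ord_mean))) {
    nm <- names(cont)
    corr <- list()
    if (length(cont) >= 2) {
      for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
        shared <- intersect(names(cont[[i]]), names(cont[[j]]))
        pr <- pearson_r(cont[[i]][shared], cont[[j]][shared])
        corr[[paste(nm[i], nm[j], sep = "_vs_")]] <-
          data.frame(pair = paste(nm[i], nm[j], sep = "-"),
                     type = "pearson", estimate = pr$r, p_value = pr$p_value)
      }
    }
    if (!is.null(ord_mean)) {
      for (i in seq_along(nm)) {
        shared <- intersect(names(cont[[i]]), names(ord_mean))
        ps <- polyserial_r(cont[[i]][shared], ord_mean[shared])
        corr[[paste(nm[i], "ordinal", sep = "_vs_")]] <-
          data.frame(pair = paste(nm[i], "ordinal", sep = "-"),
                     type = "polyserial", estimate = ps$rho,
                     p_value = ps$p_value)
      }
    }
    corr <- do.call(rbind, corr)
    rownames(corr) <- NULL
    paths$correlations <- file.path(out, "correlations.csv")
    write.csv(corr, paths$correlations, row.names = FALSE)
  }

  ## model fits + CV
  fits <- list()
  cvs <- list()
  for (m in config$models) {
    spec <- model_spec(m)
    st <- config$settings
    if (!is.null(st$seed)) st$seed <- st$seed + m
    if (!is.null(traits$ordinal)) {
      nm <- paste0("ordinal_model", m)
      fits[[nm]] <- stage(nm, suppressWarnings(
        fit_ordinal_threshold(traits$ordinal, spec, kernels, st)))
    }
    if (!is.null(traits$censored)) {
      nm <- paste0("censored_model", m)
      fits[[nm]] <- stage(nm, suppressWarnings(
        fit_censored(traits$censored, spec, kernels, st)))
      if (config$run_cv) {
        cvs[[nm]] <- stage(paste0(nm, " cv"), suppressWarnings(
          loo_cross_validate(traits$censored, spec, "censored", kernels,
                             config$cv_settings,
                             retain_bounds = config$retain_bounds)))
      }
    }
  }
  for (nm in names(fits)) {
    paths[[paste0("fit_", nm)]] <- file.path(out, paste0("fit_", nm, ".json"))
    write_gpfit_json(fits[[nm]], paths[[paste0("fit_", nm)]])
  }
  if (length(fits)) {
    vt <- variance_component_table(fits)
    paths$variance_components <- file.path(out, "variance_components.tsv")
    write.table(vt, paths$variance_components, sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  if (length(cvs)) {
    cv_folds <- do.call(rbind, lapply(names(cvs), function(nm)
      data.frame(model = nm, cvs[[nm]]$per_fold)))
    paths$cv_folds <- file.path(out, "cv_folds.csv")
    write.csv(cv_folds, paths$cv_folds, row.names = FALSE)
    agg <- lapply(cvs, function(cv)
      list(unit = cv$unit, retain_bounds = cv$retain_bounds,
           n_folds = cv$n_folds, brier = cv$brier, pccc = cv$pccc,
           predictive_ability = cv$predictive_ability))
    paths$cv_summary <- file.path(out, "cv_summary.json")
    jsonlite::write_json(agg, paths$cv_summary, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }

  manifest <- list(
    seed = config$sim$seed,
    n_lines = config$sim$n_lines, n_markers = config$sim$n_markers,
    models = config$models,
    settings = config$settings[c("n_iter", "burn_in", "thin")],
    inputs = list(genotypes = config$genotypes, ordinal = config$ordinal,
                  censored = config$censored, tr = config$tr),
    artifacts = basename(unlist(paths)))
  paths$manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(genotypes = geno, kernels = kernels, traits = traits,
                 truth = truth, tr_values = tr_values,
                 correlations = corr, fits = fits, cv = cvs,
                 paths = paths, out_dir = out))
}
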