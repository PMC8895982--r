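# CSV / JSON input-output in the supplementary-file dialects: genotype
# tables (first column line id, remaining columns marker dosages) and
# long/means/TR phenotype tables.

#' Read a genotype CSV
#'
#' First column: line identifiers; remaining columns: marker dosages with
#' a header row of marker names. Non-numeric cells become missing. Both
#' the \{0,1,2\} and \{-1,0,1\} dosage dialects are accepted; the latter is
#' detected (any negative dosage, all values within [-1, 1]) and shifted
#' by +1, unless \code{dialect} overrides the detection.
#'
#' @param path CSV file path.
#' @param dialect \code{"auto"}, \code{"012"} or \code{"-101"}.
#' @return A \code{genotype_matrix}; missing-cell count in attribute
#'   \code{"n_missing"}.
#' @export
read_genotype_csv <- function(path, dialect = c("auto", "012", "-101")) {
  dialect <- match.arg(dialect)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_arg("genotype file needs an id column plus markers")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop_arg("duplicate line IDs in genotype file")
  x <- as.matrix(raw[-1])
  storage.mode(x) <- "numeric"   # non-numeric cells coerce to NA
  if (any(colMeans(is.na(x)) == 1))
    stop_arg("all-missing marker column in genotype file")
  rng <- range(x, na.rm = TRUE)
  shifted <- switch(dialect,
                    "012" = FALSE,
                    "-101" = TRUE,
                    auto = rng[1] < 0 && rng[1] >= -1 && rng[2] <= 1)
  if (shifted) x <- x + 1
  rownames(x) <- ids
  out <- as_genotype_matrix(x)
  attr(out, "n_missing") <- sum(is.na(x))
  out
}

#' Write a genotype CSV
#'
#' Inverse of \code{\link{read_genotype_csv}} (always the \{0,1,2\}
#' dialect).
#'
#' @param geno A \code{genotype_matrix}.
#' @param path Output path.
#' @export
write_genotype_csv <- function(geno, path) {
  df <- data.frame(line = rownames(geno), unclass(geno),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

pheno_schemas <- list(
  long = c("line", "replicate", "value"),
  means = c("line", "blue", "se"),
  tr = c("line", "vpd", "tr"))

#' Read a phenotype CSV with schema validation
#'
#' @param path CSV path.
#' @param schema \code{"long"} (line, replicate, value), \code{"means"}
#'   (line, blue, se), or \code{"tr"} (line, vpd, tr).
#' @return data.frame with at least the schema columns.
#' @export
read_phenotype_csv <- function(path, schema = c("long", "means", "tr")) {
  schema <- match.arg(schema)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(pheno_schemas[[schema]], names(df))
  if (length(missing_cols))
    stop_arg("phenotype file does not match schema '", schema,
             "': missing column(s) ", paste(missing_cols, collapse = ", "))
  df
}

#' Write a phenotype CSV
#'
#' @param df data.frame matching one of the phenotype schemas.
#' @param path Output path.
#' @export
write_phenotype_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a GP fit summary as JSON
#'
#' Posterior means and credible intervals of fixed effects, thresholds
#' (ordinal), variance components, plus diagnostics and a settings echo.
#'
#' @param fit A \code{gp_fit}.
#' @param path Output JSON path.
#' @export
write_gpfit_json <- function(fit, path) {
  stopifnot(inherits(fit, "gp_fit"))
  summary <- list(
    family = fit$family,
    predictors = list(replicate = fit$spec$replicate, line = fit$spec$line,
                      markers = fit$spec$markers,
                      epistasis = fit$spec$epistasis),
    n_lines = length(fit$lines), n_obs = fit$n_obs,
    n_draws = fit$n_draws,
    beta = fit$beta, variances = fit$variances,
    settings = list(n_iter = fit$settings$n_iter,
                    burn_in = fit$settings$burn_in,
                    thin = fit$settings$thin,
                    prior_df = fit$settings$prior_df,
                    prior_r2 = fit$settings$prior_r2))
  if (!is.null(fit$gamma)) summary$gamma <- fit$gamma
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
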