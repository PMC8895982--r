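#' Simulation configuration for the synthetic MAGIC population
#'
#' Bundles every parameter the synthetic-data generators need. The defaults
#' emulate the winter-barley MAGIC study design this package targets: 89
#' inbred 8-founder lines genotyped at ~20k biallelic SNPs; an ordinal
#' seedling trait (seminal root number) with 7 categories labelled 2–8
#' scored in 12 replicates; and trait architectures on the liability scale
#' with small line / additive / epistatic variances against a unit probit
#' residual.
#'
#' @param n_lines Number of inbred MAGIC lines.
#' @param n_markers Number of biallelic SNP markers.
#' @param n_founders Number of founder haplotypes (8-way MAGIC by default).
#' @param n_replicates Number of replicates for replicated trait designs.
#' @param variance_components Named list with elements \code{sigma2_L}
#'   (iid line variance), \code{sigma2_g} (additive genomic variance),
#'   \code{sigma2_gA} (additive-by-additive epistatic variance) and
#'   \code{sigma2_e} (residual variance), all on the trait/liability scale.
#' @param thresholds Strictly increasing liability cut-points for ordinal
#'   traits (length C-1 for C categories).
#' @param fixed_effects Replicate fixed effects (length \code{n_replicates});
#'   recycled if scalar.
#' @param category_labels Integer labels for the ordinal categories
#'   (length \code{length(thresholds) + 1}); defaults to 2..8 for the
#'   7-category root-number design.
#' @param maf_range Interval in (0, 0.5] from which founder-panel minor
#'   allele frequencies are drawn.
#' @param segment_length_mean Mean founder-block length, in markers, of the
#'   mosaic genomes (geometric block lengths).
#' @param het_rate Residual heterozygosity rate; MAGIC recombinant inbred
#'   lines are fully homozygous by construction, so the default is 0.
#' @param seed Integer seed; every generator is deterministic given the
#'   config (including its seed).
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_lines = 40, n_markers = 500, seed = 1)
#' @export
sim_config <- function(n_lines = 89,
                       n_markers = 20000,
                       n_founders = 8,
                       n_replicates = 12,
                       variance_components = list(sigma2_L = 0.02,
                                                  sigma2_g = 0.02,
                                                  sigma2_gA = 0.02,
                                                  sigma2_e = 1),
                       thresholds = c(-2.33, -1.55, -0.71, 0.64, 1.41, 2.05),
                       fixed_effects = 0,
                       category_labels = NULL,
                       maf_range = c(0.1, 0.5),
                       segment_length_mean = 50,
                       het_rate = 0,
                       seed = 1L) {
  if (n_lines < 1 || n_markers < 1)
    stop_arg("n_lines and n_markers must be positive")
  if (n_founders < 1) stop_arg("n_founders must be >= 1")
  if (n_replicates < 1) stop_arg("n_replicates must be >= 1")
  vc <- variance_components
  needed <- c("sigma2_L", "sigma2_g", "sigma2_gA", "sigma2_e")
  missing_vc <- setdiff(needed, names(vc))
  for (nm in missing_vc) vc[[nm]] <- 0
  if (any(unlist(vc[needed]) < 0))
    stop_arg("all variance components must be >= 0")
  if (length(thresholds) && any(diff(thresholds) <= 0))
    stop_arg("thresholds must be strictly increasing")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_arg("maf_range must be an interval within (0, 0.5]")
  if (segment_length_mean < 1) stop_arg("segment_length_mean must be >= 1")
  if (het_rate < 0 || het_rate > 1) stop_arg("het_rate must be in [0, 1]")
  n_cat <- length(thresholds) + 1L
  if (is.null(category_labels)) {
    category_labels <- if (n_cat == 7L) 2:8 else seq_len(n_cat)
  }
  if (length(category_labels) != n_cat)
    stop_arg("category_labels must have length(thresholds) + 1 entries")
  fixed_effects <- rep_len(fixed_effects, n_replicates)
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 n_founders = as.integer(n_founders),
                 n_replicates = as.integer(n_replicates),
                 variance_components = vc[needed],
                 thresholds = thresholds,
                 fixed_effects = fixed_effects,
                 category_labels = as.integer(category_labels),
                 maf_range = maf_range,
                 segment_length_mean = segment_length_mean,
                 het_rate = het_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_lines, "lines x", x$n_markers, "markers,",
      x$n_founders, "founders,", x$n_replicates, "replicates\n")
  vc <- unlist(x$variance_components)
  cat("  variances:", paste(names(vc), vc, sep = "=", collapse = ", "), "\n")
  cat("  thresholds:", paste(round(x$thresholds, 3), collapse = ", "), "\n")
  invisible(x)
}
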