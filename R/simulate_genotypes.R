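#' Simulate genotypes for an inbred MAGIC population
#'
#' Generates a lines-by-markers dosage matrix emulating a multiparent
#' advanced generation inter-cross (MAGIC) population of recombinant
#' inbred lines. A founder panel of \code{n_founders} haplotypes is drawn
#' first (per-marker allele frequencies uniform on \code{maf_range}); each
#' line's genome is then a mosaic of founder haplotypes with geometric
#' block lengths (mean \code{segment_length_mean} markers), which creates
#' local linkage disequilibrium without requiring a genetic map. Lines are
#' fully homozygous, so dosages are 0 or 2 (dosage 1 only appears at the
#' optional residual heterozygosity rate).
#'
#' @param config A \code{\link{sim_config}} object.
#' @return A numeric matrix of class \code{genotype_matrix}
#'   (\code{n_lines} x \code{n_markers}, dimnames = line/marker ids) with
#'   the founder panel attached as attribute \code{"founder_alleles"}.
#' @examples
#' geno <- simulate_magic_genotypes(sim_config(n_lines = 20, n_markers = 200,
#'                                             seed = 7))
#' dim(geno)
#' @export
simulate_magic_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  m <- config$n_markers
  nf <- config$n_founders

  p <- runif(m, config$maf_range[1], config$maf_range[2])
  founders <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nrow = nf)

  dos <- matrix(0, n, m)
  for (i in seq_len(n)) {
    # founder mosaic: geometric block lengths, uniform founder per block
    pos <- 1L
    while (pos <= m) {
      len <- rgeom(1L, 1 / config$segment_length_mean) + 1L
      end <- min(m, pos + len - 1L)
      f <- sample.int(nf, 1L)
      dos[i, pos:end] <- 2L * founders[f, pos:end]
      pos <- end + 1L
    }
  }
  if (config$het_rate > 0) {
    het <- matrix(runif(n * m) < config$het_rate, n, m)
    dos[het] <- 1L
  }
  dimnames(dos) <- list(sprintf("L%03d", seq_len(n)),
                        sprintf("M%05d", seq_len(m)))
  structure(dos, founder_alleles = founders, class = c("genotype_matrix", "matrix"))
}

#' Coerce a numeric matrix to a genotype matrix
#'
#' Validates dosage range and id uniqueness; missing dimnames get default
#' line/marker ids.
#'
#' @param x Numeric matrix, lines x markers, dosages in [0, 2] or NA.
#' @return A \code{genotype_matrix}.
#' @export
as_genotype_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_arg("genotypes must be a numeric matrix")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("L%03d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("M%05d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop_arg("duplicate line ids")
  if (anyDuplicated(colnames(x))) stop_arg("duplicate marker ids")
  rng <- range(x, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_arg("dosages must lie in [0, 2] (or be missing)")
  class(x) <- c("genotype_matrix", "matrix")
  x
}
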