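# Genomic relationship kernels: marker filtering/imputation, the VanRaden
# G matrix, its Hadamard-square epistatic counterpart, and spectral
# decomposition used by the orthogonalized Gibbs updates.

new_kernel <- function(label, matrix, line_ids) {
  dimnames(matrix) <- list(line_ids, line_ids)
  structure(list(label = label, matrix = matrix, line_ids = line_ids,
                 values = NULL, vectors = NULL, n_clipped = 0L),
            class = "gp_kernel")
}

#' @export
print.gp_kernel <- function(x, ...) {
  cat("gp_kernel '", x$label, "': ", length(x$line_ids), " lines",
      if (!is.null(x$values)) sprintf(", rank %d", sum(x$values > 0)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Filter markers and impute missing dosages
#'
#' Removes monomorphic markers, markers whose missing rate exceeds
#' \code{max_missing_rate}, and markers with minor allele frequency below
#' \code{min_maf} (frequencies computed on non-missing calls); remaining
#' missing dosages are imputed with the marker mean. A count of removed
#' markers and imputed cells is attached as attribute
#' \code{"filter_report"}.
#'
#' @param geno A \code{genotype_matrix} (dosages 0/1/2, NA allowed).
#' @param max_missing_rate Maximum tolerated per-marker missing rate.
#' @param min_maf Minimum minor allele frequency to retain a marker.
#' @return Filtered, fully imputed \code{genotype_matrix}.
#' @export
filter_and_impute <- function(geno, max_missing_rate = 0.1, min_maf = 0) {
  if (max_missing_rate < 0 || max_missing_rate > 1 || min_maf < 0 || min_maf > 0.5)
    stop_arg("rates must lie in [0,1] (min_maf in [0,0.5])")
  x <- unclass(geno)
  miss_rate <- colMeans(is.na(x))
  p <- colMeans(x, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  mono <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j][!is.na(x[, j])]
    length(unique(v)) <= 1L
  }, logical(1))
  drop_missing <- miss_rate > max_missing_rate
  drop_maf <- !mono & !drop_missing & !is.na(maf) & maf < min_maf
  keep <- !(mono | drop_missing | drop_maf)
  if (!any(keep)) stop_arg("empty genotype: all markers removed by filtering")
  x <- x[, keep, drop = FALSE]
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(x)) > 0)) {
      nas <- is.na(x[, j])
      x[nas, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  out <- as_genotype_matrix(x)
  attr(out, "filter_report") <- list(
    removed_monomorphic = sum(mono),
    removed_missing = sum(drop_missing & !mono),
    removed_maf = sum(drop_maf),
    retained = sum(keep),
    imputed_cells = n_imputed)
  out
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 construction: with per-marker allele frequencies \code{p}
#' estimated from the sample, \code{W = dosages - 2p} and
#' \code{G = W W' / (2 sum p (1 - p))}. G is symmetric positive
#' semidefinite and its entries average ~0 across lines by construction of
#' the centering.
#'
#' @param geno A fully observed \code{genotype_matrix}; run
#'   \code{\link{filter_and_impute}} first if there are missing dosages.
#' @return A \code{gp_kernel} with label \code{"G"}.
#' @examples
#' g2 <- as_genotype_matrix(rbind(L1 = rep(2, 4), L2 = rep(0, 4)))
#' vanraden_g(g2)$matrix   # [[2,-2],[-2,2]]
#' @export
vanraden_g <- function(geno) {
  x <- unclass(geno)
  if (anyNA(x)) stop_arg("missing dosages: run filter_and_impute first")
  p <- colMeans(x) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop_arg("all markers monomorphic: zero VanRaden denominator")
  w <- sweep(x, 2, 2 * p)
  G <- tcrossprod(w) / denom
  G <- (G + t(G)) / 2
  new_kernel("G", G, rownames(x))
}

#' First-order additive-by-additive epistatic kernel
#'
#' The covariance of first-order multiplicative (additive x additive)
#' epistatic effects: the element-wise (Hadamard) square of G. PSD by the
#' Schur product theorem.
#'
#' @param g A \code{gp_kernel} with label \code{"G"}.
#' @return A \code{gp_kernel} with label \code{"GxG"}.
#' @export
epistatic_kernel <- function(g) {
  stopifnot(inherits(g, "gp_kernel"))
  if (!identical(g$label, "G"))
    stop_arg("epistatic_kernel expects the kernel labelled 'G'")
  new_kernel("GxG", g$matrix * g$matrix, g$line_ids)
}

#' Identity (iid line) kernel
#'
#' @param line_ids Character vector of line identifiers.
#' @return A \code{gp_kernel} with label \code{"identity"}.
#' @export
identity_kernel <- function(line_ids) {
  new_kernel("identity", diag(length(line_ids)), line_ids)
}

#' Spectral decomposition of a kernel
#'
#' Populates the eigenvalue/eigenvector fields. Eigenvalues below 1e-10
#' are clipped to zero (count recorded in \code{n_clipped}); the clipped
#' spectrum backs the orthogonalized samplers in the model-fitting
#' functions.
#'
#' @param k A \code{gp_kernel}.
#' @return The kernel with \code{values} (nonincreasing) and
#'   \code{vectors} (orthonormal columns) filled in.
#' @export
eigendecompose <- function(k) {
  stopifnot(inherits(k, "gp_kernel"))
  if (!is.null(k$values)) return(k)
  m <- k$matrix
  if (max(abs(m - t(m))) > 1e-8) stop_arg("kernel matrix is not symmetric")
  e <- eigen(m, symmetric = TRUE)
  clip <- e$values < 1e-10
  if (min(e$values) < -1e-8)
    warning("kernel '", k$label, "' has eigenvalue ", min(e$values),
            "; clipping to 0", call. = FALSE)
  e$values[clip] <- 0
  k$values <- e$values
  k$vectors <- e$vectors
  k$n_clipped <- sum(clip)
  k
}

# n_lines x q loading matrix B = V_+ sqrt(Lambda_+) such that u = B d with
# d ~ N(0, s2 I) has covariance s2 K. Zero eigenvalues dropped.
kernel_loadings <- function(k) {
  k <- eigendecompose(k)
  pos <- k$values > 0
  k$vectors[, pos, drop = FALSE] %*% diag(sqrt(k$values[pos]),
                                          nrow = sum(pos))
}

# Moore-Penrose action K^+ x computed in the eigenbasis.
kernel_pinv_mult <- function(k, x) {
  k <- eigendecompose(k)
  pos <- k$values > 0
  V <- k$vectors[, pos, drop = FALSE]
  V %*% ((crossprod(V, x)) / k$values[pos])
}

# Restrict a kernel to a subset of lines (eigen recomputed lazily).
kernel_subset <- function(k, ids) {
  idx <- match(ids, k$line_ids)
  if (anyNA(idx)) stop_arg("kernel does not cover all requested lines")
  new_kernel(k$label, k$matrix[idx, idx, drop = FALSE], ids)
}
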