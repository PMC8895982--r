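# Descriptive statistics, Pearson and polyserial trait correlations, and
# GGE biplot scores for multi-environment yield.

#' Descriptive statistics of a trait vector
#'
#' @param v Numeric vector (NAs dropped).
#' @return data.frame with min, max, mean, median and sample SD (n - 1).
#' @export
descriptive_stats <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) stop_arg("empty trait vector")
  data.frame(n = length(v), min = min(v), max = max(v), mean = mean(v),
             median = median(v), sd = if (length(v) > 1) sd(v) else 0)
}

#' Pearson correlation between two continuous traits
#'
#' Pairwise-complete alignment, two-sided t-based p-value.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{r}, \code{p_value}, \code{n} (complete pairs).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) stop_arg("need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop_arg("constant input")
  ct <- cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Polyserial correlation between a continuous and an ordinal trait
#'
#' Two-step estimator: thresholds of the latent normal underlying the
#' ordinal variable are fixed at the inverse-normal cumulative category
#' proportions; the latent correlation rho is then found by maximizing
#' the bivariate-normal likelihood of (standardized x, latent y) by
#' one-dimensional optimization on (-1, 1). The p-value is a
#' likelihood-ratio test against rho = 0.
#'
#' @param x Continuous vector.
#' @param y Ordinal vector (integer category labels), same length.
#' @return List with \code{rho}, \code{p_value}, \code{n}.
#' @export
polyserial_r <- function(x, y) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop_arg("need at least 10 complete pairs")
  labels <- sort(unique(y))
  if (length(labels) < 2) stop_arg("degenerate category structure")
  if (sd(x) == 0) stop_arg("constant continuous input")
  z <- (x - mean(x)) / sd(x)
  ci <- match(y, labels)
  n <- length(z)
  cum <- cumsum(tabulate(ci, length(labels)))[-length(labels)] / n
  tau <- c(-Inf, qnorm(cum), Inf)

  negll <- function(rho) {
    s <- sqrt(1 - rho^2)
    up <- pnorm((tau[ci + 1L] - rho * z) / s)
    lo <- pnorm((tau[ci] - rho * z) / s)
    -sum(log(pmax(up - lo, 1e-300)))
  }
  opt <- optimize(negll, c(-0.999, 0.999))
  rho <- opt$minimum
  lrt <- 2 * (negll(0) - opt$objective)
  list(rho = rho, p_value = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
       n = n)
}

#' GGE biplot scores from line-by-environment adjusted means
#'
#' Environment-centered singular value decomposition with symmetric
#' scaling: singular values are split equally between line (genotype) and
#' environment scores. The first two components are returned together
#' with the proportion of variance each explains.
#'
#' @param gy Numeric matrix, lines x environments (dimnames used if set).
#' @param n_components Number of components to return (default 2).
#' @return List with \code{line_scores}, \code{env_scores} (each with
#'   \code{n_components} columns) and \code{var_explained} (full spectrum,
#'   proportions summing to 1).
#' @export
gge_scores <- function(gy, n_components = 2) {
  gy <- as.matrix(gy)
  if (ncol(gy) < 2) stop_arg("need at least 2 environments")
  if (anyNA(gy)) stop_arg("adjusted-means matrix must be complete")
  centered <- sweep(gy, 2, colMeans(gy))
  sv <- svd(centered)
  k <- min(n_components, length(sv$d))
  d_half <- sqrt(sv$d[seq_len(k)])
  line_scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d_half, k)
  env_scores <- sv$v[, seq_len(k), drop = FALSE] %*% diag(d_half, k)
  rownames(line_scores) <- rownames(gy)
  rownames(env_scores) <- colnames(gy)
  colnames(line_scores) <- colnames(env_scores) <-
    paste0("PC", seq_len(k))
  var_explained <- sv$d^2 / sum(sv$d^2)
  list(line_scores = line_scores, env_scores = env_scores,
       var_explained = var_explained)
}
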