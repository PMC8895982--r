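# Prediction of unphenotyped lines by kernel regression: for each fitted
# random term, predicted effect = K_new,train K_train,train^+ u_hat, with
# the pseudo-inverse action precomputed at fit time (fit$alpha).

#' Predict new lines from a fitted GP model
#'
#' For every random term present in \code{kernel_rows}, the predicted
#' effect of a new line is its kernel cross-relationship row times the
#' training-kernel regression coefficients. Terms omitted from
#' \code{kernel_rows} contribute 0 — in particular the iid line effect
#' \code{L} of a genuinely unseen line. Fixed effects enter through
#' \code{replicate} (a level of the fit's design; default: the average
#' fixed effect).
#'
#' @param fit A \code{gp_fit}.
#' @param kernel_rows Named list (names among the fit's terms: \code{L},
#'   \code{g}, \code{gA}) of matrices, each n_new x n_train with columns
#'   ordered (or named) like \code{fit$lines}.
#' @param replicate Optional replicate level for the fixed-effect part.
#' @return List with \code{pred} (linear predictor per new line; liability
#'   scale for ordinal fits) and, for ordinal fits, \code{probs} (category
#'   probabilities from Phi-differences at the posterior-mean thresholds)
#'   and \code{categories}.
#' @export
predict_new_lines <- function(fit, kernel_rows, replicate = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  bad <- setdiff(names(kernel_rows), names(fit$alpha))
  if (length(bad))
    stop_arg("kernel_rows for terms not in the fit: ", paste(bad, collapse = ", "))
  n_train <- length(fit$lines)
  n_new <- nrow(kernel_rows[[1]] %||% matrix(0, 1, n_train))
  pred <- rep(0, n_new)
  for (t in names(kernel_rows)) {
    K <- as.matrix(kernel_rows[[t]])
    if (ncol(K) != n_train)
      stop_arg("kernel rows for '", t, "' do not match the fit's line set")
    if (!is.null(colnames(K)) && !identical(colnames(K), fit$lines))
      K <- K[, fit$lines, drop = FALSE]
    pred <- pred + as.numeric(K %*% fit$alpha[[t]])
  }
  beta_part <- if (is.null(replicate)) mean(fit$beta$mean) else {
    i <- match(as.character(replicate), fit$beta$level)
    if (is.na(i)) mean(fit$beta$mean) else fit$beta$mean[i]
  }
  eta <- pred + beta_part
  out <- list(pred = eta)
  if (fit$family == "ordinal") {
    gm <- fit$gamma$mean
    cum <- pnorm(matrix(gm, n_new, length(gm), byrow = TRUE) - eta)
    probs <- cbind(cum, 1) - cbind(0, cum)
    colnames(probs) <- as.character(fit$categories)
    out$probs <- probs
    out$categories <- fit$categories
  }
  out
}

# Posterior-mean linear predictor of a line already inside a fit (used by
# the bounds-retaining cross-validation route and observation-level LOO).
fitted_eta_for_line <- function(fit, line, replicate = NULL) {
  i <- match(line, fit$lines)
  if (is.na(i)) return(NULL)
  eff <- 0
  for (t in names(fit$effects)) eff <- eff + fit$effects[[t]]$mean[i]
  beta_part <- if (is.null(replicate)) mean(fit$beta$mean) else {
    j <- match(as.character(replicate), fit$beta$level)
    if (is.na(j)) mean(fit$beta$mean) else fit$beta$mean[j]
  }
  eff + beta_part
}
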