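# Cross-validation and its scores: Brier score, proportion of cases
# correctly classified (PCCC), Pearson predictive ability, and the
# variance-component report table.

check_probs <- function(probs, observed) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs)))
    stop_arg("probability columns must be named with the category labels")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_arg("probability rows must sum to 1")
  idx <- match(as.character(observed), colnames(probs))
  if (anyNA(idx))
    stop_arg("observed categories outside the probability support")
  list(probs = probs, idx = idx)
}

#' Brier score for ordinal category predictions
#'
#' Mean squared distance between the predicted category probabilities and
#' the one-hot observed categories, halved so the score ranges from 0
#' (perfect, probability 1 on the right category everywhere) to 1
#' (probability 1 on a wrong category everywhere). Lower is better.
#'
#' @param probs n x C matrix of predicted probabilities, columns named by
#'   category label; rows must sum to 1 (tolerance 1e-6).
#' @param observed Vector of n observed category labels.
#' @return The Brier score in [0, 1].
#' @examples
#' p <- matrix(1/7, 3, 7, dimnames = list(NULL, 2:8))
#' brier_score(p, c(2, 5, 8))   # 3/7
#' @export
brier_score <- function(probs, observed) {
  cp <- check_probs(probs, observed)
  d <- matrix(0, nrow(cp$probs), ncol(cp$probs))
  d[cbind(seq_along(cp$idx), cp$idx)] <- 1
  mean(rowSums((cp$probs - d)^2)) / 2
}

#' Proportion of cases correctly classified
#'
#' Fraction of observations whose modal predicted category equals the
#' observed one. Ties between modal categories are broken toward the
#' lower category label.
#'
#' @inheritParams brier_score
#' @return PCCC in [0, 1].
#' @export
pccc <- function(probs, observed) {
  cp <- check_probs(probs, observed)
  modal <- apply(cp$probs, 1, which.max)   # first max = lower label
  mean(modal == cp$idx)
}

#' Pearson predictive ability
#'
#' Sample Pearson correlation between predicted and observed values — the
#' cross-validation score used for continuous and count traits.
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @return Correlation coefficient.
#' @export
predictive_ability_r <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3)
    stop_arg("need equal-length vectors with at least 3 values")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop_arg("undefined correlation: constant vector")
  cor(predicted, observed)
}

#' Leave-one-out cross-validation of a GP model
#'
#' Refits the model with one unit held out per fold and predicts that
#' unit. In \code{unit = "line"} mode all of a line's records are removed
#' and the line is predicted through its kernel cross-relationships
#' (\code{\link{predict_new_lines}}; iid line effects predict as 0). In
#' \code{unit = "observation"} mode a single record is removed, so the
#' line's remaining replicates keep informing its effects. For censored
#' traits, \code{retain_bounds = TRUE} keeps the held-out record in the
#' training set as an interval with unknown point value — the
#' missing-value-with-bounds convention, which leaks the record's location
#' through its censoring interval and is therefore reported explicitly.
#'
#' @param data Observations in the format of the corresponding
#'   \code{fit_*} function (\code{family}).
#' @param spec A \code{\link{predictor_spec}}.
#' @param family One of \code{"gaussian"}, \code{"censored"},
#'   \code{"ordinal"}, \code{"lognormal"}.
#' @param kernels List with \code{G}/\code{GxG} kernels over all lines.
#' @param settings MCMC settings; the default is deliberately shorter than
#'   the full-fit default since one chain runs per fold.
#' @param unit \code{"auto"} (observation mode for replicated data, line
#'   mode otherwise), \code{"observation"}, or \code{"line"}.
#' @param retain_bounds Censored family only: keep held-out records as
#'   bounds-only training records (see above).
#' @return A \code{cv_result}: per-fold predictions plus the applicable
#'   aggregate scores (\code{brier}, \code{pccc} for ordinal;
#'   \code{predictive_ability} otherwise).
#' @export
loo_cross_validate <- function(data, spec, family, kernels = NULL,
                               settings = mcmc_settings(n_iter = 6000,
                                                        burn_in = 1000),
                               unit = c("auto", "observation", "line"),
                               retain_bounds = FALSE) {
  family <- match.arg(family, c("gaussian", "censored", "ordinal", "lognormal"))
  unit <- match.arg(unit)
  value_col <- switch(family, gaussian = "value", censored = "y",
                      ordinal = "category", lognormal = "count")
  if (is.numeric(data)) data <- normalize_long(data, value_col)
  if (is.null(data$replicate)) data$replicate <- 1L
  replicated <- anyDuplicated(data$line) > 0
  if (unit == "auto") unit <- if (replicated) "observation" else "line"
  if (retain_bounds && family != "censored")
    stop_arg("retain_bounds applies to the censored family only")

  fit_fun <- switch(family,
                    gaussian = fit_gaussian, censored = fit_censored,
                    ordinal = fit_ordinal_threshold,
                    lognormal = fit_lognormal_count)
  lines_all <- unique(data$line)
  if (unit == "line" && length(lines_all) < 3)
    stop_arg("line-level LOO needs at least 3 lines")
  if (unit == "observation" && nrow(data) < 3)
    stop_arg("observation-level LOO needs at least 3 records")

  fold_settings <- function(k) {
    s <- settings
    if (!is.null(s$seed)) s$seed <- s$seed + k
    s$keep_draws <- FALSE
    s
  }
  cross_rows <- function(fit, line) {
    kr <- list()
    if (spec$markers)
      kr$g <- kernels$G$matrix[line, fit$lines, drop = FALSE]
    if (spec$epistasis)
      kr$gA <- kernels$GxG$matrix[line, fit$lines, drop = FALSE]
    kr
  }
  predict_unit <- function(fit, rows) {
    # rows: the held-out records (data.frame); returns per-record linear
    # predictors (and probs for ordinal)
    line <- rows$line[1]
    in_fit <- line %in% fit$lines
    eta <- vapply(seq_len(nrow(rows)), function(j) {
      rl <- rows$replicate[j]
      if (in_fit) fitted_eta_for_line(fit, line, rl)
      else {
        kr <- cross_rows(fit, line)
        if (!length(kr)) {
          # no genomic term: unseen line predicts at the fixed-effect level
          i <- match(as.character(rl), fit$beta$level)
          if (is.na(i)) mean(fit$beta$mean) else fit$beta$mean[i]
        } else predict_new_lines(fit, kr, replicate = rl)$pred
      }
    }, numeric(1))
    out <- list(eta = eta)
    if (family == "ordinal") {
      gm <- fit$gamma$mean
      cum <- pnorm(matrix(gm, length(eta), length(gm), byrow = TRUE) - eta)
      probs <- cbind(cum, 1) - cbind(0, cum)
      colnames(probs) <- as.character(fit$categories)
      out$probs <- probs
    }
    out
  }

  folds <- if (unit == "line") lines_all else seq_len(nrow(data))
  per_fold <- vector("list", length(folds))
  prob_list <- list()
  obs_cat <- list()
  all_labels <- if (family == "ordinal") {
    lb <- sort(unique(data$category))
    if (is.numeric(lb)) seq(min(lb), max(lb)) else lb
  } else NULL

  for (k in seq_along(folds)) {
    if (unit == "line") {
      hold <- data$line == folds[k]
    } else {
      hold <- seq_len(nrow(data)) == folds[k]
    }
    test <- data[hold, , drop = FALSE]
    if (retain_bounds) {
      train <- data
      train$y[hold] <- NA_real_       # bounds kept, point value hidden
    } else {
      train <- data[!hold, , drop = FALSE]
    }
    fit <- suppressWarnings(fit_fun(train, spec, kernels, fold_settings(k)))
    pr <- predict_unit(fit, test)
    if (family == "ordinal") {
      # pad probability columns to the global label set
      probs <- matrix(0, nrow(pr$probs), length(all_labels),
                      dimnames = list(NULL, as.character(all_labels)))
      probs[, colnames(pr$probs)] <- pr$probs
      probs <- probs / rowSums(probs)
      prob_list[[k]] <- probs
      obs_cat[[k]] <- test$category
      pred_val <- as.numeric(all_labels[apply(probs, 1, which.max)])
    } else {
      pred_val <- pr$eta
    }
    obs_val <- switch(family,
                      gaussian = test$value, censored = test$y,
                      ordinal = test$category,
                      lognormal = log(test$count + 1))
    per_fold[[k]] <- data.frame(fold = k, line = test$line,
                                replicate = test$replicate,
                                predicted = if (family == "ordinal") pred_val
                                            else pr$eta,
                                observed = obs_val,
                                stringsAsFactors = FALSE)
  }

  per_fold <- do.call(rbind, per_fold)
  res <- list(per_fold = per_fold, family = family, unit = unit,
              retain_bounds = retain_bounds, n_folds = length(folds))
  if (family == "ordinal") {
    probs <- do.call(rbind, prob_list)
    observed <- unlist(obs_cat)
    res$probs <- probs
    res$brier <- brier_score(probs, observed)
    res$pccc <- pccc(probs, observed)
  } else {
    res$predictive_ability <- predictive_ability_r(per_fold$predicted,
                                                   per_fold$observed)
  }
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result: leave-one-out,", x$n_folds, "folds, unit =", x$unit,
      if (x$retain_bounds) "(bounds retained)" else "", "\n")
  if (!is.null(x$brier))
    cat("  Brier score:", round(x$brier, 4), " PCCC:", round(x$pccc, 4), "\n")
  if (!is.null(x$predictive_ability))
    cat("  predictive ability r:", round(x$predictive_ability, 4), "\n")
  invisible(x)
}

#' Variance-component report table
#'
#' Per model: the posterior mean of each variance component and its
#' percentage of the summed total (residual included).
#'
#' @param fits Named list of \code{gp_fit} objects.
#' @return data.frame: model, component, estimate, percent, total.
#' @export
variance_component_table <- function(fits) {
  if (inherits(fits, "gp_fit")) fits <- list(model = fits)
  out <- lapply(names(fits), function(nm) {
    v <- fits[[nm]]$variances
    tot <- sum(v$mean)
    data.frame(model = nm, component = v$component, estimate = v$mean,
               percent = 100 * v$mean / tot, total = tot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
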