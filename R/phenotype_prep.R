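# Trait pre-processing: BLUE adjusted means for replicated designs and
# linear/segmented regression of transpiration rate on vapor pressure
# deficit, with R-squared based model selection.

#' Adjusted means (BLUEs) from a replicated design
#'
#' Fits the two-way fixed-effects model \code{value = line + replicate +
#' error} by least squares with a sum-to-zero constraint on replicate
#' effects, so each line's BLUE is its estimate at the mean replicate
#' level. Standard errors come from the fitted residual variance; 95%
#' confidence limits use the t distribution on the residual degrees of
#' freedom.
#'
#' @param raw data.frame with columns \code{line}, \code{replicate},
#'   \code{value}; no duplicated (line, replicate) pairs.
#' @return data.frame of class \code{adjusted_means} with columns
#'   \code{line}, \code{blue}, \code{se}, \code{ci_low}, \code{ci_high}
#'   and logical \code{estimable} (FALSE rows are flagged, not dropped).
#' @export
compute_blues <- function(raw) {
  need <- c("line", "replicate", "value")
  if (!all(need %in% names(raw)))
    stop_arg("raw trait table needs columns line, replicate, value")
  if (anyDuplicated(raw[c("line", "replicate")]))
    stop_arg("duplicated (line, replicate) pairs")
  if (!all(is.finite(raw$value))) stop_arg("trait values must be finite")
  line <- factor(raw$line)
  if (nlevels(line) < 2) stop_arg("need at least 2 lines")
  repl <- factor(raw$replicate)
  if (nlevels(repl) > 1) {
    fit <- lm(raw$value ~ 0 + line + repl,
              contrasts = list(repl = "contr.sum"))
  } else {
    fit <- lm(raw$value ~ 0 + line)
  }
  cf <- coef(fit)
  line_coef <- cf[paste0("line", levels(line))]
  estimable <- !is.na(line_coef)
  if (any(!estimable))
    warning(sum(!estimable), " line mean(s) inestimable in this design",
            call. = FALSE)
  vc <- diag(vcov(fit))
  se <- rep(NA_real_, nlevels(line))
  se[estimable] <- sqrt(vc[paste0("line", levels(line)[estimable])])
  df <- fit$df.residual
  tq <- if (df > 0) qt(0.975, df) else NA_real_
  out <- data.frame(line = levels(line),
                    blue = unname(line_coef),
                    se = se,
                    ci_low = unname(line_coef) - tq * se,
                    ci_high = unname(line_coef) + tq * se,
                    estimable = estimable,
                    stringsAsFactors = FALSE)
  class(out) <- c("adjusted_means", "data.frame")
  out
}

check_tr_curve <- function(curve, min_points) {
  if (!all(c("vpd", "tr") %in% names(curve)))
    stop_arg("a TR curve needs columns vpd and tr")
  if (nrow(curve) < min_points)
    stop_arg("need at least ", min_points, " points")
  if (any(diff(curve$vpd) <= 0)) stop_arg("vpd must be strictly increasing")
  curve
}

new_tr_fit <- function(kind, coefs, r2, sse, vpd_range, line_id = NA_character_) {
  structure(list(kind = kind,
                 intercept = unname(coefs[["intercept"]]),
                 slope1 = unname(coefs[["slope1"]]),
                 slope2 = unname(coefs[["slope2"]] %||% NA_real_),
                 breakpoint = unname(coefs[["breakpoint"]] %||% NA_real_),
                 r_squared = r2, sse = sse,
                 vpd_range = vpd_range, line_id = line_id),
            class = "tr_fit")
}

#' @export
print.tr_fit <- function(x, ...) {
  cat("tr_fit:", x$kind, "- intercept", signif(x$intercept, 4),
      "slope1", signif(x$slope1, 4))
  if (x$kind == "segmented")
    cat(" slope2", signif(x$slope2, 4), "breakpoint", signif(x$breakpoint, 4))
  cat(" R2", signif(x$r_squared, 4), "\n")
  invisible(x)
}

# R-squared defined as 0 when the total sum of squares is 0 (constant
# response), avoiding 0/0.
r2_from_sse <- function(sse, tss) if (tss <= 0) 0 else max(0, 1 - sse / tss)

#' Linear TR-vs-VPD regression
#'
#' Ordinary least squares of transpiration rate on vapor pressure deficit.
#'
#' @param curve data.frame with strictly increasing \code{vpd} and
#'   \code{tr}; at least 3 points.
#' @return A \code{tr_fit} with kind \code{"linear"}.
#' @export
fit_tr_linear <- function(curve) {
  check_tr_curve(curve, 3L)
  X <- cbind(1, curve$vpd)
  f <- stats::lm.fit(X, curve$tr)
  sse <- sum(f$residuals^2)
  tss <- sum((curve$tr - mean(curve$tr))^2)
  new_tr_fit("linear",
             list(intercept = f$coefficients[1], slope1 = f$coefficients[2]),
             r2_from_sse(sse, tss), sse, range(curve$vpd),
             curve$line[1] %||% NA_character_)
}

#' Segmented (two-phase) TR-vs-VPD regression
#'
#' Continuous two-segment model \code{tr = b0 + b1 min(vpd, bp) +
#' b2 max(0, vpd - bp)}. The breakpoint is found by grid search over the
#' interior of the VPD range (step \code{grid_step} kPa) minimizing the
#' error sum of squares, with segment coefficients estimated by OLS at
#' each candidate breakpoint.
#'
#' @param curve data.frame with \code{vpd}, \code{tr}; at least 5 points.
#' @param grid_step Breakpoint grid resolution in kPa.
#' @return A \code{tr_fit} with kind \code{"segmented"}.
#' @export
fit_tr_segmented <- function(curve, grid_step = 0.01) {
  check_tr_curve(curve, 5L)
  v <- curve$vpd
  n <- length(v)
  lo <- v[2]
  hi <- v[n - 1L]
  if (hi <= lo) stop_arg("too few interior points for a breakpoint grid")
  grid <- seq(lo, hi, by = grid_step)
  best <- NULL
  best_sse <- Inf
  for (bp in grid) {
    X <- cbind(1, pmin(v, bp), pmax(0, v - bp))
    f <- tryCatch(stats::lm.fit(X, curve$tr), error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients)) next
    sse <- sum(f$residuals^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- list(bp = bp, coef = f$coefficients)
    }
  }
  if (is.null(best)) stop_arg("segmented fit failed on every grid point")
  tss <- sum((curve$tr - mean(curve$tr))^2)
  new_tr_fit("segmented",
             list(intercept = best$coef[1], slope1 = best$coef[2],
                  slope2 = best$coef[3], breakpoint = best$bp),
             r2_from_sse(best_sse, tss), best_sse, range(v),
             curve$line[1] %||% NA_character_)
}

#' Choose between the linear and segmented TR fits
#'
#' Returns the segmented fit iff its R-squared exceeds the linear one by
#' more than \code{min_gain} and its breakpoint lies strictly inside the
#' fitted VPD range; otherwise the linear fit. A gain threshold is needed
#' because the segmented model nests the linear one, so plain R-squared
#' never prefers the smaller model.
#'
#' @param linear,segmented \code{tr_fit} objects for the same curve.
#' @param min_gain Minimum R-squared improvement (default 0.01).
#' @return The selected \code{tr_fit}.
#' @export
select_tr_model <- function(linear, segmented, min_gain = 0.01) {
  stopifnot(inherits(linear, "tr_fit"), inherits(segmented, "tr_fit"))
  gain <- segmented$r_squared - linear$r_squared
  interior <- !is.na(segmented$breakpoint) &&
    segmented$breakpoint > segmented$vpd_range[1] &&
    segmented$breakpoint < segmented$vpd_range[2]
  if (gain > min_gain && interior) segmented else linear
}

#' Evaluate a fitted TR response at a given VPD
#'
#' @param fit A \code{tr_fit}.
#' @param vpd VPD value in kPa; values outside the fitted grid trigger an
#'   extrapolation warning but are still evaluated.
#' @return Fitted TR value.
#' @examples
#' f <- fit_tr_linear(data.frame(vpd = 1:5, tr = 1 + 2 * (1:5)))
#' tr_at_vpd(f, 2.7)   # 6.4
#' @export
tr_at_vpd <- function(fit, vpd) {
  stopifnot(inherits(fit, "tr_fit"))
  if (any(vpd < fit$vpd_range[1] | vpd > fit$vpd_range[2]))
    warning("extrapolating outside the fitted VPD range", call. = FALSE)
  if (fit$kind == "linear") {
    fit$intercept + fit$slope1 * vpd
  } else {
    fit$intercept + fit$slope1 * pmin(vpd, fit$breakpoint) +
      fit$slope2 * pmax(0, vpd - fit$breakpoint)
  }
}

#' Fit and select TR response models for a set of curves
#'
#' Convenience wrapper running \code{\link{fit_tr_linear}},
#' \code{\link{fit_tr_segmented}} and \code{\link{select_tr_model}} per
#' line and evaluating the selected model at a target VPD.
#'
#' @param curves data.frame with columns \code{line}, \code{vpd}, \code{tr}.
#' @param at_vpd VPD (kPa) at which the selected fit is evaluated.
#' @param grid_step,min_gain Passed to the fitting/selection functions.
#' @return data.frame: line, kind, intercept, slope1, slope2, breakpoint,
#'   r_squared, tr_at (value at \code{at_vpd}).
#' @export
prepare_tr_values <- function(curves, at_vpd = 2.7, grid_step = 0.01,
                              min_gain = 0.01) {
  stopifnot(all(c("line", "vpd", "tr") %in% names(curves)))
  out <- lapply(split(curves, curves$line), function(cv) {
    cv <- cv[order(cv$vpd), ]
    lin <- fit_tr_linear(cv)
    seg <- fit_tr_segmented(cv, grid_step)
    sel <- select_tr_model(lin, seg, min_gain)
    data.frame(line = cv$line[1], kind = sel$kind,
               intercept = sel$intercept, slope1 = sel$slope1,
               slope2 = sel$slope2, breakpoint = sel$breakpoint,
               r_squared = sel$r_squared,
               tr_at = tr_at_vpd(sel, at_vpd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
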