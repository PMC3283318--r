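#' Ordinary least squares fit of log10 5'UTR length on features
#'
#' Fits `response ~ predictors` (intercept always included) by QR-based least
#' squares through [stats::lm()]. Rank-deficient designs are rejected with an
#' error naming the collinear columns rather than silently dropping them.
#'
#' @param table A `feature_table` or plain data frame.
#' @param predictors Character vector of predictor column names; may be empty
#'   for the intercept-only model.
#' @param response Response column name (default `"log10_length"`).
#' @return A `utr_ols` object: coefficient table (estimate, standard error,
#'   t statistic, two-sided p value), `r2`, `adj_r2`, residuals, fitted
#'   values, `n_obs`, `df_residual`, and the predictor/response names.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 3, 5, 7, 9), x = 0:4)
#' fit_ols(d, "x", "y")  # y = 2x + 1 exactly
fit_ols <- function(table, predictors, response = "log10_length") {
  stopifnot(is.data.frame(table), is.character(response),
            length(response) == 1L)
  predictors <- as.character(predictors)
  missing_cols <- setdiff(c(response, predictors), names(table))
  if (length(missing_cols)) {
    stop("columns not found in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- as.data.frame(table)[, c(response, predictors), drop = FALSE]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1L) {
    stop(sprintf("need more observations (%d) than predictors + 1 (%d)",
                 n, p + 1L), call. = FALSE)
  }
  fml <- reformulate(if (p) predictors else "1", response = response)
  fit <- lm(fml, data = d)
  if (fit$rank < p + 1L) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(cf),
                              estimate = cf[, 1L],
                              std_error = cf[, 2L],
                              t_value = cf[, 3L],
                              p_value = cf[, 4L],
                              row.names = NULL,
                              stringsAsFactors = FALSE),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    residuals = unname(residuals(fit)),
    fitted = unname(fit$fitted.values),
    n_obs = n,
    df_residual = fit$df.residual,
    predictors = predictors,
    response = response
  ), class = "utr_ols")
}

#' @export
print.utr_ols <- function(x, digits = 4L, ...) {
  cat(sprintf("OLS fit: %s ~ %s  (n = %d)\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n_obs))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n", x$r2, x$adj_r2))
  invisible(x)
}

# p values of the non-intercept terms of a utr_ols fit, named by term
.predictor_pvalues <- function(fit) {
  cf <- fit$coefficients
  keep <- cf$term != "(Intercept)"
  setNames(cf$p_value[keep], cf$term[keep])
}

#' Backward elimination of non-significant predictors
#'
#' Starting from the full candidate model, repeatedly refits after removing
#' the single predictor with the largest t-test p value, as long as that p
#' value exceeds `alpha`. The intercept is never removed. Every removal is
#' recorded in a selection trace (predictor removed, its p value at removal,
#' and the model R-squared after removal).
#'
#' @inheritParams fit_ols
#' @param candidates Character vector of candidate predictor columns.
#' @param alpha Significance threshold for retention (default 0.05).
#' @return List with elements `fit` (the final `utr_ols`, possibly
#'   intercept-only) and `trace` (a `selection_trace` with `steps`,
#'   `final_predictors` and `alpha`).
#' @export
backward_select <- function(table, candidates, response = "log10_length",
                            alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  preds <- as.character(candidates)
  fit <- fit_ols(table, preds, response)
  steps <- list()
  repeat {
    pv <- .predictor_pvalues(fit)
    if (!length(pv) || max(pv) <= alpha) break
    worst <- names(pv)[which.max(pv)]
    p_at_removal <- unname(max(pv))
    preds <- setdiff(preds, worst)
    fit <- fit_ols(table, preds, response)
    steps[[length(steps) + 1L]] <- data.frame(step = length(steps) + 1L,
                                              removed = worst,
                                              p_value = p_at_removal,
                                              r2_after = fit$r2,
                                              stringsAsFactors = FALSE)
  }
  trace <- structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(), removed = character(),
                 p_value = numeric(), r2_after = numeric()),
    final_predictors = preds,
    alpha = alpha
  ), class = "selection_trace")
  list(fit = fit, trace = trace)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("Backward elimination (alpha = %g): %d predictor(s) removed\n",
              x$alpha, nrow(x$steps)))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE, ...)
  cat("final predictors:",
      if (length(x$final_predictors))
        paste(x$final_predictors, collapse = ", ") else "(intercept only)",
      "\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' For each predictor `j`, `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from
#' regressing predictor `j` on all remaining predictors (with intercept). A
#' VIF above 10 signals collinearity strong enough that the predictor's
#' individual association with the response cannot be interpreted; such
#' predictors are flagged. Perfect collinearity yields `Inf`.
#'
#' @inheritParams fit_ols
#' @param predictors At least two predictor column names.
#' @return Named numeric vector of VIFs with attribute `flagged` (names of
#'   predictors whose VIF exceeds 10).
#' @export
vif <- function(table, predictors) {
  predictors <- as.character(predictors)
  stopifnot(is.data.frame(table), length(predictors) >= 2L,
            all(predictors %in% names(table)))
  d <- as.data.frame(table)[, predictors, drop = FALSE]
  out <- vapply(predictors, function(j) {
    others <- setdiff(predictors, j)
    r2j <- summary(lm(reformulate(others, response = j), data = d))$r.squared
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1L))
  attr(out, "flagged") <- names(out)[out > 10]
  out
}

#' Relative contribution to variability explained (RCVE)
#'
#' For each predictor `j` of the full model, the fractional drop in
#' (unadjusted) R-squared when `j` is removed:
#' `RCVE_j = (R2_full - R2_reduced_j) / R2_full`. Full and reduced models are
#' fit on the same rows, so the difference reflects the predictor alone. A
#' large RCVE marks a feature whose removal costs the model much of its
#' explanatory power. Using adjusted R-squared instead is available for
#' sensitivity analysis, in which case individual RCVE values can be
#' negative.
#'
#' @inheritParams fit_ols
#' @param predictors Predictor columns of the full model.
#' @param r2_type `"unadjusted"` (default) or `"adjusted"`.
#' @return Named numeric vector of RCVE values with attribute `r2_full`.
#' @export
rcve <- function(table, predictors, response = "log10_length",
                 r2_type = c("unadjusted", "adjusted")) {
  r2_type <- match.arg(r2_type)
  predictors <- as.character(predictors)
  stopifnot(length(predictors) >= 1L)
  full <- fit_ols(table, predictors, response)
  r2_of <- function(fit) if (r2_type == "unadjusted") fit$r2 else fit$adj_r2
  r2_full <- r2_of(full)
  if (r2_full <= 0) {
    stop("RCVE undefined: full model explains no variance (R^2 <= 0)",
         call. = FALSE)
  }
  out <- vapply(predictors, function(j) {
    red <- fit_ols(table, setdiff(predictors, j), response)
    if (r2_type == "unadjusted" && red$r2 > full$r2 + 1e-10) {
      stop("nested-model monotonicity violated for predictor ", j,
           call. = FALSE)
    }
    (r2_full - r2_of(red)) / r2_full
  }, numeric(1L))
  attr(out, "r2_full") <- r2_full
  out
}

#' Partial correlation between the response and one predictor
#'
#' The correlation between (a) the residuals of the response regressed on the
#' control predictors and (b) the residuals of the target predictor regressed
#' on the same controls — the association between response and target with
#' the controls' linear effects removed. With no controls it reduces to the
#' plain Pearson correlation. It is algebraically tied to the target's
#' t statistic in the joint model: `t / sqrt(t^2 + df)`.
#'
#' @inheritParams fit_ols
#' @param target Column name of the predictor of interest.
#' @param others Character vector of control predictor columns (possibly
#'   empty).
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_correlation <- function(table, target, others,
                                response = "log10_length") {
  others <- as.character(others)
  stopifnot(is.data.frame(table), is.character(target), length(target) == 1L)
  missing_cols <- setdiff(c(response, target, others), names(table))
  if (length(missing_cols)) {
    stop("columns not found in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- as.data.frame(table)
  rhs <- if (length(others)) others else "1"
  ey <- residuals(lm(reformulate(rhs, response = response), data = d))
  ex <- residuals(lm(reformulate(rhs, response = target), data = d))
  tol_x <- 1e-10 * (sd(d[[target]]) + .Machine$double.xmin)
  tol_y <- 1e-10 * (sd(d[[response]]) + .Machine$double.xmin)
  if (sd(ex) <= tol_x || sd(ey) <= tol_y) {
    stop("degenerate residuals: zero variance after controlling for others",
         call. = FALSE)
  }
  cor(ex, ey)
}

#' Partial correlations for a predictor set
#'
#' Applies [partial_correlation()] to each predictor in turn, controlling for
#' the remaining predictors of the set.
#'
#' @inheritParams fit_ols
#' @param predictors Predictor columns.
#' @return Named numeric vector of partial correlations.
#' @export
partial_correlations <- function(table, predictors,
                                 response = "log10_length") {
  predictors <- as.character(predictors)
  vapply(predictors, function(j) {
    partial_correlation(table, j, setdiff(predictors, j), response)
  }, numeric(1L))
}
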