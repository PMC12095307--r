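#' Stratified train/validation split
#'
#' Splits plots into training and validation sets, stratified by age group,
#' with the per-group training size equal to round-half-up of
#' `train_fraction` times the group size. With the 154-plot design
#' (33/34/26/34/27) and fraction 0.7 this gives per-group training sizes
#' 23/24/18/24/19, i.e. 108 training and 46 validation plots.
#'
#' @param groups Age-group labels, one per plot (character/factor), or a list
#'   of `plot_record`s.
#' @param train_fraction Fraction of each group assigned to training; must be
#'   strictly inside (0, 1).
#' @param seed Integer seed for the random membership.
#' @return An object of class `split_assignment`: list with `assignment`
#'   (factor `train`/`validation`, one per plot) and `counts` (per-group
#'   train/validation table).
#' @export
split_data <- function(groups, train_fraction = 0.7, seed = 1) {
  if (is.list(groups) && length(groups) && inherits(groups[[1]], "plot_record")) {
    groups <- vapply(groups, function(p) p$age_group, character(1))
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  groups <- factor(groups)
  if (any(table(groups) < 2)) {
    stop("need >= 2 plots per group", call. = FALSE)
  }
  set.seed(seed)
  assignment <- factor(rep("validation", length(groups)),
                       levels = c("train", "validation"))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n_train <- floor(train_fraction * length(idx) + 0.5)  # round half up
    assignment[sample(idx, n_train)] <- "train"
  }
  structure(list(assignment = assignment,
                 counts = table(group = groups, set = assignment)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>\n")
  print(x$counts)
  invisible(x)
}

#' Model evaluation statistics
#'
#' The evaluation set comprises: mean bias `e_bar = sum(y - yhat) / n`; bias
#' variance `sigma2 = sum((e - e_bar)^2) / (n - 1)`; the coefficient of
#' determination `R2 = 1 - SSE/SST` (reported as-is, so it can be negative
#' out of sample); total relative error
#' `TRE = 100 * sum((y - yhat)^2) / sum(y^2)`; and the bias-decomposed root
#' mean square error `RMSE = sqrt(e_bar^2 + sigma2)`. AIC (`2k - 2 ln L`) is
#' reported only when a log-likelihood is supplied.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values (same length, >= 2).
#' @param k Number of model parameters (for AIC).
#' @param loglik Optional log-likelihood.
#' @return An object of class `eval_stats`: list with `mean_bias`,
#'   `bias_variance`, `r2`, `tre`, `rmse`, `aic` (or NA), `n`.
#' @export
evaluate_predictions <- function(y_obs, y_pred, k = NULL, loglik = NULL) {
  if (length(y_obs) != length(y_pred)) {
    stop("y_obs and y_pred must have equal length", call. = FALSE)
  }
  n <- length(y_obs)
  if (n < 2) stop("need >= 2 observations", call. = FALSE)
  e <- y_obs - y_pred
  e_bar <- sum(e) / n
  sigma2 <- sum((e - e_bar)^2) / (n - 1)
  structure(list(
    mean_bias = e_bar,
    bias_variance = sigma2,
    r2 = 1 - sum(e^2) / sum((y_obs - mean(y_obs))^2),
    tre = 100 * sum(e^2) / sum(y_obs^2),
    rmse = sqrt(e_bar^2 + sigma2),
    aic = if (!is.null(loglik)) 2 * k - 2 * loglik else NA_real_,
    n = n
  ), class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf(
    "<eval_stats n=%d> bias %.4f, R2 %.3f, RMSE %.3f, TRE %.3f%s\n",
    x$n, x$mean_bias, x$r2, x$rmse, x$tre,
    if (is.na(x$aic)) "" else sprintf(", AIC %.2f", x$aic)))
  invisible(x)
}

#' Observed-versus-predicted validation regression
#'
#' Ordinary least squares of the observed values on the predictions,
#' `y = b + a * yhat`. A slope near 1, intercept near 0 and high R-squared
#' indicate small prediction bias.
#'
#' @param y_obs Observed values (>= 3).
#' @param y_pred Predicted values; must not be constant.
#' @return List with `a` (slope), `b` (intercept), `r2`.
#' @export
validation_regression <- function(y_obs, y_pred) {
  if (length(y_obs) < 3 || length(y_obs) != length(y_pred)) {
    stop("need >= 3 matched pairs", call. = FALSE)
  }
  if (stats::sd(y_pred) == 0) {
    stop("constant predictions: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y_obs ~ y_pred)
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}
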