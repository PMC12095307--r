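#' Enumerate candidate random-effect parameter subsets
#'
#' Every non-empty subset of the model's parameter vector is a candidate
#' random-effect structure. Over the six component models (five 3-parameter
#' forms and the 4-parameter logistic leaf form) this gives
#' 5 x 7 + 15 = 50 candidate mixed-effects structures.
#'
#' @param spec A [base_model_spec()].
#' @return List of character vectors (parameter subsets), ordered by subset
#'   size then lexicographically.
#' @examples
#' length(enumerate_random_effect_combos(base_model_spec("empirical")))
#' @export
enumerate_random_effect_combos <- function(spec) {
  stopifnot(inherits(spec, "base_model_spec"))
  pars <- spec$parameters
  out <- list()
  for (size in seq_along(pars)) {
    combos <- utils::combn(pars, size, simplify = FALSE)
    ord <- order(vapply(combos, paste, character(1), collapse = ","))
    out <- c(out, combos[ord])
  }
  out
}

#' Fit a nonlinear mixed-effects model with age-group random effects
#'
#' The base model's parameter vector gains additive group-level random
#' effects on the parameters in `re_subset`; the random effects are normal
#' with covariance D and the residuals independent normal. Estimation is the
#' Lindstrom--Bates algorithm (alternating penalized nonlinear least squares
#' and a linearization-based variance-component update) via [nlme::nlme()],
#' by maximum likelihood so that AIC values are comparable across random
#' structures and with the base model.
#'
#' D is diagonal: with five groups the random-effect covariance cannot be
#' estimated reliably beyond its variances, and the diagonal structure keeps
#' the optimization stable across all fifty candidate structures.
#'
#' @param spec A [base_model_spec()].
#' @param data Data frame with the predictor columns.
#' @param y Response vector.
#' @param groups Group labels (factor or character), one per row.
#' @param re_subset Character vector: parameters carrying random effects.
#' @param start Optional named fixed-effect starting values; default from the
#'   base fit.
#' @return An object of class `fir_nlme`: list with `beta`, `se`, `vcov`,
#'   `re_subset`, `ranef` (per-group effects), `D`, `sigma2`, `loglik`,
#'   `aic`, `converged`, `reduces_to_fixed_effects` flag, and the underlying
#'   `fit`.
#' @export
fit_nlme <- function(spec, data, y, groups, re_subset, start = NULL) {
  stopifnot(inherits(spec, "base_model_spec"))
  if (!all(re_subset %in% spec$parameters)) {
    stop("re_subset must be a subset of the model parameters", call. = FALSE)
  }
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  if (is.null(start)) {
    start <- fit_base_model(spec, data, y)$coefficients
  }
  df <- cbind(data[spec$predictors], .y = y, .group = groups)
  model_f <- stats::as.formula(paste(".y ~", model_rhs(spec)))
  fixed_f <- stats::as.formula(
    paste(paste(spec$parameters, collapse = " + "), "~ 1"))
  ran_f <- stats::as.formula(paste(paste(re_subset, collapse = " + "), "~ 1"))
  ran <- nlme::pdDiag(ran_f)

  ## build the call with do.call so the formulas are embedded in the fit and
  ## predict() works outside this function's environment
  fit <- do.call(nlme::nlme, list(
    model = model_f,
    fixed = fixed_f,
    random = ran,
    groups = ~.group,
    data = df,
    start = as.numeric(start[spec$parameters]),
    method = "ML",
    control = nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                                returnObject = FALSE)))
  beta <- nlme::fixef(fit)
  vc <- fit$varFix
  D <- as.matrix(fit$modelStruct$reStruct[[1]]) * fit$sigma^2
  re_sd <- sqrt(diag(D))
  collapsed <- all(re_sd < 1e-4 * pmax(abs(beta[re_subset]), 1))
  structure(list(
    spec = spec,
    beta = beta,
    se = sqrt(diag(vc)),
    vcov = vc,
    re_subset = re_subset,
    ranef = nlme::ranef(fit),
    D = D,
    sigma2 = fit$sigma^2,
    loglik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    n_par = length(beta) + 1 + length(re_subset),
    converged = TRUE,
    reduces_to_fixed_effects = collapsed,
    fit = fit
  ), class = "fir_nlme")
}

#' @export
predict.fir_nlme <- function(object, newdata, groups = NULL, ...) {
  level <- if (is.null(groups)) 0 else 1
  nd <- newdata
  if (!is.null(groups)) nd$.group <- factor(groups)
  as.numeric(stats::predict(object$fit, newdata = nd, level = level))
}

#' @export
print.fir_nlme <- function(x, ...) {
  cat(sprintf("<fir_nlme> %s model for %s; random effects on [%s]\n",
              x$spec$form, x$spec$component,
              paste(x$re_subset, collapse = ", ")))
  print(signif(x$beta, 5))
  cat(sprintf("sigma %.3f, logLik %.2f, AIC %.2f%s\n", sqrt(x$sigma2),
              x$loglik, x$aic,
              if (x$reduces_to_fixed_effects) " [reduces to fixed effects]" else ""))
  invisible(x)
}

#' Exhaustive AIC selection over random-effect structures
#'
#' Fits the mixed model for every subset from
#' [enumerate_random_effect_combos()], skips structures whose estimation
#' fails, and returns the minimum-AIC fit together with the full AIC table
#' and the fixed-effects base fit for reference.
#'
#' @inheritParams fit_nlme
#' @return List with `best` (a `fir_nlme`, or `NULL` when degenerate),
#'   `base` (the `base_fit`), `table` (data frame: `subset`, `converged`,
#'   `loglik`, `aic`), and `degenerate` (TRUE when fewer than two groups make
#'   mixed modelling impossible, in which case the base model stands).
#' @export
select_nlme_by_aic <- function(spec, data, y, groups) {
  base <- fit_base_model(spec, data, y)
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    return(list(best = NULL, base = base, table = NULL, degenerate = TRUE))
  }
  combos <- enumerate_random_effect_combos(spec)
  rows <- vector("list", length(combos))
  fits <- vector("list", length(combos))
  for (i in seq_along(combos)) {
    f <- tryCatch(
      fit_nlme(spec, data, y, groups, combos[[i]],
               start = base$coefficients),
      error = function(e) conditionMessage(e))
    if (inherits(f, "fir_nlme")) {
      fits[[i]] <- f
      rows[[i]] <- data.frame(subset = paste(combos[[i]], collapse = "+"),
                              converged = TRUE, loglik = f$loglik, aic = f$aic)
    } else {
      rows[[i]] <- data.frame(subset = paste(combos[[i]], collapse = "+"),
                              converged = FALSE, loglik = NA_real_,
                              aic = NA_real_)
      attr(rows[[i]], "message") <- f
    }
  }
  tab <- do.call(rbind, rows)
  if (!any(tab$converged)) {
    stop("no random-effect structure converged; diagnostics: ",
         paste(unique(vapply(rows, function(r) attr(r, "message") %||% "",
                             character(1))), collapse = " | "), call. = FALSE)
  }
  best <- fits[[which.min(ifelse(tab$converged, tab$aic, Inf))]]
  list(best = best, base = base, table = tab, degenerate = FALSE)
}
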