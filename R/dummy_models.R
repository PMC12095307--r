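#' Dummy-variable model with backward t-test pruning
#'
#' Each base-model parameter p is expanded to
#' `p + delta_p_Q1 Q1 + ... + delta_p_Q4 Q4`, where Q1..Q4 are the age-group
#' indicators of [age_group_dummies()] (over-mature is the all-zero
#' reference). The expanded model is fitted by Levenberg--Marquardt least
#' squares, then the single least-significant dummy term (largest p-value at
#' or above `alpha`) is removed and the model refitted, until every retained
#' dummy term is significant. Indicators for age groups absent from the data
#' are not expanded.
#'
#' @inheritParams fit_nlme
#' @param alpha Significance level of the retention t-test.
#' @return An object of class `dummy_fit`: list with `coefficients` (base
#'   parameters and retained dummy offsets), `t_table` (estimate, t, p per
#'   term), `retained`, `eliminated` (in drop order), `all_pruned` flag (TRUE
#'   when every dummy term was removed, i.e. the model reduces to the base
#'   model), `loglik`, `aic`, and the underlying `fit`.
#' @export
fit_dummy_model <- function(spec, data, y, groups, alpha = 0.05) {
  stopifnot(inherits(spec, "base_model_spec"))
  groups <- as.character(groups)
  Q <- age_group_dummies(groups)
  present <- colnames(Q)[colSums(Q) > 0 & colSums(Q) < nrow(Q)]
  base <- fit_base_model(spec, data, y)

  terms_for <- function(par) paste0(par, "_", present)
  all_terms <- unlist(lapply(spec$parameters, terms_for))

  dummy_data <- cbind(data[spec$predictors], as.data.frame(Q))

  build_fit <- function(active) {
    par_expr <- vapply(spec$parameters, function(p) {
      tt <- intersect(terms_for(p), active)
      if (!length(tt)) return(p)
      qs <- sub(paste0("^", p, "_"), "", tt)
      paste0("(", p, " + ", paste(paste0(tt, " * ", qs), collapse = " + "), ")")
    }, character(1))
    st <- c(as.list(base$coefficients),
            stats::setNames(as.list(rep(0, length(active))), active))
    lower <- upper <- NULL
    if (spec$form == "logistic") {
      ## same box constraints as the base fit on the shared parameters, and
      ## group offsets bounded by the width of their parameter's box
      np <- length(spec$parameters) - 2
      base_lo <- c(0.5 * max(y), 1e-4, rep(-5, np))
      base_hi <- c(3 * max(y), 1e4, rep(5, np))
      width <- stats::setNames(base_hi - base_lo, spec$parameters)
      dw <- width[sub("_Q[1-4]$", "", active)]
      lower <- c(base_lo, -dw)
      upper <- c(base_hi, dw)
      st <- stats::setNames(as.list(pmin(pmax(unlist(st), lower), upper)),
                            names(st))
    }
    nlslm_fit(model_rhs(spec, par_expr), dummy_data, y, st,
              lower = lower, upper = upper)
  }

  ## t-statistics and two-sided p-values for the fitted terms
  t_table <- function(res) {
    se <- sqrt(diag(res$vcov))
    est <- res$coefficients[names(se)]
    tv <- est / se
    data.frame(term = names(se), estimate = unname(est), se = unname(se),
               t = unname(tv),
               p = unname(2 * stats::pt(-abs(tv), df = res$df_residual)))
  }

  active <- all_terms
  eliminated <- character(0)
  ## identifiability guard: keep total parameter count at most n - 2
  n_free <- length(y) - 2 - length(spec$parameters)
  if (length(active) > n_free) {
    eliminated <- rev(active[-seq_len(max(0, n_free))])
    active <- active[seq_len(max(0, n_free))]
  }
  res <- NULL
  repeat {
    res <- tryCatch(build_fit(active), error = function(e) e)
    if (!inherits(res, "error") && is.null(res$vcov)) {
      res <- simpleError("singular fit: coefficient covariance unavailable")
    }
    if (inherits(res, "error")) {
      if (!length(active)) {
        stop("dummy model fit failed even with no dummy terms: ",
             conditionMessage(res), call. = FALSE)
      }
      ## unidentifiable expansion: retreat by dropping the last dummy term
      eliminated <- c(eliminated, active[length(active)])
      active <- active[-length(active)]
      next
    }
    tt <- t_table(res)
    dn <- intersect(tt$term, active)
    if (!length(dn)) break
    pv <- tt$p[match(dn, tt$term)]
    if (all(pv < alpha)) break
    worst <- dn[which.max(pv)]
    eliminated <- c(eliminated, worst)
    active <- setdiff(active, worst)
  }

  structure(list(
    spec = spec,
    coefficients = res$coefficients,
    t_table = t_table(res),
    retained = active,
    eliminated = eliminated,
    all_pruned = length(active) == 0,
    loglik = res$loglik,
    aic = res$aic,
    fit = res$fit
  ), class = "dummy_fit")
}

#' @export
predict.dummy_fit <- function(object, newdata, groups, ...) {
  Q <- age_group_dummies(as.character(groups))
  spec <- object$spec
  par_expr <- vapply(spec$parameters, function(p) {
    tt <- grep(paste0("^", p, "_Q"), object$retained, value = TRUE)
    if (!length(tt)) return(p)
    qs <- sub(paste0("^", p, "_"), "", tt)
    paste0("(", p, " + ", paste(paste0(tt, " * ", qs), collapse = " + "), ")")
  }, character(1))
  env <- c(as.list(newdata), as.list(as.data.frame(Q)),
           as.list(object$coefficients))
  eval(str2lang(model_rhs(spec, par_expr)), envir = env)
}

#' @export
print.dummy_fit <- function(x, ...) {
  cat(sprintf("<dummy_fit> %s model for %s; %d dummy term(s) retained%s\n",
              x$spec$form, x$spec$component, length(x$retained),
              if (x$all_pruned) " (reduces to base model)" else ""))
  print(signif(x$coefficients, 5))
  invisible(x)
}
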