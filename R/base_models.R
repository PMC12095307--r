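#' Base model specification
#'
#' The four candidate forms relating a component biomass to LiDAR predictors
#' X1..Xn:
#' \describe{
#'   \item{linear}{`b0 + b1 X1 + ... + bn Xn`}
#'   \item{logistic}{`d0 / (1 + d1 exp(-d2 X1 - ... - d(n+1) Xn))`}
#'   \item{exponential}{`b0 exp(-b1 X1 - ... - bn Xn)`}
#'   \item{empirical}{`b0 X1^b1 ... Xn^bn` (the power-law form)}
#' }
#' Parameters are named `b0..bn` (logistic: `d0..d(n+1)`).
#'
#' @param form One of `"linear"`, `"logistic"`, `"exponential"`,
#'   `"empirical"`.
#' @param component Which biomass the model targets (one of `"trunk"`,
#'   `"bark"`, `"branch"`, `"leaf"`, `"above_ground"`, `"under_ground"`).
#' @param predictors Character vector of predictor column names, e.g.
#'   `c("AIH2", "LAI")`.
#' @return An object of class `base_model_spec` with a `parameters` element
#'   naming the free parameters.
#' @export
base_model_spec <- function(form = c("empirical", "linear", "logistic",
                                     "exponential"),
                            component = c("above_ground", "trunk", "bark",
                                          "branch", "leaf", "under_ground"),
                            predictors = c("AIH2", "LAI")) {
  form <- match.arg(form)
  component <- match.arg(component)
  if (length(predictors) < 1) stop("need >= 1 predictor", call. = FALSE)
  npar <- length(predictors) + if (form == "logistic") 2L else 1L
  prefix <- if (form == "logistic") "d" else "b"
  structure(list(
    form = form,
    component = component,
    predictors = predictors,
    parameters = paste0(prefix, seq_len(npar) - 1L)
  ), class = "base_model_spec")
}

#' The six component models of the final system
#'
#' The empirical (power) form with predictors AIH2 and LAI for trunk, bark,
#' branch, above-ground and under-ground biomass, and the logistic form for
#' leaf biomass.
#'
#' @return Named list of six [base_model_spec()] objects.
#' @export
component_model_specs <- function() {
  comps <- c("trunk", "bark", "branch", "leaf", "above_ground", "under_ground")
  stats::setNames(lapply(comps, function(cc) {
    base_model_spec(if (cc == "leaf") "logistic" else "empirical", cc,
                    c("AIH2", "LAI"))
  }), comps)
}

## Right-hand-side expression of a model form, as a string; `par_expr` allows
## the dummy model to substitute expanded parameter expressions.
model_rhs <- function(spec, par_expr = spec$parameters) {
  p <- par_expr
  x <- spec$predictors
  switch(spec$form,
    linear = paste(c(p[1], paste0(p[-1], " * ", x)), collapse = " + "),
    empirical = paste(c(p[1], paste0(x, "^(", p[-1], ")")), collapse = " * "),
    exponential = paste0(p[1], " * exp(-(",
                         paste(paste0(p[-1], " * ", x), collapse = " + "), "))"),
    logistic = paste0(p[1], " / (1 + ", p[2], " * exp(-(",
                      paste(paste0(p[-(1:2)], " * ", x), collapse = " + "),
                      ")))")
  )
}

## Documented starting values: empirical from log-log OLS, exponential from
## semi-log OLS, logistic from inverting the curve at d0 = 1.05 * max(y).
start_values <- function(spec, data, y) {
  x <- data[spec$predictors]
  eps <- 1e-6
  if (spec$form == "empirical") {
    lf <- stats::lm(log(pmax(y, eps)) ~ ., data = lapply(x, log))
    st <- c(exp(stats::coef(lf)[1]), stats::coef(lf)[-1])
  } else if (spec$form == "exponential") {
    lf <- stats::lm(log(pmax(y, eps)) ~ ., data = x)
    st <- c(exp(stats::coef(lf)[1]), -stats::coef(lf)[-1])
  } else if (spec$form == "logistic") {
    d0 <- 1.05 * max(y)
    z <- log(pmax(d0 / pmax(y, eps) - 1, eps))
    lf <- stats::lm(z ~ ., data = x)
    st <- c(d0, exp(min(stats::coef(lf)[1], 20)), -stats::coef(lf)[-1])
  } else {
    stop("linear form is solved in closed form", call. = FALSE)
  }
  stats::setNames(as.numeric(st), spec$parameters)
}

## Levenberg--Marquardt least squares of y on a model expression. Returns a
## self-contained fit (coefficients, covariance from the local quadratic
## approximation, Gaussian log-likelihood) without constructing an `nls`
## object, so weakly identified solutions still return diagnosable fits.
nlslm_fit <- function(rhs, data, y, start, lower = NULL, upper = NULL) {
  expr <- str2lang(rhs)
  resid_fun <- function(par) {
    y - eval(expr, envir = c(as.list(data), as.list(par)))
  }
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || any(!is.finite(unlist(fit$par)))) {
    stop("nonlinear least squares failed: ", fit$message, call. = FALSE)
  }
  par <- unlist(fit$par)
  n <- length(y)
  p <- length(par)
  rss <- sum(fit$fvec^2)
  sigma <- sqrt(rss / max(1, n - p))
  resvar <- rss / (n - p)
  vcov_regularized <- FALSE
  vc <- tryCatch({
    v <- chol2inv(chol(fit$hessian)) * resvar
    dimnames(v) <- list(names(par), names(par))
    v
  }, error = function(e) NULL)
  if (is.null(vc)) {
    ## singular local curvature (weakly identified direction): floor the
    ## eigenvalues so unidentified directions get very large, not spuriously
    ## small, variances
    eg <- eigen(fit$hessian, symmetric = TRUE)
    flo <- pmax(eg$values, max(abs(eg$values)) * 1e-10)
    vc <- eg$vectors %*% (t(eg$vectors) / flo) * resvar
    dimnames(vc) <- list(names(par), names(par))
    vcov_regularized <- TRUE
  }
  s2_ml <- rss / n
  ll <- -n / 2 * (log(2 * pi * s2_ml) + 1)
  list(coefficients = par, vcov = vc, vcov_regularized = vcov_regularized,
       sigma = sigma, loglik = ll,
       aic = 2 * (p + 1) - 2 * ll,
       converged = fit$info %in% 1:4,
       fitted = y - fit$fvec, residuals = fit$fvec, fit = fit,
       df_residual = n - p)
}

#' Fit a base model
#'
#' The linear form is solved in closed form (ordinary least squares); the
#' nonlinear forms by Levenberg--Marquardt least squares from documented
#' starting values (see the package vignette).
#'
#' @param spec A [base_model_spec()].
#' @param data Data frame containing the predictor columns; for the
#'   empirical and exponential forms the predictors must be strictly
#'   positive.
#' @param y Response vector (component biomass, t/hm^2).
#' @return An object of class `base_fit`: list with `spec`, `coefficients`
#'   (named), `vcov`, `sigma`, `loglik`, `aic` (2k - 2 ln L, k counting the
#'   residual variance), `converged`, `fitted`, `residuals`, and the
#'   underlying `fit` object.
#' @export
fit_base_model <- function(spec, data, y) {
  stopifnot(inherits(spec, "base_model_spec"))
  if (length(y) < length(spec$parameters) + 2) {
    stop("too few rows for the number of parameters", call. = FALSE)
  }
  if (spec$form %in% c("empirical", "exponential") &&
      any(as.matrix(data[spec$predictors]) <= 0)) {
    stop("predictors must be strictly positive for the ", spec$form, " form",
         call. = FALSE)
  }
  df <- cbind(data[spec$predictors], .y = y)
  if (spec$form == "linear") {
    fit <- stats::lm(stats::reformulate(spec$predictors, ".y"), data = df)
    cf <- stats::setNames(stats::coef(fit), spec$parameters)
    vc <- stats::vcov(fit)
    dimnames(vc) <- list(spec$parameters, spec$parameters)
    conv <- TRUE
  } else {
    st <- start_values(spec, data, y)
    ## neutral fallback start: scale at the response level, weak shape terms
    st_fallback <- stats::setNames(
      if (spec$form == "logistic") c(1.05 * max(y), 1, rep(0.1, length(spec$parameters) - 2))
      else c(mean(y), rep(0.1, length(spec$parameters) - 1)),
      spec$parameters)
    ## the logistic asymptote is weakly identified when the response does not
    ## saturate; box constraints keep it near the data range (see vignette)
    lower <- upper <- NULL
    if (spec$form == "logistic") {
      np <- length(spec$parameters) - 2
      lower <- c(0.5 * max(y), 1e-4, rep(-5, np))
      upper <- c(3 * max(y), 1e4, rep(5, np))
    }
    res <- NULL
    last_err <- NULL
    for (s in list(st, st_fallback)) {
      if (!is.null(lower)) s <- pmin(pmax(s, lower), upper)
      res <- tryCatch(nlslm_fit(model_rhs(spec), data, y, as.list(s),
                                lower = lower, upper = upper),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      last_err <- res
    }
    if (inherits(res, "error")) {
      stop(sprintf("base model fit failed (%s, %s): %s; starts were [%s]",
                   spec$form, spec$component, conditionMessage(last_err),
                   paste(signif(st, 4), collapse = ", ")), call. = FALSE)
    }
    return(structure(c(list(spec = spec), res), class = "base_fit"))
  }
  structure(list(
    spec = spec,
    coefficients = cf,
    vcov = vc,
    sigma = stats::sigma(fit),
    loglik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    converged = conv,
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    fit = fit
  ), class = "base_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.base_fit <- function(object, newdata, ...) {
  env <- c(as.list(newdata), as.list(object$coefficients))
  eval(str2lang(model_rhs(object$spec)), envir = env)
}

#' @export
print.base_fit <- function(x, ...) {
  cat(sprintf("<base_fit> %s model for %s biomass on [%s]\n", x$spec$form,
              x$spec$component, paste(x$spec$predictors, collapse = ", ")))
  print(signif(x$coefficients, 5))
  cat(sprintf("sigma %.3f, AIC %.2f\n", x$sigma, x$aic))
  invisible(x)
}
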