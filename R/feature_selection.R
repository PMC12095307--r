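#' Pearson significance screening of metrics against component biomass
#'
#' Computes, for every (metric, component) pair, the Pearson correlation and
#' its two-sided t-based p-value, and flags the pair as selected when
#' p < alpha. P-values are unadjusted. Metrics with zero variance cannot be
#' correlated and are excluded with a warning.
#'
#' @param metrics Data frame of plot-level metrics (numeric columns only;
#'   `plot_id` / `age_group` columns are dropped automatically).
#' @param biomass Data frame of component biomasses, same rows.
#' @param alpha Significance level for selection.
#' @return An object of class `screening_report`: list with `table` (one row
#'   per pair: `metric`, `component`, `r`, `p`, `selected`), `dropped`
#'   (zero-variance metrics), and `alpha`.
#' @export
pearson_screen <- function(metrics, biomass, alpha = 0.05) {
  metrics <- metrics[, setdiff(names(metrics), c("plot_id", "age_group")),
                     drop = FALSE]
  biomass <- biomass[, setdiff(names(biomass), c("plot_id", "age_group")),
                     drop = FALSE]
  if (nrow(metrics) < 3) stop("need >= 3 plots for screening", call. = FALSE)
  if (nrow(metrics) != nrow(biomass)) stop("row mismatch", call. = FALSE)
  if (anyNA(metrics) || anyNA(biomass)) stop("missing values", call. = FALSE)
  sds <- vapply(metrics, stats::sd, numeric(1))
  dropped <- names(metrics)[sds == 0]
  if (length(dropped)) {
    warning("zero-variance metric(s) excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    metrics <- metrics[, sds > 0, drop = FALSE]
  }
  pairs <- expand.grid(metric = names(metrics), component = names(biomass),
                       stringsAsFactors = FALSE)
  res <- mapply(function(m, b) {
    ct <- stats::cor.test(metrics[[m]], biomass[[b]],
                          alternative = "two.sided", method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }, pairs$metric, pairs$component)
  tab <- cbind(pairs, r = res["r", ], p = res["p", ])
  tab$selected <- tab$p < alpha
  rownames(tab) <- NULL
  structure(list(table = tab, dropped = dropped, alpha = alpha),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d pairs, %d selected at p < %.3g\n",
              nrow(x$table), sum(x$table$selected), x$alpha))
  invisible(x)
}

## VIFs of a metric table: 1 / (1 - R^2_j), R^2_j from regressing column j on
## the remaining columns. Perfect collinearity gives Inf.
compute_vifs <- function(metrics) {
  vapply(seq_along(metrics), function(j) {
    fit <- stats::lm(metrics[[j]] ~ ., data = metrics[-j])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor screening
#'
#' Repeatedly computes the VIF of every retained metric (1/(1 - R^2) of the
#' regression of that metric on the others) and drops the highest-VIF metric
#' until all VIFs fall below the threshold. Exact collinearity (infinite VIF)
#' is dropped immediately. VIF ties are broken alphabetically: the
#' alphabetically last of the tied names is dropped, so the first-named copy
#' of a duplicated column survives.
#'
#' @param metrics Data frame of candidate metrics (>= 2 numeric columns).
#' @param threshold VIF threshold (default 10).
#' @return List with `retained` (metric names), `vif` (named VIFs of the
#'   retained set), `dropped` (names in drop order).
#' @export
vif_screen <- function(metrics, threshold = 10) {
  metrics <- metrics[, setdiff(names(metrics), c("plot_id", "age_group")),
                     drop = FALSE]
  if (ncol(metrics) < 2) stop("need >= 2 candidate metrics", call. = FALSE)
  dropped <- character(0)
  repeat {
    if (ncol(metrics) == 1) {
      vifs <- stats::setNames(1, names(metrics))
      break
    }
    vifs <- stats::setNames(compute_vifs(metrics), names(metrics))
    if (all(vifs < threshold)) break
    worst <- vifs[vifs == max(vifs)]
    drop_name <- sort(names(worst), decreasing = TRUE)[1]
    dropped <- c(dropped, drop_name)
    metrics <- metrics[, setdiff(names(metrics), drop_name), drop = FALSE]
  }
  list(retained = names(metrics), vif = vifs, dropped = dropped)
}
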