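#' Random-forest biomass regression
#'
#' Bootstrap-aggregated regression trees: each tree is grown on a bootstrap
#' sample using the sum-of-squared-deviation split criterion (every candidate
#' split minimizes the within-child squared deviation from the child means),
#' leaf prediction is the leaf mean, and the forest prediction is the mean
#' over trees. Backed by the `randomForest` CART implementation, whose
#' squared-error split rule is this criterion; the package test suite checks
#' the equivalence on a hand-enumerable case against an exhaustive
#' split-search oracle.
#'
#' @param X Data frame or matrix of predictors (>= 5 rows).
#' @param y Numeric response.
#' @param n_trees Number of trees.
#' @param seed Integer seed; fixes the bootstrap and split randomization.
#' @param ... Passed to [randomForest::randomForest()] (e.g. `maxnodes`,
#'   `mtry`, `replace`, `sampsize`).
#' @return An object of class `rf_fit` wrapping the forest.
#' @export
fit_random_forest <- function(X, y, n_trees = 500, seed = 1, ...) {
  X <- as.data.frame(X)
  if (nrow(X) < 5) stop("need >= 5 rows", call. = FALSE)
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = y, ntree = n_trees, ...)
  structure(list(forest = forest, n_trees = n_trees, seed = seed),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$forest, newdata = as.data.frame(newdata)))
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("<rf_fit> %d trees (seed %d), %% variance explained: %.1f\n",
              x$n_trees, x$seed,
              100 * x$forest$rsq[length(x$forest$rsq)]))
  invisible(x)
}
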