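# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (and the library routines behind them) so the two
# routes only meet at the answer.

# percentile by linear interpolation between closest ranks, written out
oracle_percentile <- function(values, p) {
  v <- sort(values)
  n <- length(v)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# cumulative height percentile by explicit running-sum loop
oracle_aih <- function(values, p) {
  v <- sort(values)
  target <- p / 100 * sum(v)
  s <- 0
  for (i in seq_along(v)) {
    s <- s + v[i]
    if (s >= target - 1e-12) return(v[i])
  }
  v[length(v)]
}

# evaluation statistics re-derived term by term
oracle_eval <- function(y, yhat) {
  n <- length(y)
  e <- y - yhat
  ebar <- sum(e) / n
  s2 <- sum((e - ebar)^2) / (n - 1)
  list(mean_bias = ebar, bias_variance = s2,
       r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
       tre = 100 * sum(e^2) / sum(y^2),
       rmse = sqrt(ebar^2 + s2))
}

# maximum-likelihood linear mixed model with a random intercept, by
# profiling lambda = sigma_u^2 / sigma_e^2: GLS for beta given lambda,
# closed-form sigma_e^2, 1-D optimization of the profile likelihood.
oracle_lmm_ml <- function(X, y, groups) {
  groups <- factor(groups)
  idx <- split(seq_along(y), groups)
  n <- length(y)
  prof <- function(log_lambda) {
    lam <- exp(log_lambda)
    XtVX <- 0; XtVy <- 0
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]; yi <- y[ii]; ni <- length(ii)
      # (I + lam J)^{-1} = I - lam/(1+ni*lam) J  (Sherman-Morrison)
      a <- lam / (1 + ni * lam)
      Vi_inv_X <- Xi - a * matrix(colSums(Xi), ni, ncol(Xi), byrow = TRUE)
      XtVX <- XtVX + crossprod(Xi, Vi_inv_X)
      XtVy <- XtVy + crossprod(Vi_inv_X, yi)
    }
    beta <- solve(XtVX, XtVy)
    rss <- 0; logdet <- 0
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]; yi <- y[ii]; ni <- length(ii)
      ri <- yi - Xi %*% beta
      a <- lam / (1 + ni * lam)
      rss <- rss + sum(ri^2) - a * sum(ri)^2
      logdet <- logdet + log(1 + ni * lam)
    }
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
    list(ll = ll, beta = beta, s2 = s2, lambda = lam)
  }
  opt <- stats::optimize(function(l) -prof(l)$ll, c(-15, 15))
  prof(opt$minimum)
}

# exhaustive best binary split of 1-D data under the sum-of-squared-
# deviation criterion: minimize SSE(left) + SSE(right) over all cut points
oracle_best_split <- function(x, y) {
  xs <- sort(unique(x))
  cuts <- (xs[-1] + xs[-length(xs)]) / 2
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  obj <- vapply(cuts, function(cp) {
    sse(y[x <= cp]) + sse(y[x > cp])
  }, numeric(1))
  best <- which.min(obj)
  list(cut = cuts[best],
       left_mean = mean(y[x <= cuts[best]]),
       right_mean = mean(y[x > cuts[best]]))
}
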