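test_that("noise-free empirical data returns its generating parameters", {
  d <- simulate_component_biomass(re_sd = 0, sigma = 0,
                                  beta = c(b0 = 9.5, b1 = 0.71, b2 = 0.33),
                                  seed = 1)
  fit <- fit_base_model(base_model_spec("empirical", "trunk"), d, d$y)
  expect_equal(unname(fit$coefficients), c(9.5, 0.71, 0.33),
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the linear form equals the normal-equation solution", {
  set.seed(2)
  d <- data.frame(AIH2 = runif(40, 3, 10), LAI = runif(40, 1, 4))
  y <- 5 + 2 * d$AIH2 - 3 * d$LAI + rnorm(40)
  fit <- fit_base_model(base_model_spec("linear", "trunk"), d, y)
  Xm <- cbind(1, d$AIH2, d$LAI)
  beta_ne <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta_ne),
               tolerance = 1e-10)
})

test_that("a flat logistic truth yields a near-constant fitted curve", {
  set.seed(3)
  d <- data.frame(AIH2 = runif(60, 3, 10), LAI = runif(60, 1, 4))
  y <- rep(20 / (1 + 0.6), 60) + rnorm(60, 0, 1e-3)
  fit <- fit_base_model(base_model_spec("logistic", "leaf"), d, y)
  expect_lt(diff(range(fit$fitted)), 0.05)
  expect_equal(mean(fit$fitted), 12.5, tolerance = 0.01)
})

test_that("exponential form fits its own truth", {
  set.seed(4)
  d <- data.frame(AIH2 = runif(80, 3, 10), LAI = runif(80, 1, 4))
  y <- 150 * exp(-(0.12 * d$AIH2 + 0.3 * d$LAI)) * exp(rnorm(80, 0, 0.02))
  fit <- fit_base_model(base_model_spec("exponential", "bark"), d, y)
  expect_equal(unname(fit$coefficients), c(150, 0.12, 0.3), tolerance = 0.1)
})

test_that("random-effect enumeration is exhaustive and ordered", {
  spec3 <- base_model_spec("empirical", "trunk")
  combos <- enumerate_random_effect_combos(spec3)
  expect_length(combos, 7)
  expect_equal(combos[[1]], "b0")
  expect_equal(vapply(combos, length, integer(1)), c(1, 1, 1, 2, 2, 2, 3))
  expect_equal(combos[[7]], c("b0", "b1", "b2"))

  spec4 <- base_model_spec("logistic", "leaf")
  expect_length(enumerate_random_effect_combos(spec4), 15)

  # two-parameter univariate model: 3 subsets
  spec2 <- base_model_spec("empirical", "leaf", predictors = "LAI")
  expect_length(enumerate_random_effect_combos(spec2), 3)

  # the full component system enumerates 50 candidate structures
  total <- sum(vapply(component_model_specs(),
                      function(s) length(enumerate_random_effect_combos(s)),
                      integer(1)))
  expect_equal(total, 50)
})

test_that("bivariate fits never lose to their nested univariate forms", {
  set.seed(5)
  d <- simulate_component_biomass(re_sd = 0, seed = 5)
  for (form in c("linear", "empirical")) {
    uni <- fit_base_model(base_model_spec(form, "trunk", "AIH2"),
                          d["AIH2"], d$y)
    biv <- fit_base_model(base_model_spec(form, "trunk", c("AIH2", "LAI")),
                          d, d$y)
    expect_lte(sum(biv$residuals^2), sum(uni$residuals^2) * (1 + 1e-8),
               label = form)
  }
})

test_that("age-group indicator coding matches the study design", {
  Q <- age_group_dummies(age_group_labels())
  expect_equal(unname(Q["young" == age_group_labels(), ]), c(1, 0, 0, 0))
  expect_equal(unname(Q[2, ]), c(0, 1, 0, 0))
  expect_equal(unname(Q[3, ]), c(0, 0, 1, 0))
  expect_equal(unname(Q[4, ]), c(0, 0, 0, 1))
  expect_equal(unname(Q[5, ]), c(0, 0, 0, 0))  # over-mature is the reference
  expect_true(all(rowSums(Q) <= 1))
  expect_error(age_group_dummies("seedling"), "unknown")
})

test_that("dummy pruning keeps a genuinely shifted group", {
  # young group scale raised well above the noise: delta on the scale must
  # survive with positive sign
  d <- simulate_component_biomass(re_sd = 0, sigma = 8,
                                  group_offsets = c(young = 6), seed = 6)
  fit <- fit_dummy_model(base_model_spec("empirical", "trunk"), d, d$y,
                         d$group)
  expect_true("b0_Q1" %in% fit$retained)
  expect_gt(fit$coefficients[["b0_Q1"]], 0)
  # elimination bookkeeping: drop order and retained set partition the terms
  expect_length(intersect(fit$retained, fit$eliminated), 0)
})

test_that("random forest reproduces constants, seeds, and the split rule", {
  set.seed(7)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  f_const <- suppressWarnings(
    fit_random_forest(X, rep(4.2, 30), n_trees = 50, seed = 1))
  expect_equal(predict(f_const, X), rep(4.2, 30), tolerance = 1e-12)

  y <- X$a + X$b^2 + rnorm(30, 0, 0.1)
  f1 <- fit_random_forest(X, y, n_trees = 100, seed = 9)
  f2 <- fit_random_forest(X, y, n_trees = 100, seed = 9)
  expect_identical(predict(f1, X), predict(f2, X))
  f3 <- fit_random_forest(X, y, n_trees = 100, seed = 10)
  expect_false(identical(predict(f3, X), predict(f1, X)))
  expect_error(fit_random_forest(X[1:3, ], y[1:3]), ">= 5")

  # one depth-1 tree on a clean step recovers the oracle split
  xs <- c(-3, -2.2, -1.1, -0.4, 0.6, 1.3, 2.0, 3.1)
  ys <- as.numeric(xs > 0)
  o <- oracle_best_split(xs, ys)
  expect_equal(o$left_mean, 0)
  expect_equal(o$right_mean, 1)
  ft <- suppressWarnings(
    fit_random_forest(data.frame(x = xs), ys, n_trees = 1, seed = 2,
                      maxnodes = 2, mtry = 1, replace = FALSE,
                      sampsize = length(xs), nodesize = 1))
  tree <- randomForest::getTree(ft$forest, 1)
  expect_equal(tree[1, "split point"], o$cut, tolerance = 1e-9)
  expect_equal(sort(predict(ft, data.frame(x = c(-2, 2)))), c(0, 1))
})

test_that("the forest out-fits a parametric form under interaction-rich truth", {
  set.seed(8)
  n <- 150
  d <- data.frame(AIH2 = runif(n, 3, 10), LAI = runif(n, 1, 4.5))
  # thresholded interaction the smooth power law cannot represent
  y <- 10 * d$AIH2^0.6 * d$LAI^0.3 +
    40 * (d$AIH2 > 7 & d$LAI > 3) + rnorm(n, 0, 3)
  par_fit <- fit_base_model(base_model_spec("empirical", "trunk"), d, y)
  rf_fit <- fit_random_forest(d, y, n_trees = 300, seed = 11)
  r2 <- function(pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_gt(r2(predict(rf_fit, d)), r2(par_fit$fitted))
})
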