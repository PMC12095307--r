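test_that("height percentiles follow the closest-rank interpolation rule", {
  expect_equal(height_percentiles(1:10, 50), 5.5)
  expect_equal(height_percentiles(1:10, 100), 10)
  expect_equal(height_percentiles(rep(3.2, 7)), rep(3.2, 20))
  set.seed(10)
  for (r in 1:20) {
    v <- runif(sample(2:1000, 1), 0, 30)
    lv <- sort(sample(1:100, 5))
    expect_equal(height_percentiles(v, lv),
                 vapply(lv, function(p) oracle_percentile(v, p), numeric(1)))
  }
  # non-decreasing in level
  v <- rexp(200)
  expect_true(all(diff(height_percentiles(v)) >= 0))
})

test_that("cumulative height percentiles follow the running-sum rule", {
  expect_equal(cumulative_height_percentiles(c(1, 2, 3, 4), 50), 3)
  expect_equal(cumulative_height_percentiles(7.5, c(1, 50, 100)), rep(7.5, 3))
  expect_equal(cumulative_height_percentiles(c(2, 9, 4, 1), 100), 9)
  set.seed(11)
  for (r in 1:20) {
    v <- runif(sample(2:1000, 1), 0, 30)
    lv <- sort(sample(1:100, 5))
    expect_equal(cumulative_height_percentiles(v, lv),
                 vapply(lv, function(p) oracle_aih(v, p), numeric(1)))
  }
  v <- rexp(300)
  aih <- cumulative_height_percentiles(v)
  expect_true(all(diff(aih) >= 0))
  expect_true(all(aih <= max(v)))
})

test_that("height statistics use n-1 sd and moment skewness/kurtosis", {
  s <- height_statistics(c(0, 10))
  expect_equal(s$h_mean, 5)
  expect_equal(s$h_sd, sqrt(50))
  expect_equal(s$h_cv, sqrt(50) / 5)

  expect_warning(s0 <- height_statistics(rep(4, 5)), "undefined")
  expect_equal(s0$h_sd, 0)
  expect_equal(s0$h_cv, 0)
  expect_true(is.nan(s0$h_skewness) && is.nan(s0$h_kurtosis))

  sym <- c(1, 2, 3, 4, 5)
  expect_lt(abs(height_statistics(sym)$h_skewness), 1e-12)
  # independent moment arithmetic
  v <- c(1.2, 5.4, 2.2, 9.9, 4.4, 4.4)
  m <- mean(v); m2 <- mean((v - m)^2)
  expect_equal(height_statistics(v)$h_skewness, mean((v - m)^3) / m2^1.5)
  expect_equal(height_statistics(v)$h_kurtosis, mean((v - m)^4) / m2^2)
  expect_error(height_statistics(3), "metric error")
})

test_that("intensity percentiles are interpolated deciles", {
  expect_equal(intensity_percentiles(rep(7, 4)), rep(7, 9))
  expect_equal(intensity_percentiles(1:100)[5], 50.5)
  set.seed(12)
  v <- rgamma(500, 2)
  expect_true(all(diff(intensity_percentiles(v)) >= 0))
  expect_equal(intensity_percentiles(v),
               vapply(seq(10, 90, 10), function(p) oracle_percentile(v, p),
                      numeric(1)))
})

test_that("canopy cover counts first echoes above the cutoff", {
  cl <- make_cloud(z = c(5, 3, 0.4, 9), return_number = c(1, 1, 1, 1))
  expect_equal(canopy_cover(cl, cutoff = 2), 0.75)
  expect_equal(canopy_cover(make_cloud(z = c(5, 6, 7)), 2), 1)
  ground <- make_cloud(z = c(0, 0.1, 0.3), classification = "ground")
  expect_equal(canopy_cover(ground, 2), 0)
  # second returns do not enter the cover
  cl2 <- make_cloud(z = c(5, 3, 0.4, 9, 50), return_number = c(1, 1, 1, 1, 2))
  expect_equal(canopy_cover(cl2, 2), 0.75)
})

test_that("leaf area index inverts the gap fraction", {
  # closed form: m of n returns at/below the cutoff -> -log(m/n)/k
  cl <- make_cloud(z = c(rep(0.5, 25), rep(8, 75)))
  expect_equal(leaf_area_index(cl, cutoff = 2, k = 0.5), -log(0.25) / 0.5)
  bare <- make_cloud(z = rep(0.2, 50), classification = "ground")
  expect_equal(leaf_area_index(bare, 2), 0)
  # strictly decreasing in gap fraction
  lai <- vapply(c(10, 30, 60, 90), function(m) {
    leaf_area_index(make_cloud(z = c(rep(0, m), rep(8, 100 - m))), 2)
  }, numeric(1))
  expect_true(all(diff(lai) < 0))
})

test_that("the metric vector has exactly the 57 canonical entries", {
  expect_length(metric_names(), 57)
  expect_false(anyDuplicated(metric_names()) > 0)

  cfg <- tiny_config()
  cl <- generate_point_cloud(generate_stand("near_mature", cfg, seed = 2),
                             cfg, seed = 3)
  m <- extract_metrics(normalize_heights(cl))
  expect_length(m, 57)
  expect_named(m, metric_names())
  # the 5% cumulative level is addressable as AIH2
  expect_equal(percentile_levels()[2], 5)
  expect_true("AIH2" %in% names(m))
  expect_true(all(diff(m[paste0("h", percentile_levels())]) >= 0))
  expect_true(all(diff(m[paste0("AIH", 1:20)]) >= 0))
  expect_true(m[["CC"]] >= 0 && m[["CC"]] <= 1)
  expect_gte(m[["LAI"]], 0)
  expect_equal(m[["h_cv"]], m[["h_sd"]] / m[["h_mean"]])
})

test_that("degenerate clouds raise metric errors rather than zeros", {
  cfg <- tiny_config()
  cl <- generate_point_cloud(bare_plot(), cfg, seed = 5)
  expect_error(extract_metrics(normalize_heights(cl)), "metric error")
  expect_error(extract_metrics(make_cloud(z = 5:9, normalized = FALSE)),
               "normalized")
})

test_that("metrics ignore point order and rigid x-y translation", {
  cfg <- tiny_config()
  cl <- normalize_heights(generate_point_cloud(
    generate_stand("mature", cfg, seed = 6), cfg, seed = 7))
  m0 <- extract_metrics(cl)

  set.seed(1)
  shuf <- cl[sample(nrow(cl)), ]
  attributes(shuf)$normalized <- TRUE
  class(shuf) <- class(cl)
  expect_equal(extract_metrics(shuf), m0)

  moved <- cl
  moved$x <- moved$x + 250
  moved$y <- moved$y - 97
  expect_equal(extract_metrics(moved), m0)
})

test_that("normalization recovers the analytic ground surface", {
  # flat ground maps ground returns to zero exactly
  flat <- point_cloud(x = runif(200, 0, 20), y = runif(200, 0, 20),
                      z = 100, classification = "ground")
  nf <- normalize_heights(flat, grid_size = 2)
  expect_equal(nf$z, rep(0, 200))

  # sinusoidal terrain: normalized ground heights stay near zero
  cfg <- tiny_config()
  cl <- generate_point_cloud(generate_stand("young", cfg, seed = 8), cfg,
                             seed = 9)
  nz <- normalize_heights(cl, grid_size = 2)
  gz <- nz$z[nz$classification == "ground"]
  expect_lt(stats::quantile(gz, 0.99), 0.75)
  expect_lt(mean(gz), 0.35)

  # idempotence on flat, already-normalized ground
  again <- normalize_heights(nf, grid_size = 2)
  expect_equal(again$z, nf$z)
  expect_error(normalize_heights(make_cloud(z = 1:5)), "ground")
})

test_that("upper height percentiles track the tallest tree of a plot", {
  cfg <- tiny_config()
  p <- generate_stand("over_mature", cfg, seed = 10)
  cl <- normalize_heights(generate_point_cloud(p, cfg, seed = 11))
  m <- extract_metrics(cl)
  tallest <- max(p$trees$height)
  expect_lt(abs(m[["h_max"]] - tallest), 5 * cfg$noise_sd + 0.5)
  # cone geometry puts the 99th percentile just below the apex
  expect_gt(m[["h99"]], 0.8 * tallest)
  expect_lte(m[["h99"]], m[["h_max"]])
})

test_that("xyzi text round-trips a cloud", {
  cfg <- tiny_config()
  cl <- generate_point_cloud(generate_stand("young", cfg, seed = 12), cfg,
                             seed = 13)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyzi(cl, path)
  back <- read_xyzi(path, plot_id = attr(cl, "plot_id"))
  expect_equal(back$z, cl$z, tolerance = 1e-12)
  expect_equal(as.character(back$classification),
               as.character(cl$classification))
  expect_equal(extract_metrics(normalize_heights(back)),
               extract_metrics(normalize_heights(cl)), tolerance = 1e-9)
})
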