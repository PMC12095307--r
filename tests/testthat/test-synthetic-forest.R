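test_that("stand generation is deterministic and respects tree invariants", {
  cfg <- tiny_config()
  p1 <- generate_stand("middle_aged", cfg, seed = 42)
  p2 <- generate_stand("middle_aged", cfg, seed = 42)
  expect_identical(p1$trees, p2$trees)
  p3 <- generate_stand("middle_aged", cfg, seed = 43)
  expect_false(identical(p1$trees, p3$trees))

  for (g in age_group_labels()) {
    p <- generate_stand(g, cfg, seed = 7)
    expect_true(all(p$trees$dbh >= 5))
    expect_true(all(p$trees$crown_base_height < p$trees$height))
    expect_true(all(p$trees$x >= 0 & p$trees$x <= p$side_length))
    expect_true(all(p$trees$crown_radius >= 0))
    expect_equal(p$stand_density, nrow(p$trees) * 10000 / p$side_length^2)
    expect_equal(p$mean_dbh, sqrt(mean(p$trees$dbh^2)))
  }
})

test_that("stand attributes stay inside the age-group envelopes", {
  cfg <- generator_config()  # full 30 m plots
  for (g in age_group_labels()) {
    env <- age_group_envelope(g)
    for (s in 1:5) {
      p <- generate_stand(g, cfg, seed = s)
      expect_gte(p$mean_dbh, env$dbh[1])
      expect_lte(p$mean_dbh, env$dbh[2])
      expect_gte(p$mean_height, env$height[1])
      expect_lte(p$mean_height, env$height[2])
      expect_gte(p$stand_density, env$density[1])
      expect_lte(p$stand_density, env$density[2])
    }
  }
  # the young group at the default configuration and seed 1
  p <- generate_stand("young", cfg, seed = 1)
  expect_gte(p$mean_dbh, 6.1)
  expect_lte(p$mean_dbh, 15.3)
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(side_length = 0), "side_length")
  expect_error(generator_config(point_density = -1), "point_density")
  expect_error(generator_config(plots_per_group = c(1, 2, 3)), "five")
  expect_error(generate_stand("sapling", tiny_config(), seed = 1), "unknown")
})

test_that("plot sets honour the configured group counts", {
  cfg <- tiny_config()
  plots <- generate_plot_set(cfg, seed = 1)
  expect_length(plots, 10)
  ids <- vapply(plots, function(p) p$plot_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  tab <- table(vapply(plots, function(p) p$age_group, character(1)))
  expect_true(all(tab[age_group_labels()] == 2))

  expect_length(generate_plot_set(
    generator_config(plots_per_group = rep(0L, 5)), seed = 1), 0)
  one_each <- generate_plot_set(
    generator_config(plots_per_group = rep(1L, 5), side_length = 15), seed = 1)
  expect_length(one_each, 5)
  expect_setequal(vapply(one_each, function(p) p$age_group, character(1)),
                  age_group_labels())
})

test_that("point clouds hit the target density and carry both classes", {
  cfg <- tiny_config()
  p <- generate_stand("mature", cfg, seed = 3)
  cl <- generate_point_cloud(p, cfg, seed = 4)
  target <- cfg$point_density * p$side_length^2
  expect_lt(abs(nrow(cl) - target) / target, 0.10)

  expect_true(all(c("ground", "vegetation") %in% cl$classification))
  expect_true(all(is.finite(cl$z)))
  expect_setequal(unique(cl$return_number), c(1L, 2L))

  # intensity distributions of the two classes are distinct
  expect_gt(mean(cl$intensity[cl$classification == "vegetation"]),
            mean(cl$intensity[cl$classification == "ground"]) + 10)

  # determinism
  cl2 <- generate_point_cloud(p, cfg, seed = 4)
  expect_identical(as.data.frame(cl), as.data.frame(cl2))
})

test_that("a treeless plot yields a ground-only cloud", {
  cfg <- tiny_config()
  cl <- generate_point_cloud(bare_plot(), cfg, seed = 5)
  expect_true(all(cl$classification == "ground"))
  target <- cfg$point_density * 15^2
  expect_lt(abs(nrow(cl) - target) / target, 0.10)
})

test_that("one master seed fixes the whole generation chain", {
  cfg <- tiny_config()
  run <- function() {
    plots <- generate_plot_set(cfg, seed = 11)
    list(biomass = plot_biomass_table(plots),
         metrics = extract_metrics_table(plots, cfg, seed = 12))
  }
  expect_identical(run(), run())
})

test_that("simulated component biomass reflects its generating parameters", {
  d <- simulate_component_biomass(seed = 1)
  expect_equal(nrow(d), 154)
  expect_equal(as.integer(table(d$group)), c(33, 34, 26, 34, 27))
  # noiseless, no-random-effect simulation is exactly the power law
  d0 <- simulate_component_biomass(re_sd = 0, sigma = 0,
                                   beta = c(b0 = 2, b1 = 0.5, b2 = 1),
                                   seed = 2)
  expect_equal(d0$y, 2 * d0$AIH2^0.5 * d0$LAI, tolerance = 1e-12)
})
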