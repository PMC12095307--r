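#' Configuration for the synthetic stand and point-cloud generator
#'
#' Bundles every tunable of the simulator in one object. The defaults are the
#' study design emulated by the package: 154 plots of 30 m x 30 m split
#' 33/34/26/34/27 over the five age groups, and clouds of approximately
#' 110 points/m^2 with ground and vegetation returns carrying intensity.
#'
#' @param plots_per_group Integer vector of length 5: number of plots per age
#'   group, in the order of [age_group_labels()].
#' @param side_length Plot side (m); plots are square.
#' @param point_density Target return density (points/m^2).
#' @param noise_sd Vertical noise of crown-surface returns (m).
#' @param ground_amplitude Amplitude of the sinusoidal ground surface (m).
#' @param ground_wavelength Wavelength of the ground surface (m).
#' @param dbh_cv Within-plot coefficient of variation of DBH.
#' @param height_exponent Exponent of the per-plot height--DBH allometry
#'   h = alpha * dbh^gamma (alpha is calibrated per plot).
#' @param height_noise_sd Log-scale residual sd of individual tree heights.
#' @param interior_fraction Probability that a crown-surface pulse also yields
#'   a second (interior) vegetation return.
#' @param ground_penetration Probability that a crown pulse also yields a
#'   last-return ground echo (keeps terrain observable under closed canopy).
#' @return An object of class `generator_config` (a list).
#' @seealso [generate_plot_set()], [generate_point_cloud()]
#' @export
generator_config <- function(plots_per_group = c(33, 34, 26, 34, 27),
                             side_length = 30,
                             point_density = 110,
                             noise_sd = 0.15,
                             ground_amplitude = 1.5,
                             ground_wavelength = 19,
                             dbh_cv = 0.12,
                             height_exponent = 0.85,
                             height_noise_sd = 0.04,
                             interior_fraction = 0.3,
                             ground_penetration = 0.08) {
  if (length(plots_per_group) != 5 || any(plots_per_group < 0) ||
      any(plots_per_group != round(plots_per_group))) {
    stop("plots_per_group must be five non-negative integers", call. = FALSE)
  }
  if (side_length <= 0) stop("side_length must be > 0", call. = FALSE)
  if (point_density <= 0) stop("point_density must be > 0", call. = FALSE)
  if (ground_amplitude < 0 || ground_amplitude > 2) {
    stop("ground_amplitude must be in [0, 2] m", call. = FALSE)
  }
  structure(list(
    plots_per_group = as.integer(plots_per_group),
    side_length = side_length,
    point_density = point_density,
    noise_sd = noise_sd,
    ground_amplitude = ground_amplitude,
    ground_wavelength = ground_wavelength,
    dbh_cv = dbh_cv,
    height_exponent = height_exponent,
    height_noise_sd = height_noise_sd,
    interior_fraction = interior_fraction,
    ground_penetration = ground_penetration
  ), class = "generator_config")
}

## Analytic ground elevation used by the simulator; exactly invertible so the
## normalization step can be checked against truth.
#' Ground surface elevation of the simulator
#'
#' @param x,y Coordinates (m).
#' @param config A [generator_config()].
#' @return Elevation (m) of the synthetic terrain at (x, y).
#' @export
ground_elevation <- function(x, y, config = generator_config()) {
  A <- config$ground_amplitude
  L <- config$ground_wavelength
  A * sin(2 * pi * x / L) * cos(2 * pi * y / L)
}

## truncated-normal draw by rejection (vectorized, simple ranges only)
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- stats::rnorm(n, mean, sd)
    out <- c(out, z[z >= lower & z <= upper])
  }
  out[seq_len(n)]
}

#' Generate one age-structured plot with a tree list
#'
#' Draws stand density, quadratic mean DBH and mean height inside the
#' envelope of the requested age group (see [age_group_envelope()]), then
#' populates the plot with trees whose heights follow a per-plot allometry
#' h = alpha * dbh^gamma with multiplicative noise, so height and DBH are
#' positively correlated. All DBH values respect the 5 cm survey threshold.
#'
#' Stand density is drawn uniformly within the envelope; the target quadratic
#' mean DBH from a truncated normal centred mid-envelope. Mean height tracks
#' the plot's position within the DBH envelope plus noise, which reproduces
#' the positive DBH--height association across plots.
#'
#' @param age_group One of [age_group_labels()].
#' @param config A [generator_config()].
#' @param seed Integer seed; fixes the full stream of draws.
#' @return An object of class `plot_record`: a list with `plot_id`,
#'   `age_group`, `side_length`, `trees` (data frame with `dbh`, `height`,
#'   `x`, `y`, `crown_radius`, `crown_base_height`), `stand_density`,
#'   `mean_dbh` (quadratic mean), `mean_height`.
#' @examples
#' p <- generate_stand("young", generator_config(), seed = 1)
#' p$mean_dbh
#' @export
generate_stand <- function(age_group, config = generator_config(), seed = 1) {
  age_group <- as.character(age_group)
  if (!age_group %in% age_group_labels()) {
    stop("unknown age-group label: ", age_group, call. = FALSE)
  }
  stopifnot(inherits(config, "generator_config"))
  env <- age_group_envelope(age_group)
  set.seed(seed)
  side <- config$side_length
  area_hm2 <- side^2 / 10000

  ## stand density: uniform within envelope, inset so the realized (rounded
  ## tree count) density stays inside
  d_lo <- env$density[1] + 10 / area_hm2 * 0  # inset applied via count guard below
  density <- stats::runif(1, env$density[1] + 15, env$density[2] - 15)
  n_trees <- max(1L, as.integer(round(density * area_hm2)))

  ## quadratic mean DBH target: truncated normal inside a 10% inset envelope
  r <- diff(env$dbh)
  dq <- rtruncnorm1(1, mean = mean(env$dbh), sd = r / 4,
                    lower = env$dbh[1] + 0.1 * r, upper = env$dbh[2] - 0.1 * r)

  ## mean height target tracks position in the DBH envelope
  hr <- diff(env$height)
  pos <- (dq - env$dbh[1]) / r
  h_target <- env$height[1] + 0.1 * hr + pos * 0.8 * hr +
    stats::rnorm(1, 0, 0.05 * hr)
  h_target <- min(max(h_target, env$height[1] + 0.05 * hr),
                  env$height[2] - 0.05 * hr)

  ## individual DBH: truncated normal, rescaled so the sample quadratic mean
  ## equals the target
  dbh <- rtruncnorm1(n_trees, mean = dq, sd = config$dbh_cv * dq,
                     lower = 5.05, upper = Inf)
  dbh <- dbh * dq / sqrt(mean(dbh^2))
  dbh <- pmax(5, dbh)

  ## heights: h = alpha * dbh^gamma * exp(noise); alpha calibrated so the
  ## arithmetic mean height hits the target
  gam <- config$height_exponent
  base <- dbh^gam
  noise <- exp(stats::rnorm(n_trees, 0, config$height_noise_sd))
  alpha <- h_target / mean(base * noise)
  height <- pmax(1.5, alpha * base * noise)

  crown_base <- height * stats::runif(n_trees, 0.35, 0.55)
  crown_radius <- pmax(0.5, 0.16 * height * exp(stats::rnorm(n_trees, 0, 0.1)))

  trees <- data.frame(
    dbh = dbh,
    height = height,
    x = stats::runif(n_trees, 0, side),
    y = stats::runif(n_trees, 0, side),
    crown_radius = crown_radius,
    crown_base_height = crown_base
  )
  structure(list(
    plot_id = NA_character_,
    age_group = age_group,
    side_length = side,
    trees = trees,
    stand_density = nrow(trees) * 10000 / side^2,
    mean_dbh = sqrt(mean(trees$dbh^2)),
    mean_height = mean(trees$height)
  ), class = "plot_record")
}

#' @export
print.plot_record <- function(x, ...) {
  cat(sprintf(
    "<plot_record %s> %s, %d trees, density %.0f trees/hm2, Dq %.1f cm, H %.1f m\n",
    x$plot_id, x$age_group, nrow(x$trees), x$stand_density, x$mean_dbh,
    x$mean_height))
  invisible(x)
}

#' Generate the full set of plots for all age groups
#'
#' @param config A [generator_config()]; `plots_per_group` gives the group
#'   sizes (defaults reproduce the 154-plot design).
#' @param seed Master seed; per-plot seeds are derived from it.
#' @return A list of [generate_stand()] plot records in deterministic order
#'   (groups in developmental order, plots numbered within group); `plot_id`s
#'   are unique.
#' @export
generate_plot_set <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  labels <- age_group_labels()
  n_total <- sum(config$plots_per_group)
  if (n_total == 0) return(list())
  set.seed(seed)
  plot_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  plots <- vector("list", n_total)
  k <- 0L
  for (g in seq_along(labels)) {
    for (j in seq_len(config$plots_per_group[g])) {
      k <- k + 1L
      p <- generate_stand(labels[g], config, seed = plot_seeds[k])
      p$plot_id <- sprintf("%s_%02d", labels[g], j)
      plots[[k]] <- p
    }
  }
  plots
}

#' Construct a point cloud
#'
#' Container for per-return LiDAR records: coordinates, intensity, return
#' number and a ground/vegetation/noise classification. Coordinates must be
#' finite. Used by the simulator and by readers of external data.
#'
#' @param x,y,z Coordinates (m).
#' @param intensity Return intensity (dimensionless, >= 0).
#' @param return_number Echo number within pulse (1 = first).
#' @param classification `"ground"`, `"vegetation"` or `"noise"`.
#' @param normalized Whether `z` is height above ground rather than
#'   elevation.
#' @param plot_id Optional plot identifier.
#' @return A `point_cloud`: a data frame with the columns above and
#'   attributes `normalized` and `plot_id`.
#' @export
point_cloud <- function(x, y, z, intensity = 0, return_number = 1L,
                        classification = "vegetation", normalized = FALSE,
                        plot_id = NA_character_) {
  n <- length(x)
  new_point_cloud(x, y, z, rep_len(intensity, n),
                  rep_len(return_number, n), rep_len(classification, n),
                  normalized = normalized, plot_id = plot_id)
}

## point-cloud constructor/validator
new_point_cloud <- function(x, y, z, intensity, return_number, classification,
                            normalized = FALSE, plot_id = NA_character_) {
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(z)))
  df <- data.frame(
    x = x, y = y, z = z,
    intensity = intensity,
    return_number = as.integer(return_number),
    classification = factor(classification,
                            levels = c("ground", "vegetation", "noise"))
  )
  structure(df, normalized = normalized, plot_id = plot_id,
            class = c("point_cloud", "data.frame"))
}

#' Simulate the LiDAR point cloud of one plot
#'
#' Ground returns lie on a gently varying sinusoidal surface (see
#' [ground_elevation()]); each tree crown is a solid of revolution (cone with
#' apex at the tree top, base at the crown base height) and pulses hitting a
#' crown return from its upper surface with vertical noise. Crown-surface
#' returns carry `return_number` 1, interior and canopy-penetrating ground
#' echoes 2. Ground and vegetation intensities are drawn from distinct
#' distributions. Total returns land within about 10% of
#' `point_density * area`; the pulse count is calibrated by a first pass that
#' measures the canopy fraction.
#'
#' Classification labels are the simulation truth; downstream code may ignore
#' them and re-derive classes.
#'
#' @param plot A `plot_record`.
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A `point_cloud` (data frame with `x`, `y`, `z`, `intensity`,
#'   `return_number`, `classification`; attribute `normalized = FALSE`).
#' @export
generate_point_cloud <- function(plot, config = generator_config(), seed = 1) {
  stopifnot(inherits(plot, "plot_record"), inherits(config, "generator_config"))
  if (config$point_density <= 0) stop("point_density must be > 0", call. = FALSE)
  set.seed(seed)
  side <- plot$side_length
  target <- as.integer(round(config$point_density * side^2))
  tr <- plot$trees
  p2 <- config$interior_fraction
  pg <- config$ground_penetration

  ## crown upper-surface height (above local ground) under pulses at (px, py)
  crown_surface <- function(px, py) {
    zs <- rep(-Inf, length(px))
    for (t in seq_len(nrow(tr))) {
      d2 <- (px - tr$x[t])^2 + (py - tr$y[t])^2
      idx <- which(d2 <= tr$crown_radius[t]^2)
      if (!length(idx)) next
      h <- tr$height[t]; cb <- tr$crown_base_height[t]
      z <- h - (h - cb) * sqrt(d2[idx]) / tr$crown_radius[t]
      zs[idx] <- pmax(zs[idx], z)
    }
    zs
  }

  ## pass 1: canopy fraction under `target` pulses
  f <- if (nrow(tr)) {
    px <- stats::runif(target, 0, side); py <- stats::runif(target, 0, side)
    mean(is.finite(crown_surface(px, py)))
  } else 0
  n_pulse <- max(1L, as.integer(round(target / (1 + (p2 + pg) * f))))

  ## pass 2: the cloud itself
  px <- stats::runif(n_pulse, 0, side)
  py <- stats::runif(n_pulse, 0, side)
  zs <- if (nrow(tr)) crown_surface(px, py) else rep(-Inf, n_pulse)
  canopy <- is.finite(zs)
  zg <- ground_elevation(px, py, config)

  ## first returns: crown surface for canopy pulses, ground otherwise
  z1 <- ifelse(canopy,
               zg + pmax(0.1, zs + stats::rnorm(n_pulse, 0, config$noise_sd)),
               zg + stats::rnorm(n_pulse, 0, 0.3 * config$noise_sd))
  int1 <- ifelse(canopy,
                 pmax(0, stats::rnorm(n_pulse, 60, 10)),
                 pmax(0, stats::rnorm(n_pulse, 30, 5)))
  cls1 <- ifelse(canopy, "vegetation", "ground")

  ## second returns: crown interior, plus canopy-penetrating ground echoes
  ci <- which(canopy & stats::runif(n_pulse) < p2)
  z2 <- zg[ci] + stats::runif(length(ci), 0.4, 1) * zs[ci]
  gi <- which(canopy & stats::runif(n_pulse) < pg)
  z3 <- zg[gi] + stats::rnorm(length(gi), 0, 0.3 * config$noise_sd)

  new_point_cloud(
    x = c(px, px[ci], px[gi]),
    y = c(py, py[ci], py[gi]),
    z = c(z1, z2, z3),
    intensity = c(int1,
                  pmax(0, stats::rnorm(length(ci), 60, 10)),
                  pmax(0, stats::rnorm(length(gi), 30, 5))),
    return_number = c(rep(1L, n_pulse), rep(2L, length(ci)), rep(2L, length(gi))),
    classification = c(cls1, rep("vegetation", length(ci)),
                       rep("ground", length(gi))),
    normalized = FALSE,
    plot_id = plot$plot_id
  )
}

#' Simulate component biomass directly from a fitted model form
#'
#' For model-recovery experiments the biomass "truth" is generated from the
#' component model forms themselves (empirical power form, or the logistic
#' leaf form) with known parameters, a group-level random intercept and
#' residual noise, so that parameter recovery is well-posed. Predictors
#' emulate the study's screening outcome: the 5% cumulative height percentile
#' (`AIH2`) rises with stand age, and leaf area index (`LAI`) varies freely.
#'
#' Default parameter values are the reported above-ground component fit
#' (scale 12.6607, exponents 0.6715 and 0.3724) with residual sd equal to its
#' training RMSE (15.496) and a random-intercept sd of 10% of the scale.
#'
#' @param n_per_group Plots per age group (default the 154-plot design).
#' @param beta Named vector of true fixed effects. For `form = "empirical"`
#'   names `b0, b1, b2`; for `form = "logistic"` names `d0, d1, d2, d3`.
#' @param re_sd Standard deviation of the group random effect added to the
#'   first (scale) parameter. Use 0 for no group effect.
#' @param sigma Residual standard deviation (t/hm^2).
#' @param form `"empirical"` or `"logistic"`.
#' @param group_offsets Optional named-by-group additive offsets on the scale
#'   parameter (for dummy-model recovery experiments); default none.
#' @param seed Integer seed.
#' @return A data frame with columns `y`, `AIH2`, `LAI`, `group` (factor in
#'   developmental order).
#' @export
simulate_component_biomass <- function(n_per_group = c(33, 34, 26, 34, 27),
                                       beta = c(b0 = 12.6607, b1 = 0.6715,
                                                b2 = 0.3724),
                                       re_sd = 1.27,
                                       sigma = 15.496,
                                       form = c("empirical", "logistic"),
                                       group_offsets = NULL,
                                       seed = 1) {
  form <- match.arg(form)
  stopifnot(length(n_per_group) == 5, all(n_per_group >= 0))
  set.seed(seed)
  labels <- age_group_labels()
  grp <- factor(rep(labels, n_per_group), levels = labels)
  n <- length(grp)
  gidx <- as.integer(grp)
  ## AIH2 rises with developmental stage (m); LAI dimensionless
  mu_aih <- c(4, 6, 7.5, 9, 8.5)[gidx]
  AIH2 <- pmax(0.5, stats::rnorm(n, mu_aih, 1.5))
  LAI <- stats::runif(n, 1, 4.5)
  u <- stats::rnorm(5, 0, re_sd)
  off <- rep(0, 5)
  if (!is.null(group_offsets)) off[match(names(group_offsets), labels)] <- group_offsets
  scale_i <- beta[[1]] + u[gidx] + off[gidx]
  mu <- if (form == "empirical") {
    scale_i * AIH2^beta[["b1"]] * LAI^beta[["b2"]]
  } else {
    scale_i / (1 + beta[["d1"]] * exp(-beta[["d2"]] * AIH2 - beta[["d3"]] * LAI))
  }
  data.frame(y = mu + stats::rnorm(n, 0, sigma), AIH2 = AIH2, LAI = LAI,
             group = grp)
}
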