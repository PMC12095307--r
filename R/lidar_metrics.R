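#' Canonical percentile levels and metric names
#'
#' The per-plot feature set comprises 57 variables: 20 height percentiles
#' `h1, h5, h10, ..., h80, h90, h95, h99`; 20 cumulative height percentiles
#' `AIH1 ... AIH20` (sequentially indexed, so `AIH2` is the 5% level); six
#' height statistics (`h_max`, `h_mean`, `h_sd`, `h_cv`, `h_skewness`,
#' `h_kurtosis`); nine intensity deciles `d1 ... d9`; canopy cover `CC` and
#' leaf area index `LAI`.
#'
#' @return `percentile_levels()`: the 20 percentile levels;
#'   `metric_names()`: the 57 canonical metric names, in table order.
#' @export
percentile_levels <- function() {
  c(1, 5, seq(10, 80, by = 5), 90, 95, 99)
}

#' @rdname percentile_levels
#' @export
metric_names <- function() {
  c(paste0("h", percentile_levels()),
    paste0("AIH", seq_along(percentile_levels())),
    c("h_max", "h_mean", "h_sd", "h_cv", "h_skewness", "h_kurtosis"),
    paste0("d", 1:9),
    c("CC", "LAI"))
}

metric_error <- function(msg, plot_id = NA_character_) {
  stop(sprintf("metric error [plot %s]: %s", plot_id, msg), call. = FALSE)
}

#' Terrain-normalize a point cloud
#'
#' Builds a ground surface as the gridded minimum z of ground-classified
#' returns (bilinear interpolation between cell centers; empty cells filled
#' from the nearest non-empty cell) and subtracts it from every return's z.
#' Negative normalized heights are clamped to 0.
#'
#' @param cloud A `point_cloud` with at least one ground-class return.
#' @param grid_size Ground grid cell size (m).
#' @return The normalized `point_cloud` (attribute `normalized = TRUE`).
#' @export
normalize_heights <- function(cloud, grid_size = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (grid_size <= 0) stop("grid_size must be > 0", call. = FALSE)
  gr <- cloud$classification == "ground"
  if (!any(gr)) {
    stop("normalization error: cloud has no ground-class returns",
         call. = FALSE)
  }
  x0 <- min(cloud$x); y0 <- min(cloud$y)
  nx <- max(1L, ceiling((max(cloud$x) - x0) / grid_size))
  ny <- max(1L, ceiling((max(cloud$y) - y0) / grid_size))
  cell_of <- function(u, u0, n) pmin(n, pmax(1L, ceiling((u - u0) / grid_size)))
  gi <- cell_of(cloud$x[gr], x0, nx)
  gj <- cell_of(cloud$y[gr], y0, ny)
  surf <- matrix(NA_real_, nx, ny)
  mins <- tapply(cloud$z[gr], list(gi, gj), min)
  surf[cbind(as.integer(rep(rownames(mins), ncol(mins))),
             as.integer(rep(colnames(mins), each = nrow(mins))))] <- as.vector(mins)

  ## nearest-fill empty cells from non-empty cell centers
  if (anyNA(surf)) {
    filled <- which(!is.na(surf), arr.ind = TRUE)
    empty <- which(is.na(surf), arr.ind = TRUE)
    for (r in seq_len(nrow(empty))) {
      d2 <- (filled[, 1] - empty[r, 1])^2 + (filled[, 2] - empty[r, 2])^2
      surf[empty[r, 1], empty[r, 2]] <- surf[filled[which.min(d2), , drop = FALSE]]
    }
  }

  ## bilinear interpolation at the return locations, between cell centers
  cx <- x0 + (seq_len(nx) - 0.5) * grid_size
  cy <- y0 + (seq_len(ny) - 0.5) * grid_size
  ix <- pmin(nx - 1L, pmax(1L, findInterval(cloud$x, cx)))
  iy <- pmin(ny - 1L, pmax(1L, findInterval(cloud$y, cy)))
  if (nx == 1L) ix <- rep(1L, nrow(cloud))
  if (ny == 1L) iy <- rep(1L, nrow(cloud))
  ix2 <- pmin(nx, ix + 1L); iy2 <- pmin(ny, iy + 1L)
  tx <- if (nx > 1) pmin(1, pmax(0, (cloud$x - cx[ix]) / grid_size)) else 0
  ty <- if (ny > 1) pmin(1, pmax(0, (cloud$y - cy[iy]) / grid_size)) else 0
  z00 <- surf[cbind(ix, iy)]; z10 <- surf[cbind(ix2, iy)]
  z01 <- surf[cbind(ix, iy2)]; z11 <- surf[cbind(ix2, iy2)]
  ground_z <- (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11

  out <- cloud
  out$z <- pmax(0, cloud$z - ground_z)
  attr(out, "normalized") <- TRUE
  out
}

## percentile by linear interpolation between closest ranks (quantile type 7)
interp_percentile <- function(values, levels) {
  if (length(values) < 1) metric_error("empty input to percentile")
  unname(stats::quantile(values, probs = levels / 100, type = 7, names = FALSE))
}

#' Height percentiles
#'
#' Linear-interpolation percentiles (between closest ranks) of the normalized
#' vegetation-return heights.
#'
#' @param heights Numeric vector of normalized heights (m), non-empty.
#' @param levels Percentile levels in percent (default the canonical 20).
#' @return Numeric vector of heights, one per level, non-decreasing in level.
#' @export
height_percentiles <- function(heights, levels = percentile_levels()) {
  interp_percentile(heights, levels)
}

#' Cumulative height percentiles (AIH)
#'
#' Sort the heights ascending and accumulate them; `AIH_X` is the height of
#' the first point at which the running sum reaches X% of the total height
#' sum.
#'
#' @inheritParams height_percentiles
#' @return Numeric vector, one value per level.
#' @export
cumulative_height_percentiles <- function(heights,
                                          levels = percentile_levels()) {
  if (length(heights) < 1) metric_error("empty input to AIH")
  hs <- sort(heights)
  cs <- cumsum(hs)
  total <- cs[length(cs)]
  vapply(levels, function(p) {
    hs[which(cs >= p / 100 * total)[1]]
  }, numeric(1))
}

#' Height distribution statistics
#'
#' Standard deviation uses the n-1 denominator; the coefficient of variation
#' is sd/mean; skewness and kurtosis use the moment definitions
#' m3/m2^(3/2) and m4/m2^2 (central moments with denominator n; kurtosis is
#' not excess-adjusted). For constant input sd and cv are 0 and skewness /
#' kurtosis are undefined (NaN, with a warning).
#'
#' @param heights Numeric vector of at least two heights.
#' @return Named list: `h_max`, `h_mean`, `h_sd`, `h_cv`, `h_skewness`,
#'   `h_kurtosis`.
#' @export
height_statistics <- function(heights) {
  n <- length(heights)
  if (n < 2) metric_error("need >= 2 heights for statistics")
  m <- mean(heights)
  s <- stats::sd(heights)
  m2 <- mean((heights - m)^2)
  if (m2 == 0) {
    warning("constant heights: skewness and kurtosis undefined", call. = FALSE)
    skew <- NaN; kurt <- NaN
  } else {
    skew <- mean((heights - m)^3) / m2^1.5
    kurt <- mean((heights - m)^4) / m2^2
  }
  list(h_max = max(heights), h_mean = m, h_sd = s,
       h_cv = if (m > 0) s / m else NaN,
       h_skewness = skew, h_kurtosis = kurt)
}

#' Intensity percentiles
#'
#' Deciles (10%, 20%, ..., 90%) of vegetation-return intensities, by the same
#' interpolation rule as [height_percentiles()].
#'
#' @param intensities Numeric vector, non-empty.
#' @param levels Levels in percent.
#' @return Numeric vector `d1 ... d9` (for the default levels).
#' @export
intensity_percentiles <- function(intensities, levels = seq(10, 90, by = 10)) {
  interp_percentile(intensities, levels)
}

#' Canopy cover
#'
#' Fraction of first-echo returns whose normalized height exceeds the
#' vegetation cutoff.
#'
#' @param cloud A normalized `point_cloud` with at least one first return.
#' @param cutoff Vegetation height cutoff (m).
#' @return Fraction in `[0, 1]`.
#' @export
canopy_cover <- function(cloud, cutoff = 2) {
  stopifnot(inherits(cloud, "point_cloud"))
  first <- cloud$return_number == 1 & cloud$classification != "noise"
  if (!any(first)) metric_error("no first returns", attr(cloud, "plot_id"))
  mean(cloud$z[first] > cutoff)
}

#' Leaf area index from gap fraction
#'
#' Beer--Lambert inversion of the gap fraction: with GF the share of returns
#' at or below the cutoff, `LAI = -ln(GF) / k` where `k` is the extinction
#' coefficient. GF is clamped to `[1e-6, 1]`, so bare ground gives LAI = 0.
#'
#' @param cloud A normalized `point_cloud`, non-empty.
#' @param cutoff Vegetation height cutoff (m).
#' @param k Extinction coefficient (default 0.5, a spherical leaf-angle
#'   canopy).
#' @return LAI (dimensionless, >= 0).
#' @export
leaf_area_index <- function(cloud, cutoff = 2, k = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"))
  keep <- cloud$classification != "noise"
  if (!any(keep)) metric_error("empty cloud", attr(cloud, "plot_id"))
  gf <- mean(cloud$z[keep] <= cutoff)
  gf <- min(1, max(1e-6, gf))
  -log(gf) / k
}

#' Extract the 57 per-plot feature variables
#'
#' Computes, from a terrain-normalized cloud, the full metric vector listed
#' by [metric_names()]. Height percentiles, cumulative height percentiles and
#' height statistics use returns above the vegetation cutoff (noise excluded);
#' intensity percentiles use the same returns; canopy cover uses first
#' returns and LAI all returns, as defined in their own help pages.
#'
#' @param cloud A `point_cloud`; must be normalized ([normalize_heights()])
#'   and contain at least two returns above the cutoff.
#' @param cutoff Vegetation height cutoff (m); returns at or below it are
#'   treated as ground/understorey.
#' @param k Extinction coefficient for [leaf_area_index()].
#' @return Named numeric vector of length 57.
#' @export
extract_metrics <- function(cloud, cutoff = 2, k = 0.5) {
  stopifnot(inherits(cloud, "point_cloud"))
  pid <- attr(cloud, "plot_id")
  if (!isTRUE(attr(cloud, "normalized"))) {
    metric_error("cloud must be normalized before metric extraction", pid)
  }
  veg <- cloud$classification != "noise" & cloud$z > cutoff
  if (sum(veg) < 2) {
    metric_error(sprintf("fewer than 2 returns above the %.1f m cutoff", cutoff),
                 pid)
  }
  hts <- cloud$z[veg]
  ints <- cloud$intensity[veg]
  stats6 <- height_statistics(hts)
  out <- c(
    height_percentiles(hts),
    cumulative_height_percentiles(hts),
    unlist(stats6),
    intensity_percentiles(ints),
    canopy_cover(cloud, cutoff),
    leaf_area_index(cloud, cutoff, k)
  )
  names(out) <- metric_names()
  out
}

#' Metric table for a set of plots
#'
#' Generates (or accepts) the plot clouds, normalizes them and extracts the
#' 57 metrics for each plot.
#'
#' @param plots List of `plot_record`s.
#' @param config A [generator_config()] used to simulate the clouds.
#' @param seed Master seed for cloud simulation.
#' @param cutoff,k Passed to [extract_metrics()].
#' @param grid_size Passed to [normalize_heights()].
#' @return Data frame with `plot_id`, `age_group` and 57 metric columns.
#' @export
extract_metrics_table <- function(plots, config = generator_config(), seed = 1,
                                  cutoff = 2, k = 0.5, grid_size = 2) {
  set.seed(seed)
  cloud_seeds <- sample.int(.Machine$integer.max - 1L, length(plots))
  rows <- vector("list", length(plots))
  for (i in seq_along(plots)) {
    cl <- generate_point_cloud(plots[[i]], config, seed = cloud_seeds[i])
    cl <- normalize_heights(cl, grid_size = grid_size)
    m <- extract_metrics(cl, cutoff = cutoff, k = k)
    rows[[i]] <- cbind(
      data.frame(plot_id = plots[[i]]$plot_id,
                 age_group = plots[[i]]$age_group,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(m)))
  }
  do.call(rbind, rows)
}
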