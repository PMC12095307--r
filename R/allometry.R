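#' Allometric coefficients for above- and under-ground biomass
#'
#' The component system predicts above-ground biomass as
#' `a1 * D^b1 * H^c1` (kg) and under-ground biomass as `a2 * D^b2 * H^c2`,
#' with D in cm and H in m. The power-law coefficients are configuration:
#' the defaults below were calibrated once against the per-group stand
#' biomass envelopes the generator emulates (34.8--469.6 t/hm^2 above ground)
#' and are used by the synthetic generator and tests; substitute regionally
#' fitted values for real inventories.
#'
#' @param a1,b1,c1 Above-ground power law: scale (kg), DBH exponent, height
#'   exponent.
#' @param a2,b2,c2 Under-ground power law.
#' @return An object of class `allometric_coefficients`.
#' @export
allometric_coefficients <- function(a1 = 0.073, b1 = 1.7, c1 = 1.0,
                                    a2 = 0.010, b2 = 1.85, c2 = 0.8) {
  if (a1 <= 0 || a2 <= 0) stop("scale coefficients a1, a2 must be > 0",
                               call. = FALSE)
  structure(list(a1 = a1, b1 = b1, c1 = c1, a2 = a2, b2 = b2, c2 = c2),
            class = "allometric_coefficients")
}

#' Bark, branch and leaf ratio functions
#'
#' Ratios of bark, branch and leaf biomass to trunk biomass as power
#' functions of stand mean DBH `D` (cm) and mean height `H` (m):
#' \deqn{g_1 = 0.37301\,H^{-0.29282}}
#' \deqn{g_2 = 0.80058\,D^{0.79098}\,H^{-1.29690}}
#' \deqn{g_3 = 3.23395\,D^{0.48038}\,H^{-1.71324}}
#'
#' @param D DBH (cm), > 0. Vectorized.
#' @param H Height (m), > 0.
#' @return A list with numeric components `g1`, `g2`, `g3` (dimensionless,
#'   all > 0).
#' @examples
#' ratio_functions(15, 11)
#' @export
ratio_functions <- function(D, H) {
  if (any(D <= 0) || any(H <= 0)) {
    stop("D and H must be > 0", call. = FALSE)
  }
  list(
    g1 = 0.37301 * H^-0.29282,
    g2 = 0.80058 * D^0.79098 * H^-1.29690,
    g3 = 3.23395 * D^0.48038 * H^-1.71324
  )
}

#' Component biomass of a single tree
#'
#' Above-ground biomass follows the power law `a1 * D^b1 * H^c1`, and is
#' partitioned into trunk, bark, branch and leaf with the
#' [ratio_functions()]: trunk = AGB / (1 + g1 + g2 + g3), bark = g1 * trunk,
#' branch = g2 * trunk, leaf = g3 * trunk, so the four parts sum exactly to
#' the above-ground total. Under-ground biomass is a separate power law.
#'
#' @param D DBH (cm), > 0. Vectorized over trees.
#' @param H Height (m), > 0.
#' @param coeffs An [allometric_coefficients()] object.
#' @return An object of class `biomass_components`: a data frame with columns
#'   `trunk`, `bark`, `branch`, `leaf`, `above_ground`, `under_ground` (kg per
#'   tree).
#' @export
tree_biomass <- function(D, H, coeffs = allometric_coefficients()) {
  stopifnot(inherits(coeffs, "allometric_coefficients"))
  g <- ratio_functions(D, H)
  agb <- coeffs$a1 * D^coeffs$b1 * H^coeffs$c1
  denom <- 1 + g$g1 + g$g2 + g$g3
  trunk <- agb / denom
  out <- data.frame(
    trunk = trunk,
    bark = g$g1 * trunk,
    branch = g$g2 * trunk,
    leaf = g$g3 * trunk,
    above_ground = agb,
    under_ground = coeffs$a2 * D^coeffs$b2 * H^coeffs$c2
  )
  class(out) <- c("biomass_components", "data.frame")
  out
}

#' Per-hectare component biomass of a plot
#'
#' Sums [tree_biomass()] over the plot's tree list and converts to t/hm^2
#' (kg to tonnes, area scaled by 10000 / side^2). The partition identity
#' (trunk + bark + branch + leaf = above-ground) is preserved by linearity.
#'
#' @param plot A `plot_record`.
#' @param coeffs An [allometric_coefficients()] object.
#' @return One-row `biomass_components` data frame in t/hm^2. A plot with no
#'   trees yields all-zero components.
#' @export
plot_biomass <- function(plot, coeffs = allometric_coefficients()) {
  stopifnot(inherits(plot, "plot_record"))
  if (plot$side_length <= 0) stop("plot area must be > 0", call. = FALSE)
  comp_names <- c("trunk", "bark", "branch", "leaf", "above_ground",
                  "under_ground")
  if (nrow(plot$trees) == 0) {
    out <- as.data.frame(as.list(stats::setNames(numeric(6), comp_names)))
  } else {
    per_tree <- tree_biomass(plot$trees$dbh, plot$trees$height, coeffs)
    scale <- 1 / 1000 * 10000 / plot$side_length^2  # kg/plot -> t/hm^2
    out <- as.data.frame(lapply(per_tree, function(v) sum(v) * scale))
  }
  class(out) <- c("biomass_components", "data.frame")
  out
}

#' Component biomass table for a set of plots
#'
#' @param plots List of `plot_record`s.
#' @param coeffs An [allometric_coefficients()] object.
#' @return Data frame with `plot_id`, `age_group` and the six component
#'   columns (t/hm^2), one row per plot.
#' @export
plot_biomass_table <- function(plots, coeffs = allometric_coefficients()) {
  rows <- lapply(plots, function(p) {
    cbind(data.frame(plot_id = p$plot_id, age_group = p$age_group,
                     stringsAsFactors = FALSE),
          as.data.frame(plot_biomass(p, coeffs)))
  })
  do.call(rbind, rows)
}
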