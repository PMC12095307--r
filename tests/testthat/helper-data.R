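# Small-scale fixtures built in code. Unit tests use reduced plot sides and
# point densities; the generator's full-scale defaults are exercised by the
# acceptance suite where the design counts matter.

tiny_config <- function(...) {
  generator_config(plots_per_group = c(2, 2, 2, 2, 2), side_length = 15,
                   point_density = 25, ...)
}

# a hand-built normalized cloud for metric unit tests
make_cloud <- function(z, intensity = seq_along(z), return_number = 1L,
                       classification = "vegetation", normalized = TRUE) {
  n <- length(z)
  point_cloud(x = seq_len(n), y = rep(1, n), z = z, intensity = intensity,
              return_number = return_number, classification = classification,
              normalized = normalized, plot_id = "test")
}

# plot record with no trees (bare ground)
bare_plot <- function(side = 15) {
  p <- generate_stand("young", tiny_config(), seed = 1)
  p$trees <- p$trees[0, ]
  p$side_length <- side
  p$stand_density <- 0
  p$plot_id <- "bare"
  p
}
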