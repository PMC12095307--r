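#' Write / read a point cloud as a plain-text XYZI table
#'
#' Whitespace-separated columns `x y z intensity return class` with a header
#' line; `class` is the classification label. Intended for small fixtures and
#' interchange; the format round-trips through [read_xyzi()].
#'
#' @param cloud A `point_cloud`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyzi <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  df <- data.frame(
    x = cloud$x, y = cloud$y, z = cloud$z,
    intensity = cloud$intensity,
    return_number = cloud$return_number,
    classification = as.character(cloud$classification)
  )
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xyzi
#' @param normalized Whether the stored heights are terrain-normalized.
#' @param plot_id Plot identifier to attach.
#' @export
read_xyzi <- function(path, normalized = FALSE, plot_id = NA_character_) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  new_point_cloud(df$x, df$y, df$z, df$intensity, df$return_number,
                  df$classification, normalized = normalized,
                  plot_id = plot_id)
}

#' Write plot and tree tables as CSV
#'
#' `write_tree_table()` writes one row per tree (`plot_id`, `dbh_cm`,
#' `height_m`, `x_m`, `y_m`, `crown_radius_m`, `crown_base_height_m`);
#' `write_plot_table()` writes one row per plot (`plot_id`, `age_group`,
#' `side_length_m`, `n_trees`, `stand_density`, `mean_dbh_cm`,
#' `mean_height_m`).
#'
#' @param plots List of `plot_record`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(plots, path) {
  rows <- lapply(plots, function(p) {
    if (nrow(p$trees) == 0) return(NULL)
    data.frame(plot_id = p$plot_id,
               dbh_cm = p$trees$dbh, height_m = p$trees$height,
               x_m = p$trees$x, y_m = p$trees$y,
               crown_radius_m = p$trees$crown_radius,
               crown_base_height_m = p$trees$crown_base_height)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_table
#' @export
write_plot_table <- function(plots, path) {
  rows <- lapply(plots, function(p) {
    data.frame(plot_id = p$plot_id, age_group = p$age_group,
               side_length_m = p$side_length, n_trees = nrow(p$trees),
               stand_density = p$stand_density, mean_dbh_cm = p$mean_dbh,
               mean_height_m = p$mean_height)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
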