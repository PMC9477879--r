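# ggplot2 views of the core objects. Axes are microns in the image frame,
# so the y axis is reversed to match how the section is scanned.

region_fill_scale <- function() {
  ggplot2::scale_fill_manual(
    values = c(
      synchronous_DCIS = "#d73027", IDC = "#1a9850",
      mixed = "#fee08b", excluded = "grey80", whole_section = "#74add1"
    ),
    na.value = "grey90", drop = TRUE
  )
}

#' Plot a typed Voronoi partition
#'
#' Draws the Voronoi quadrats coloured by region type (red synchronous
#' DCIS, green IDC, yellow mixed, grey excluded), optionally with duct
#' outlines and cells overlaid.
#'
#' @param object A `region_partition` (typed via [classify_polygons()] or
#'   not).
#' @param ducts Optional [duct_mask()] drawn as outlines.
#' @param show_cells Overlay the cells, coloured by class.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_partition <- function(object, ducts = NULL, show_cells = FALSE, ...) {
  poly_df <- purrr::imap_dfr(object$polygons, function(p, i) {
    tibble(polygon_id = i, x_um = p[, 1], y_um = p[, 2])
  }) |>
    left_join(object$regions[, c("polygon_id", "region_type")], by = "polygon_id")
  gg <- ggplot2::ggplot(poly_df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_polygon(
      ggplot2::aes(group = .data$polygon_id, fill = .data$region_type),
      colour = "white", linewidth = 0.3, alpha = 0.8
    ) +
    region_fill_scale() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)", fill = "region",
      title = paste("Voronoi quadrats -", object$section_id)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(ducts) && length(ducts$polygons) > 0) {
    duct_df <- tidy.duct_mask(ducts)
    gg <- gg + ggplot2::geom_path(
      data = duct_df,
      ggplot2::aes(group = interaction(.data$polygon, .data$ring)),
      colour = "black", linewidth = 0.4
    )
  }
  if (show_cells) {
    gg <- gg + ggplot2::geom_point(
      data = object$cells,
      ggplot2::aes(colour = .data$cell_class),
      size = 0.3, alpha = 0.6
    )
  }
  gg
}

#' Plot a synthetic or real tissue section
#'
#' Cells coloured by class over the duct outlines.
#'
#' @param cells A [cell_map()].
#' @param ducts Optional [duct_mask()].
#' @return A ggplot object.
#' @export
plot_section <- function(cells, ducts = NULL) {
  gg <- ggplot2::ggplot(as_tibble(cells), ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cell_class), size = 0.4, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      CA9_pos_epithelial = "#d73027", CA9_neg_epithelial = "#fc8d59",
      FOXP3_pos_lymphocyte = "#542788", FOXP3_neg_lymphocyte = "#998ec3",
      stroma = "grey70"
    )) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)", colour = "class",
      title = section_id_of(cells)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(ducts) && length(ducts$polygons) > 0) {
    gg <- gg + ggplot2::geom_path(
      data = tidy.duct_mask(ducts),
      ggplot2::aes(group = interaction(.data$polygon, .data$ring)),
      colour = "black", linewidth = 0.4
    )
  }
  gg
}

#' Plot per-group colocalization indices
#'
#' Boxplots of Morisita-Horn indices by group, one facet per class pair —
#' the standard view for comparing pure DCIS, synchronous DCIS and IDC
#' components.
#'
#' @param coloc The `colocalization` tibble of a [run_pipeline()] result
#'   (needs `mh_index`, `class_a`, `class_b` and a `group` column).
#' @return A ggplot object.
#' @export
plot_colocalization <- function(coloc) {
  d <- filter(coloc, !.data$insufficient_data)
  d$pair <- paste(
    sub("_lymphocyte", "", d$class_a), "/",
    sub("_epithelial", "", d$class_b)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$mh_index, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    region_fill_scale() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = NULL, y = "Morisita-Horn index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none", axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  }
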