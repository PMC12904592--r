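#' Plot the rule trend: windowed phenotypic vs developmental similarity
#'
#' @param profiles Profile tibble with `median_simD`, `median_simP`.
#' @param window Sliding-window size.
#' @return A ggplot: per-gene scatter with the windowed trend line.
#' @export
plot_dp_trend <- function(profiles, window = 100L) {
  trend <- sliding_window_trend(profiles, min(window, nrow(profiles)))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$median_simD, y = .data$median_simP)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(data = trend,
                       ggplot2::aes(x = .data$mean_simD, y = .data$mean_simP),
                       color = "#d1495b", linewidth = 1) +
    ggplot2::labs(x = "median developmental similarity ⟨simD⟩",
                  y = "median phenotypic similarity ⟨simP⟩") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quintile_contingency <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$developmental_class,
                                   y = .data$phenotypic_class,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2e6f95") +
    ggplot2::labs(x = "developmental percentile class",
                  y = "phenotypic percentile class", fill = "fraction") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mediator_result <- function(object, mask_nonsignificant = TRUE, ...) {
  df <- tidy(object)
  if (mask_nonsignificant) df$ks[!df$significant] <- 0
  ord <- cluster_heatmap(object)
  df$cell_type <- factor(df$cell_type, levels = ord$row_order)
  df$component <- factor(df$component, levels = ord$col_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$cell_type,
                                   fill = .data$ks)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#1b4332") +
    ggplot2::labs(x = "latent phenotype component", y = "cell type",
                  fill = "KS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.coordinate_enrichment <- function(object, ...) {
  df <- tidyr::separate(object, "coordinate", into = c("cell_type", "stage"),
                        sep = "\\|", remove = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$cell_type,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$top, ], shape = 21, size = 1.5,
                        fill = "#80b918") +
    ggplot2::scale_fill_gradient2(low = "#2e6f95", mid = "white",
                                  high = "#d1495b") +
    ggplot2::labs(x = "embryonic stage", y = "cell type", fill = "z") +
    ggplot2::theme_minimal()
}

#' Density plot of pleiotropy scores by rule class
#'
#' @param class_pleio A `class_pleiotropy` object.
#' @return A ggplot of the kernel-density curves with class medians.
#' @export
plot_class_pleiotropy <- function(class_pleio) {
  stopifnot(inherits(class_pleio, "class_pleiotropy"))
  dens <- dplyr::bind_rows(class_pleio$densities, .id = "rule_class")
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$score, y = .data$density,
                                     color = .data$rule_class)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::geom_vline(data = class_pleio$summary,
                        ggplot2::aes(xintercept = .data$median,
                                     color = .data$rule_class),
                        linetype = "dashed") +
    ggplot2::labs(x = "pleiotropy score", y = "density", color = "class") +
    ggplot2::theme_minimal()
}
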