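# ggplot2 visualizations for alignments, shape models and risk models.

#' Plot aligned outlines with the mean shape
#'
#' @param object A `gpa_alignment`.
#' @param max_shapes Plot at most this many individual outlines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpa_alignment <- function(object, max_shapes = 50, ...) {
  td <- tidy(object)
  ids <- unique(td$subject_id)
  if (length(ids) > max_shapes) {
    td <- dplyr::filter(td, .data$subject_id %in% ids[seq_len(max_shapes)])
  }
  mean_df <- landmark_tibble(object$mean_shape, subject_id = "mean")
  ggplot2::ggplot(td, ggplot2::aes(.data$x, .data$y, group = .data$subject_id)) +
    ggplot2::geom_path(alpha = 0.2, colour = "grey40") +
    ggplot2::geom_path(data = mean_df, colour = "firebrick", linewidth = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Procrustes-aligned outlines",
      subtitle = "mean shape in red", x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Mode-of-variation gallery plot
#'
#' Outlines reconstructed at each SD value along the requested modes,
#' overlaid on the mean shape, one facet per mode.
#'
#' @param model A [shape_pca()] fit.
#' @param modes Mode indices (default all retained).
#' @param sd_values SD grid (default -2, 0, +2).
#' @return A ggplot object.
#' @export
plot_mode_gallery <- function(model, modes = seq_len(model$n_modes),
                              sd_values = c(-2, 0, 2)) {
  df <- purrr::map_dfr(modes, mode_gallery, model = model, sd_values = sd_values)
  df$sd_label <- factor(paste0(ifelse(df$sd > 0, "+", ""), df$sd, " SD"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
    group = .data$sd_label, colour = .data$sd_label
  )) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~mode, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = NULL, x = NULL, y = NULL,
      title = "Modes of variation"
    ) +
    ggplot2::theme_minimal()
}

#' @param object A `shape_model`.
#' @param ... Passed to [plot_mode_gallery()].
#' @rdname plot_mode_gallery
#' @export
autoplot.shape_model <- function(object, ...) {
  plot_mode_gallery(object, ...)
}

#' Scree plot of a shape model's eigenvalue spectrum
#'
#' @param model A [shape_pca()] fit.
#' @return A ggplot object.
#' @export
plot_scree <- function(model) {
  td <- tidy(model)
  ggplot2::ggplot(td, ggplot2::aes(.data$mode, .data$variance_fraction)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$retained), show.legend = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_fraction)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey70")) +
    ggplot2::labs(
      x = "mode", y = "variance fraction",
      title = "Eigenvalue spectrum", subtitle = "line: cumulative fraction"
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of a fracture-risk model
#'
#' @param object A `fracture_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fracture_fit <- function(object, ...) {
  p <- fitted(object)
  y <- as.logical(object$fit$y)
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  roc <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(
      fpr = mean(p[!y] >= t),
      tpr = mean(p[y] >= t)
    )
  })
  g <- glance(object)
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      title = sprintf("AUROC %.3f (95%% CI %.3f-%.3f)", g$auroc, g$conf_low, g$conf_high)
    ) +
    ggplot2::theme_minimal()
}
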