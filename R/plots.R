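# ggplot2 visualisations for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation report as a confusion-matrix heatmap
#'
#' @param object a `switchnet_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot switchnet_eval
#' @export
autoplot.switchnet_eval <- function(object, ...) {
  cm <- object$confusion
  df <- tidyr::expand_grid(true = seq_len(nrow(cm)) - 1L,
                           pred = seq_len(ncol(cm)) - 1L)
  df$count <- as.vector(t(cm))[df$true * ncol(cm) + df$pred + 1L]
  df$true_name <- factor(object$class_names[df$true + 1L],
                         levels = rev(object$class_names))
  df$pred_name <- factor(object$class_names[df$pred + 1L],
                         levels = object$class_names)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred_name, .data$true_name,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("accuracy %.3f, mAP %.3f",
                                  object$accuracy, object$mAP)) +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Loss, validation accuracy and the mean information-switching weight
#' alpha per epoch.
#'
#' @param object a `switchnet_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot switchnet_fit
#' @export
autoplot.switchnet_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_accuracy",
                                          "mean_alpha"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Plot an ablation comparison
#'
#' @param object a `switchnet_ablation`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot switchnet_ablation
#' @export
autoplot.switchnet_ablation <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(.data$variant, .data$val_accuracy)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$seed)), size = 2) +
    ggplot2::labs(color = "seed", y = "best validation accuracy",
                  title = sprintf("information switching gap: %.3f",
                                  object$accuracy_gap)) +
    ggplot2::theme_minimal()
}

#' Plot Grad-CAM heatmaps
#'
#' @param object a `switchnet_cam`.
#' @param ... unused.
#' @return a ggplot object with one facet per modality.
#' @method autoplot switchnet_cam
#' @export
autoplot.switchnet_cam <- function(object, ...) {
  dfs <- lapply(names(object$heatmaps), function(nm) {
    hm <- object$heatmaps[[nm]]
    tibble::tibble(
      modality = nm,
      row = rep(seq_len(nrow(hm)), times = ncol(hm)),
      col = rep(seq_len(ncol(hm)), each = nrow(hm)),
      value = as.vector(hm)
    )
  })
  df <- dplyr::bind_rows(dfs)
  df$modality <- factor(df$modality, levels = names(object$heatmaps))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~modality, nrow = 1) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "activation")
}
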