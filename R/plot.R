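# ggplot2 displays for slices, heatmaps, masks and CV results.

raster_df <- function(m, value = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value := as.vector(m)
  )
}

#' Plot a synthetic or loaded RCM slice
#'
#' Grayscale image with the ground-truth lesion mask outlined.
#'
#' @param object An `rcm_slice`.
#' @param show_mask Overlay the lesion mask?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rcm_slice <- function(object, show_mask = TRUE, ...) {
  df <- raster_df(object$image, "intensity")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s / %s / slice %d", object$case_id,
                                  object$stack_id, object$slice_index),
                  x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (show_mask && sum(object$mask) > 0) {
    mdf <- raster_df(object$mask, "mask")
    p <- p + ggplot2::geom_contour(
      data = mdf, ggplot2::aes(z = .data$mask), breaks = 0.5,
      colour = "red", linewidth = 0.4)
  }
  p
}

#' Plot a probability heatmap
#'
#' Malignant-channel probability field.
#'
#' @param object An `rcm_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rcm_heatmap <- function(object, ...) {
  df <- raster_df(object$prob[, , 2], "p_malignant")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$p_malignant)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "p(malignant)") +
    ggplot2::theme_minimal()
}

#' Plot a binary segmentation mask
#'
#' @param mask Binary 0/1 matrix.
#' @return A ggplot.
#' @export
plot_mask <- function(mask) {
  check_binary_matrix(mask, "mask")
  df <- raster_df(mask, "lesion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$lesion))) +
    ggplot2::scale_fill_manual(values = c(`0` = "grey10", `1` = "red")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "mask") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' Sensitivity and specificity per fold with the pooled values as dashed
#' lines.
#'
#' @param object An `rcm_cv` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rcm_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  pooled <- tibble::tibble(
    metric = c("sensitivity", "specificity"),
    value = c(object$pooled_metrics$sensitivity,
              object$pooled_metrics$specificity))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = pooled,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
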