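#' Display a grayscale image matrix
#'
#' Convenience wrapper around [graphics::image()] with the row/column
#' orientation used throughout the package (row 1 at the top).
#'
#' @param img Numeric intensity matrix (or 0/1 mask).
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return `img`, invisibly.
#' @export
plot_gray_image <- function(img, main = "", ...) {
  graphics::image(t(img[rev(seq_len(nrow(img))), , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(img) / ncol(img), main = main, ...)
  invisible(img)
}

#' Loss curves of a fitted classifier
#'
#' @param object An `ann_fit`.
#' @param ... Unused.
#' @return A ggplot of training and validation loss against epoch, with the
#'   best-validation epoch marked.
#' @method autoplot ann_fit
#' @export
autoplot.ann_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_loss, set = "training"),
    data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map with counts printed per cell.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
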