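# ggplot2 visualisation helpers.

#' Plot a slice with mask / prediction contours
#'
#' @param img HxW image matrix in [0,1].
#' @param mask Optional binary ground-truth mask.
#' @param pred Optional binary predicted mask.
#' @return A ggplot object (grayscale raster; truth in green, prediction
#'   in red).
#' @export
plot_slice <- function(img, mask = NULL, pred = NULL) {
  as_df <- function(m, what) {
    d <- dim(m)
    data.frame(row = rep(seq_len(d[1]), d[2]),
               col = rep(seq_len(d[2]), each = d[1]),
               value = as.vector(m), layer = what)
  }
  df <- as_df(img, "image")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
  if (!is.null(mask) && any(mask > 0)) {
    dm <- as_df(mask, "truth")
    p <- p + ggplot2::geom_tile(data = dm[dm$value > 0, ],
                                fill = NA, colour = "green3",
                                linewidth = 0.2)
  }
  if (!is.null(pred) && any(pred > 0)) {
    dp <- as_df(pred, "pred")
    p <- p + ggplot2::geom_tile(data = dp[dp$value > 0, ],
                                fill = NA, colour = "red",
                                linewidth = 0.2)
  }
  p
}

#' Training-curve plot
#'
#' @param object An `attunet_train_log` (the `log` element of an
#'   `attunet_fit`).
#' @param ... Unused.
#' @return A ggplot object with train/validation loss and validation Dice
#'   over epochs.
#' @export
autoplot.attunet_train_log <- function(object, ...) {
  df <- rbind(
    data.frame(epoch = object$epoch, value = object$train_loss,
               series = "train loss"),
    data.frame(epoch = object$epoch, value = object$val_loss,
               series = "validation loss"),
    data.frame(epoch = object$epoch, value = object$val_dice,
               series = "validation dice"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_epoch"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
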