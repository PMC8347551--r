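#' Plot training history
#'
#' Dice training loss and validation Jaccard/Dice per epoch.
#'
#' @param object a `facnet_fit`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.facnet_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$loss, series = "train Dice loss"),
    tibble::tibble(epoch = h$epoch, value = h$val_ja, series = "val Jaccard"),
    tibble::tibble(epoch = h$epoch, value = h$val_dc, series = "val Dice")
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "FAC-Net training history") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Per-image metric distributions with the per-image mean marked.
#'
#' @param object a `facnet_eval`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.facnet_eval <- function(object, ...) {
  cols <- c("acc", "se", "sp", "pc", "ja", "dc")
  long <- purrr::map_dfr(cols, function(cl) {
    tibble::tibble(metric = toupper(cl), value = object$per_image[[cl]])
  })
  means <- purrr::map_dfr(cols, function(cl) {
    tibble::tibble(metric = toupper(cl), value = object$mean[[cl]])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_point(data = means, colour = "red", size = 2) +
    ggplot2::labs(x = NULL, y = NULL, title = "Segmentation metrics",
                  subtitle = "red: per-image mean") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Show an image, its mask, and optionally a prediction
#'
#' @param sample a `segmentation_sample`.
#' @param pred optional probability or binary map `c(1, H, W)`.
#' @return a ggplot object (grayscale image with mask/prediction contours).
#' @export
plot_sample <- function(sample, pred = NULL) {
  gray <- apply(sample$image, c(2, 3), mean)
  H <- nrow(gray)
  df <- tibble::tibble(
    h = rep(seq_len(H), times = ncol(gray)),
    w = rep(seq_len(ncol(gray)), each = H),
    value = as.vector(gray),
    mask = as.vector(sample$mask[1, , ])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$w, -.data$h)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "green", linewidth = 0.4) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sample$id)
  if (!is.null(pred)) {
    df$pred <- as.vector(pred[1, , ])
    p <- p + ggplot2::geom_contour(data = df, ggplot2::aes(z = .data$pred),
                                   breaks = 0.5, colour = "red",
                                   linewidth = 0.4)
  }
  p
}
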