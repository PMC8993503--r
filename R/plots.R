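# ggplot2 views of the main result types.

#' Plot a labelled 12-lead signal
#'
#' Faceted trace with the wave-class labels shown as a coloured rug along
#' the baseline.
#'
#' @param object An `ecg_signal`.
#' @param leads Leads to show (default all 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ecg_signal <- function(object, leads = ecg_leads(), ...) {
  df <- as_tibble(object)
  df <- df[df$lead %in% leads, ]
  classes <- wave_classes()
  df$class <- factor(classes$class[df$label + 1L], levels = classes$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_rug(
      data = df[df$label != 0L, ],
      ggplot2::aes(colour = .data$class), sides = "b", length = ggplot2::unit(0.06, "npc")
    ) +
    ggplot2::facet_wrap(~lead, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "mV", colour = "wave class",
                  title = sprintf("%s / %s", object$rhythm, object$phenotype)) +
    ggplot2::theme_minimal()
}

#' Plot a rendered ECG with its mask overlay
#'
#' @param object An `ecg_render`.
#' @param show_mask Overlay the non-background mask pixels in colour.
#' @param ... Unused.
#' @return A ggplot object (raster-based; large images downsample poorly in
#'   vector devices).
#' @export
autoplot.ecg_render <- function(object, show_mask = TRUE, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  df <- tibble::tibble(
    col = rep(seq_len(w), each = h),
    row = rep(seq_len(h), times = w),
    fill = grDevices::rgb(img[, , 1] / 255, img[, , 2] / 255, img[, , 3] / 255)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_mask) {
    classes <- wave_classes()
    idx <- which(object$mask != 0L, arr.ind = TRUE)
    mdf <- tibble::tibble(
      row = idx[, 1], col = idx[, 2],
      class = factor(classes$class[object$mask[idx] + 1L],
                     levels = classes$class)
    )
    p <- p +
      ggplot2::geom_point(data = mdf, size = 0.1,
                          ggplot2::aes(colour = .data$class)) +
      ggplot2::labs(colour = "wave class")
  }
  p
}

#' Plot the threshold-fitting F1 surface
#'
#' @param object A fitted [fit_thresholds()] object (with its `grid`).
#' @param ... Unused.
#' @return A ggplot heat map of validation F1 over the X x Y lattice with
#'   the selected pair marked.
#' @export
autoplot.af_thresholds <- function(object, ...) {
  if (is.null(object$grid)) {
    stop_ecgforge("No search grid stored on this object.", "ecgforge_invalid_argument")
  }
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$x, y = .data$y,
                                            fill = .data$f1)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$x_min_p_fraction, y = object$y_rr_sd,
                      shape = 4, size = 3, colour = "red") +
    ggplot2::labs(x = "X (min P-preceded fraction)", y = "Y (R-R sd, ms)",
                  fill = "F1") +
    ggplot2::theme_minimal()
}
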