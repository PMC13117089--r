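frame_to_tibble <- function(pixels) {
  tibble::tibble(
    col = rep(seq_len(ncol(pixels)), each = nrow(pixels)),
    row = rep(seq_len(nrow(pixels)), ncol(pixels)),
    intensity = as.vector(pixels))
}

#' Plot a detection overlay
#'
#' Renders the analysed ROI in grayscale with a cross at the selected stone
#' and a rectangle around the extracted posterior shadow region (the same
#' markers used in clinical overlay figures). Depth increases downward.
#'
#' @param object A `stone_detection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stone_detection <- function(object, ...) {
  img <- object$roi_image
  dr <- object$roi$row0 - 1L
  dc <- object$roi$col0 - 1L
  df <- frame_to_tibble(img$pixels)
  df$col <- df$col + dc
  df$row <- df$row + dr
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "SIU") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (px)", y = "depth (px)",
                  title = sprintf("%s: %s", object$source_id, object$status)) +
    ggplot2::theme_minimal()
  if (object$status == "detected") {
    p <- p + ggplot2::annotate("point", x = object$winner$xc,
                               y = object$winner$yc, shape = 3, size = 4,
                               colour = "red", stroke = 1.2)
    if (!is.null(object$shadow_roi)) {
      b <- object$shadow_roi
      p <- p + ggplot2::annotate("rect",
        xmin = b$col0 - 0.5, xmax = b$col0 + b$n_cols - 0.5,
        ymin = b$row0 - 0.5, ymax = b$row0 + b$n_rows - 0.5,
        colour = "yellow", fill = NA, linewidth = 0.6)
    }
  }
  p
}

#' Plot the axial shadow profiles
#'
#' Centre profile PC(y) and lateral reference PL(y) against depth, with the
#' steepest-drop and steepest-rise rows marked. A genuine stone shows PC
#' falling well below PL right beneath the candidate.
#'
#' @param object A `shadow_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shadow_profile <- function(object, ...) {
  ys <- object$y_start + seq_len(object$valid_rows) - 1L
  df <- tibble::tibble(
    depth = rep(ys, 2L),
    value = c(object$pc, object$pl),
    profile = rep(c("centre PC", "lateral PL"), each = object$valid_rows))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$value,
                                        colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (row)", y = "intensity (SIU)") +
    ggplot2::theme_minimal()
  if (!is.na(object$i_drop)) {
    p <- p + ggplot2::geom_vline(xintercept = object$y_start + object$i_drop - 1L,
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.na(object$i_rise)) {
    p <- p + ggplot2::geom_vline(xintercept = object$y_start + object$i_rise - 1L,
                                 linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot ablation accuracies
#'
#' Accuracy per score variant, one line per confidence group — the visual
#' analogue of the ablation table.
#'
#' @param object An `ablation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ablation_result <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = .data$variant, y = .data$accuracy,
                               colour = .data$group_label,
                               group = .data$group_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "score variant", y = "acceptance accuracy",
                  colour = "confidence group") +
    ggplot2::theme_minimal()
}
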