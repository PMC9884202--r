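# ggplot2 views of the main result types.

#' Plot a localization field
#'
#' @param locs Localization tibble; points are coloured by `label` when
#'   present.
#' @param point_size Point size.
#' @return A ggplot.
#' @export
plot_field <- function(locs, point_size = 0.3) {
  p <- ggplot2::ggplot(locs, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if ("label" %in% names(locs)) {
    p + ggplot2::geom_point(
      ggplot2::aes(colour = .data$label),
      size = point_size, alpha = 0.6
    ) +
      ggplot2::scale_colour_manual(
        values = c(object = "magenta4", noise = "cyan4", unknown = "grey50")
      )
  } else {
    p + ggplot2::geom_point(size = point_size, alpha = 0.6, colour = "grey20")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sarcloc_image <- function(object, ...) {
  df <- expand.grid(
    ix = seq_len(nrow(object$intensity)),
    iy = seq_len(ncol(object$intensity))
  )
  df$value <- as.vector(object$intensity)
  df$x <- object$origin[1] + (df$ix - 0.5) * object$pixel_size
  df$y <- object$origin[2] + (df$iy - 0.5) * object$pixel_size
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sarcloc_mlp <- function(object, ...) {
  hist <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "series", values_to = "loss"
  )
  ggplot2::ggplot(
    dplyr::filter(hist, !is.na(.data$loss)),
    ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}

#' Class-averaged feature profiles
#'
#' The two diagnostic curves for a labelled feature table: the mean sorted
#' neighbour-distance curve per class (object localizations sit in denser
#' surroundings, so their curve lies below the noise curve at small ranks)
#' and the mean aligned direction histogram per class (object localizations
#' show a major peak with a minor peak at 90 degrees; noise shows one broad
#' peak).
#'
#' @param features Feature tibble from [featurize()].
#' @param labels Truth labels aligned with `features` rows.
#' @param which `"distances"` or `"directions"`.
#' @return A ggplot.
#' @export
plot_feature_profiles <- function(features, labels,
                                  which = c("distances", "directions")) {
  which <- match.arg(which)
  cols <- feature_cols(which)
  X <- as.matrix(features[cols])
  df <- purrr::map_dfr(unique(labels), function(l) {
    tibble(
      label = l, index = seq_along(cols),
      value = colMeans(X[labels == l, , drop = FALSE])
    )
  })
  xlab <- if (which == "distances") "neighbour rank" else "direction bin"
  ylab <- if (which == "distances") "mean distance (nm)" else "mean frequency"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$index, y = .data$value,
    colour = .data$label
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot detected boxes over a localization field
#'
#' @param locs Localization tibble.
#' @param rois List of `sarcloc_roi` objects; detection boxes drawn red,
#'   analysis boxes yellow.
#' @return A ggplot.
#' @export
plot_rois <- function(locs, rois) {
  box_df <- function(getter, kind) {
    purrr::imap_dfr(rois, function(r, i) {
      b <- r[[getter]]
      tibble(roi = i, xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4],
        kind = kind)
    })
  }
  boxes <- bind_rows(
    box_df("detect_box", "detect"),
    box_df("analysis_box", "analysis")
  )
  plot_field(locs) +
    ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax, ymin = .data$ymin,
        ymax = .data$ymax, linetype = .data$kind
      ),
      colour = "red", fill = NA, inherit.aes = FALSE
    )
}
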