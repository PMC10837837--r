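# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a signature report
#'
#' Returns the report as a plain tibble ordered by contrast and feature
#' (the report already carries one row per contrast x feature).
#'
#' @param x A `signature_report` from [run_contrasts()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy signature_report
#' @export
tidy.signature_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dplyr::arrange(out, .data$label, .data$feature)
}

#' @rdname tidy.signature_report
#' @method glance signature_report
#' @export
glance.signature_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$label, .data$target, .data$reference) |>
    dplyr::summarise(
      n_features = dplyr::n(),
      n_significant = sum(.data$p_value <= 0.05, na.rm = TRUE),
      n_double_arrow = sum(.data$arrow %in% c("↑↑", "↓↓"), na.rm = TRUE),
      .groups = "drop")
}

#' Plot a signature report as an arrow/effect grid
#'
#' Tiles features by contrast, filled by the percentage difference and
#' annotated with the arrow class.
#'
#' @param object A `signature_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_report
#' @export
autoplot.signature_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$feature,
                                   fill = .data$d)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$arrow), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "% difference") +
    ggplot2::labs(x = "contrast", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.signature_report
#' @param clades Optional tibble `isolate_id` -> `clade` to colour points.
#' @method autoplot ecosig_ordination
#' @export
autoplot.ecosig_ordination <- function(object, clades = NULL, ...) {
  df <- object$points
  if (!is.null(clades)) df <- dplyr::left_join(df, clades, by = "isolate_id")
  aes <- if (!is.null(clades)) {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2, color = .data$clade)
  } else {
    ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(caption = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' @export
print.signature_report <- function(x, ...) {
  cat("Signature report:", length(unique(x$label)), "contrast(s),",
      length(unique(x$feature)), "feature(s)\n")
  NextMethod()
}

#' @export
print.ecosig_ordination <- function(x, ...) {
  cat("NMDS ordination (", x$distance, "), k = ",
      ncol(x$points) - 1, ", stress = ", signif(x$stress, 4), "\n", sep = "")
  print(x$points)
  invisible(x)
}
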