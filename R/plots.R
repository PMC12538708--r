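#' Plot a seed layout
#'
#' Seed centers on the belt, sized by seed length and colored by class.
#'
#' @param object A [sample_layout()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot layout_scene
#' @export
autoplot.layout_scene <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x_mm, .data$y_mm,
                               color = .data$class_label, size = .data$length_mm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, attr(object, "belt_width_mm")),
                         ylim = c(attr(object, "belt_height_mm"), 0)) +
    ggplot2::scale_size_continuous(range = c(1, 3), guide = "none") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", color = "class",
                  title = sprintf("Seed layout (%s process)", attr(object, "process"))) +
    ggplot2::theme_minimal()
}

#' Plot grid proportions as a tile heatmap
#'
#' @param object A [grid_proportions()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grid_proportions
#' @export
autoplot.grid_proportions <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$col, .data$row, fill = .data$proportion)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_reverse(breaks = seq_len(attr(object, "n_rows"))) +
    ggplot2::scale_x_continuous(breaks = seq_len(attr(object, "n_cols"))) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "tile column", y = "tile row", fill = "seed-pixel\nfraction") +
    ggplot2::theme_minimal()
}

#' Main-effects plot of a response table
#'
#' One panel per factor; level means (or S/N) connected by lines, the
#' standard Minitab-style main-effects display.
#'
#' @param object A [response_table()].
#' @param response `"mean"` or `"sn"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot response_table
#' @export
autoplot.response_table <- function(object, response = c("mean", "sn"), ...) {
  response <- match.arg(response)
  df <- tibble::as_tibble(object)
  df$factor <- factor(df$factor, levels = unique(df$factor))
  df$value <- df[[response]]
  ref <- if (response == "mean") attr(object, "grand_mean") else attr(object, "grand_sn")
  ggplot2::ggplot(df, ggplot2::aes(.data$level, .data$value, group = 1)) +
    ggplot2::geom_hline(yintercept = ref, linetype = "dashed", color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor, scales = "free_x", nrow = 1) +
    ggplot2::labs(x = NULL,
                  y = if (response == "mean") "mean Moran's I" else "S/N (dB)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Permutation-null plot for a Moran's I result
#'
#' Histogram of permuted statistics with the observed value marked;
#' requires `n_perm > 0` in [morans_i()].
#'
#' @param object A `moran_result` with permutations.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot moran_result
#' @export
autoplot.moran_result <- function(object, ...) {
  if (is.null(object$perm_values)) {
    rlang::abort("no permutations stored; call morans_i() with n_perm > 0")
  }
  ggplot2::ggplot(tibble::tibble(I = object$perm_values), ggplot2::aes(.data$I)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$I, color = "red") +
    ggplot2::geom_vline(xintercept = object$expected_I_null,
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "Moran's I (permuted)", y = "count",
                  subtitle = sprintf("observed I = %.4f, p = %.4f",
                                     object$I, object$p_perm)) +
    ggplot2::theme_minimal()
}
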