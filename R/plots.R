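#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an ordination
#'
#' Scatter of the first two axes; the caption reports retained dimensions
#' (PCA) or stress (NMDS).
#'
#' @param object An `ed_ordination`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ed_ordination <- function(object, ...) {
  m <- ord_coords(object)
  df <- tibble::tibble(x = m[, 1], y = if (ncol(m) > 1) m[, 2] else 0)
  cap <- if (object$kind == "pca") {
    sprintf("correlation PCA, %d component(s) retained (Kaiser)", object$k)
  } else {
    sprintf("NMDS, stress = %.4f", object$stress)
  }
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.6) +
    labs(x = colnames(m)[1], y = if (ncol(m) > 1) colnames(m)[2] else "",
         caption = cap) +
    theme_minimal()
}

#' Plot a selection in its ordination space
#'
#' All sites in grey, selected sites highlighted; optionally overlays the
#' demand grid (p-median).
#'
#' @param space The `ed_ordination` the selection was made in.
#' @param selection An `ed_selection`.
#' @param demand Optional `ed_demand_grid` to overlay.
#' @return A ggplot.
#' @export
plot_selection <- function(space, selection, demand = NULL) {
  m <- ord_coords(space)
  sel <- selected_sites(selection)
  df <- tibble::tibble(x = m[, 1], y = if (ncol(m) > 1) m[, 2] else 0,
                       selected = seq_len(nrow(m)) %in% sel)
  p <- ggplot(df, aes(x = .data$x, y = .data$y))
  if (!is.null(demand)) {
    p <- p + geom_point(data = tibble::as_tibble(demand),
                        aes(x = .data$x, y = .data$y),
                        shape = 3, size = 0.3, colour = "grey80",
                        inherit.aes = FALSE)
  }
  p +
    geom_point(aes(colour = .data$selected, size = .data$selected), alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "#d95f02")) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 1, `TRUE` = 2.2)) +
    labs(x = colnames(m)[1], y = if (ncol(m) > 1) colnames(m)[2] else "",
         colour = "selected", size = "selected",
         caption = sprintf("%s selection, m = %d", attr(selection, "method"),
                           length(sel))) +
    theme_minimal()
}

#' Plot an SAI sweep
#'
#' Per-fraction SAI with the zero (random-equivalent) line and the median
#' over defined fractions.
#'
#' @param object An `ed_sai_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ed_sai_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df[df$defined, ], aes(x = .data$fraction, y = .data$SAI)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_hline(yintercept = attr(object, "median_sai"), colour = "#1b9e77") +
    geom_line() +
    geom_point() +
    labs(x = "fraction of landscape reserved", y = "SAI",
         caption = sprintf("median SAI = %.3f", attr(object, "median_sai"))) +
    theme_minimal()
}
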