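#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_hline facet_wrap labs scale_fill_brewer theme_minimal
#' @export
ggplot2::autoplot

#' Bar chart of variation-partition fractions
#'
#' @param object a [variation_partition()] object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.variation_partition <- function(object, ...) {
  lab <- c(a = "pure environment [a]", b = "shared [b]",
           c = "pure space [c]", d = "residual [d]")
  df <- dplyr::mutate(object$fractions,
                      fraction = factor(lab[.data$fraction], levels = lab))
  ggplot(df, aes(x = .data$fraction, y = .data$adj_r2, fill = .data$fraction)) +
    geom_col(show.legend = FALSE) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = "adjusted R²") +
    theme_minimal()
}

#' Fraction bars for every facet and scale of a pipeline report
#'
#' @param object a [run_pipeline()] report.
#' @param ... unused.
#' @return a ggplot faceted by facet x scale.
#' @exportS3Method
#' @export
autoplot.rao_report <- function(object, ...) {
  ggplot(object$fractions,
         aes(x = .data$fraction, y = .data$adj_r2, fill = .data$fraction)) +
    geom_col(show.legend = FALSE) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~ facet + scale) +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "fraction", y = "adjusted R²") +
    theme_minimal()
}

#' Correlogram plot (Moran's I or Mantel r against distance class)
#'
#' Filled points mark classes significant at `p < 0.05`, the usual display.
#'
#' @param object a [morans_correlogram()] or [mantel_correlogram()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method
#' @export
autoplot.moran_correlogram <- function(object, ...) {
  correlogram_plot(object, "moran_i", "Moran's I")
}

#' @rdname autoplot.moran_correlogram
#' @exportS3Method
#' @export
autoplot.mantel_correlogram <- function(object, ...) {
  correlogram_plot(object, "mantel_r", "Mantel r")
}

correlogram_plot <- function(df, col, ylab) {
  mid <- (df$lower + df$upper) / 2
  d <- dplyr::mutate(df, mid = mid, significant = .data$p_value < 0.05)
  ggplot(d, aes(x = .data$mid, y = .data[[col]])) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    geom_line() +
    geom_point(aes(fill = .data$significant), shape = 21, size = 2.5,
               show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    labs(x = "distance class midpoint", y = ylab) +
    theme_minimal()
}

#' Scree-style plot of PCNM eigenvalues
#'
#' @param object a [pcnm_basis()] object.
#' @param ... unused.
#' @return a ggplot of eigenvalues, positive-Moran eigenfunctions marked.
#' @exportS3Method
#' @export
autoplot.pcnm_basis <- function(object, ...) {
  df <- tibble::tibble(order = seq_along(object$values),
                       eigenvalue = object$values,
                       positive_moran = object$positive_moran)
  ggplot(df, aes(x = .data$order, y = .data$eigenvalue,
                 fill = .data$positive_moran)) +
    geom_col() +
    labs(x = "eigenfunction", y = "eigenvalue", fill = "Moran's I > null") +
    theme_minimal()
}
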