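#' Plot a diversity panel
#'
#' Heat map of unbiased expected heterozygosity by population and locus,
#' with observed heterozygosity printed in each cell.
#'
#' @param object An `ssr_diversity` tibble from [diversity_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_diversity <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus, y = .data$population,
                                   fill = .data$Hs)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$Ho)),
                       size = 2.6) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Hs") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Expected heterozygosity (fill) and observed (text)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a linkage-disequilibrium panel
#'
#' Tile map of the standardised index of association for every locus pair,
#' faceted by population group.
#'
#' @param object An `ssr_ld` tibble from [ld_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_ld <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$locus_a, y = .data$locus_b,
                                   fill = .data$rbar_d)) +
    ggplot2::geom_tile(colour = "grey90") +
    ggplot2::facet_wrap(~population) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = expression(bar(r)[d])) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a marker screen
#'
#' Bar chart of marker counts per polymorphism status.
#'
#' @param object An `ssr_screen` object from [screen_markers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_screen <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "markers") +
    ggplot2::theme_minimal()
}
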