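#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_col
#'   geom_hline geom_vline scale_fill_gradient2 labs theme_minimal theme
#'   element_text
#' @export
ggplot2::autoplot

#' Volcano plot of clone-level enrichment
#'
#' @param object A `phip_enrichment` from [call_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phip_enrichment <- function(object, ...) {
  th <- attr(object, "thresholds")
  d <- tibble::as_tibble(object)
  d$neglog10p <- -log10(pmax(d$p, 1e-300))
  ggplot(d, aes(x = .data$log2fc, y = .data$neglog10p,
                colour = .data$is_hit & !.data$blacklisted)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_vline(xintercept = th$min_log2fc, linetype = 2) +
    geom_hline(yintercept = th$min_neglog10p, linetype = 2) +
    labs(x = "log2 fold change vs bead controls", y = "-log10 p",
         colour = "hit") +
    theme_minimal()
}

#' Heatmap of row-standardized reactive proportions
#'
#' @param object A `phip_zscores` from [proportion_zscores()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phip_zscores <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"protein_id",
                              names_to = "group", values_to = "z")
  ggplot(long, aes(x = .data$group, y = .data$protein_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    theme(axis.text.y = element_text(size = 6))
}

#' Per-sample library coverage plot
#'
#' Bar plot of mapped-read coverage of the clone library with the 1x and 5x
#' thresholds marked.
#'
#' @param qc Tibble from [qc_coverage()].
#' @return A ggplot.
#' @export
plot_coverage <- function(qc) {
  ggplot(qc, aes(x = .data$sample_id, y = .data$coverage_x)) +
    geom_col() +
    geom_hline(yintercept = 1, linetype = 2) +
    geom_hline(yintercept = 5, linetype = 3, colour = "red") +
    labs(x = NULL, y = "library coverage (x)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Dot plot of group-vs-rest antigen comparisons
#'
#' @param object A `phip_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phip_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$neglog10p <- -log10(pmax(d$p, 1e-300))
  ggplot(d, aes(x = .data$prop_group, y = .data$neglog10p,
                colour = .data$distinct)) +
    geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~group) +
    labs(x = "proportion reactive in group", y = "-log10 Fisher p",
         colour = "distinct") +
    theme_minimal()
}
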