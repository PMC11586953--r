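#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

strip_phip <- function(x) {
  class(x) <- class(tibble::tibble())
  for (a in c("blacklist", "dispersion", "thresholds", "size_factors",
              "alpha", "n_group", "n_rest", "sd_type", "phi_common",
              "shrinkage_weight", "n_query", "n_background")) {
    attr(x, a) <- NULL
  }
  x
}

#' Tidy / summarize phipkit result objects
#'
#' `tidy()` returns the underlying per-row tibble; `glance()` a one-row
#' summary in the broom style.
#'
#' @param x A phipkit result object.
#' @param ... Unused.
#' @return A tibble.
#' @name phip-tidiers
NULL

#' @rdname phip-tidiers
#' @export
tidy.phip_enrichment <- function(x, ...) strip_phip(x)

#' @rdname phip-tidiers
#' @export
glance.phip_enrichment <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble::tibble(
    n_clones = dplyr::n_distinct(x$clone_id),
    n_samples = dplyr::n_distinct(x$sample_id),
    n_hits = sum(x$is_hit),
    n_hits_clean = sum(x$is_hit & !x$blacklisted),
    n_blacklisted_clones = length(attr(x, "blacklist")),
    phi_common = attr(attr(x, "dispersion"), "phi_common"),
    min_log2fc = th$min_log2fc,
    min_neglog10p = th$min_neglog10p
  )
}

#' @rdname phip-tidiers
#' @export
tidy.phip_comparison <- function(x, ...) strip_phip(x)

#' @rdname phip-tidiers
#' @export
glance.phip_comparison <- function(x, ...) {
  x |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_distinct_antigens = sum(.data$distinct),
      .groups = "drop"
    )
}

#' @rdname phip-tidiers
#' @export
tidy.phip_ora <- function(x, ...) strip_phip(x)

#' @rdname phip-tidiers
#' @export
glance.phip_ora <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    n_significant = sum(x$p_adj < 0.05),
    n_query = attr(x, "n_query"),
    n_background = attr(x, "n_background")
  )
}

#' @rdname phip-tidiers
#' @export
glance.phip_library <- function(x, ...) {
  tibble::tibble(
    n_clones = nrow(x),
    n_proteins = dplyr::n_distinct(x$protein_id),
    tile_len = attr(x, "tile_len"),
    overlap = attr(x, "overlap")
  )
}

#' @rdname phip-tidiers
#' @export
glance.phip_sim <- function(x, ...) {
  tibble::tibble(
    n_clones = nrow(x$counts),
    n_samples = nrow(x$meta),
    n_controls = sum(x$meta$is_control),
    n_truth_pairs = nrow(x$truth),
    depth = attr(x, "config")$depth_per_sample
  )
}

#' @rdname phip-tidiers
#' @export
tidy.phip_sim <- function(x, ...) {
  tidyr::pivot_longer(x$counts, -"clone_id",
                      names_to = "sample_id", values_to = "count")
}
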