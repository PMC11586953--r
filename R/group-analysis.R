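#' Collapse clone hits to Boolean protein reactivity
#'
#' A sample is reactive to a protein when at least one non-blacklisted clone of
#' that protein is an enrichment hit in that sample, regardless of which
#' epitope the clone tiles. Every library protein and every tested sample
#' appears in the output (non-hits as `FALSE`).
#'
#' @param enrichment A `phip_enrichment` (or any data frame with `clone_id`,
#'   `sample_id`, `is_hit` and optionally `blacklisted`).
#' @param library A `phip_library`, used as the clone-to-protein map. Clones
#'   already named by protein collapse to themselves, so collapsing a
#'   protein-level matrix is the identity.
#' @return A `phip_reactivity` tibble: `protein_id`, `sample_id`, `reactive`.
#' @export
collapse_to_protein <- function(enrichment, library) {
  stopifnot(all(c("clone_id", "sample_id", "is_hit") %in% names(enrichment)))
  if (!("blacklisted" %in% names(enrichment))) enrichment$blacklisted <- FALSE
  unknown <- setdiff(unique(enrichment$clone_id), library$clone_id)
  if (length(unknown)) {
    abort(paste0("Unknown clone_id(s): ", toString(head(unknown, 3))))
  }
  map <- dplyr::distinct(tibble::as_tibble(library[, c("clone_id", "protein_id")]))
  res <- enrichment |>
    dplyr::left_join(map, by = "clone_id") |>
    dplyr::group_by(.data$protein_id, .data$sample_id) |>
    dplyr::summarise(
      reactive = any(.data$is_hit & !.data$blacklisted),
      .groups = "drop"
    ) |>
    tidyr::complete(
      protein_id = unique(library$protein_id),
      sample_id = unique(enrichment$sample_id),
      fill = list(reactive = FALSE)
    )
  structure(res, class = c("phip_reactivity", class(tibble::tibble())))
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Direct hypergeometric enumeration, vectorized over tables. The default
#' two-sided p-value sums the probabilities of all tables with the same
#' margins whose probability does not exceed that of the observed table
#' (minimum-likelihood convention, matching R's `fisher.test`); the doubling
#' alternative (`2 * min(tail probabilities)`, capped at 1) is available via
#' `method = "doubling"`.
#'
#' @param a,b,c,d Cell counts: `a` successes / `b` failures in the first arm,
#'   `c` / `d` in the second. Vectors are recycled to a common length.
#' @param method Two-sided convention.
#' @return Numeric vector of p-values.
#' @export
#' @examples
#' fisher_exact_2x2(10, 2, 2, 10)  # 0.00333
fisher_exact_2x2 <- function(a, b, c, d, method = c("minlike", "doubling")) {
  method <- match.arg(method)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) abort("All cells must be non-negative.")
  vapply(seq_len(n), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; k <- a[i] + c[i]
    if (r1 + r2 == 0) abort("Empty table.")
    support <- max(0, k - r2):min(k, r1)
    lp <- stats::dhyper(support, r1, r2, k, log = TRUE)
    obs <- lp[support == a[i]]
    if (method == "minlike") {
      sum(exp(lp[lp <= obs + log(1 + 1e-7)]))
    } else {
      lower <- sum(exp(lp[support <= a[i]]))
      upper <- sum(exp(lp[support >= a[i]]))
      min(1, 2 * min(lower, upper))
    }
  }, numeric(1))
}

#' Compare one disease group against the rest, protein by protein
#'
#' For every protein with any reactivity among the serum samples, builds the
#' 2x2 table (reactive / non-reactive in the group of interest vs the pooled
#' remaining disease groups), applies the two-sided Fisher exact test, and
#' flags proteins with `p < alpha` as distinct targeted antigens of the group.
#' Bead controls and spike-in samples are excluded.
#'
#' @param reactivity A `phip_reactivity` from [collapse_to_protein()].
#' @param meta Sample metadata (`sample_id`, `group`, `is_control`).
#' @param group Group of interest (must appear in `meta$group`).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`; with BH, `distinct` uses the
#'   adjusted p-value.
#' @param method Two-sided convention passed to [fisher_exact_2x2()].
#' @return A `phip_comparison` tibble: `protein_id`, `group`, `a`, `b`, `c`,
#'   `d`, `p` (+ `p_adj` under BH), `prop_group`, `prop_rest`,
#'   `pct_group`, `pct_rest` (percentages truncated toward zero, the
#'   convention used in published hit tables), `distinct`.
#' @export
group_vs_rest <- function(reactivity, meta, group, alpha = 0.05,
                          p_adjust = c("none", "BH"),
                          method = c("minlike", "doubling")) {
  p_adjust <- match.arg(p_adjust)
  method <- match.arg(method)
  serum <- meta[!meta$is_control & meta$group != "spike", ]
  if (!group %in% serum$group) {
    abort(paste0("Group not present among serum samples: ", group))
  }
  in_group <- serum$sample_id[serum$group == group]
  in_rest <- serum$sample_id[serum$group != group]
  r <- reactivity[reactivity$sample_id %in% serum$sample_id, ]
  tab <- r |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      a = sum(.data$reactive[.data$sample_id %in% in_group]),
      c = sum(.data$reactive[.data$sample_id %in% in_rest]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$a + .data$c > 0) |>
    dplyr::mutate(
      b = length(in_group) - .data$a,
      d = length(in_rest) - .data$c,
      group = group,
      p = fisher_exact_2x2(.data$a, .data$b, .data$c, .data$d, method = method),
      prop_group = .data$a / length(in_group),
      prop_rest = .data$c / length(in_rest),
      pct_group = trunc(100 * .data$prop_group),
      pct_rest = trunc(100 * .data$prop_rest)
    )
  if (p_adjust == "BH") {
    tab$p_adj <- p.adjust(tab$p, method = "BH")
    tab$distinct <- tab$p_adj < alpha
  } else {
    tab$distinct <- tab$p < alpha
  }
  tab <- dplyr::arrange(
    tab[, c("protein_id", "group", "a", "b", "c", "d", "p",
            intersect("p_adj", names(tab)), "prop_group", "prop_rest",
            "pct_group", "pct_rest", "distinct")],
    .data$p, .data$protein_id
  )
  structure(tab, class = c("phip_comparison", class(tibble::tibble())),
            alpha = alpha, n_group = length(in_group), n_rest = length(in_rest))
}

#' Run [group_vs_rest()] for every disease group
#'
#' @inheritParams group_vs_rest
#' @return A `phip_comparison` tibble stacking one comparison per group.
#' @export
compare_groups <- function(reactivity, meta, alpha = 0.05,
                           p_adjust = c("none", "BH"),
                           method = c("minlike", "doubling")) {
  serum <- meta[!meta$is_control & meta$group != "spike", ]
  groups <- unique(serum$group)
  out <- purrr::map_dfr(groups, function(g) {
    group_vs_rest(reactivity, meta, g, alpha = alpha,
                  p_adjust = p_adjust, method = method)
  })
  structure(out, class = c("phip_comparison", class(tibble::tibble())),
            alpha = alpha)
}

#' Row-standardized reactive-proportion matrix
#'
#' Standardizes each protein's per-group reactive proportions to z-scores
#' (`(x - row mean) / row sd`), the transform behind group-comparison
#' heatmaps. Rows with zero spread map to all-zero.
#'
#' @param comparisons A `phip_comparison` covering >= 2 groups (e.g. from
#'   [compare_groups()]).
#' @param sd_type `"sample"` (n-1 denominator, default, matching R's `scale()`)
#'   or `"population"`.
#' @return A `phip_zscores` tibble: `protein_id` + one z column per group.
#' @export
proportion_zscores <- function(comparisons, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  wide <- comparisons |>
    dplyr::select("protein_id", "group", "prop_group") |>
    tidyr::pivot_wider(names_from = "group", values_from = "prop_group")
  if (ncol(wide) < 3) abort("Need proportions for >= 2 groups.")
  m <- as.matrix(wide[, -1])
  mu <- rowMeans(m)
  dev <- m - mu
  denom <- if (sd_type == "sample") ncol(m) - 1 else ncol(m)
  s <- sqrt(rowSums(dev^2) / denom)
  z <- dev / ifelse(s > 0, s, Inf)   # zero-spread rows -> 0
  out <- dplyr::bind_cols(wide[, 1], tibble::as_tibble(z))
  structure(out, class = c("phip_zscores", class(tibble::tibble())),
            sd_type = sd_type)
}

#' Overlap partition of two antigen (or gene) sets
#'
#' @param list_a,list_b Character vectors.
#' @return List with `intersection`, `a_only`, `b_only` (sorted unique values)
#'   and `counts`, a one-row tibble of the three sizes — the numbers a Venn
#'   diagram displays.
#' @export
set_overlap <- function(list_a, list_b) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  out <- list(
    intersection = sort(intersect(list_a, list_b)),
    a_only = sort(setdiff(list_a, list_b)),
    b_only = sort(setdiff(list_b, list_a))
  )
  out$counts <- tibble::tibble(
    intersection = length(out$intersection),
    a_only = length(out$a_only),
    b_only = length(out$b_only)
  )
  out
}
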