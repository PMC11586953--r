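#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: term, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene symbols, upper-cased).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", which(bad)[1]))
  }
  setNames(
    lapply(fields, function(f) unique(toupper(f[-(1:2)]))),
    vapply(fields, `[[`, character(1), 1)
  )
}

#' Hypergeometric over-representation analysis
#'
#' Offline ORA of a gene list against a gene-set collection: for each set, an
#' upper-tail hypergeometric test of the overlap given a background universe,
#' with Benjamini-Hochberg adjustment across sets. The background defaults to
#' the union of all set members plus the query but should normally be the full
#' set of genes the assay can detect (e.g. all tiled proteins' gene symbols).
#' Symbol matching is case-insensitive; an alias map can rename known synonyms
#' before matching. Query genes outside the background are dropped with a
#' warning.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param background Character vector defining the gene universe.
#' @param alias Optional named character vector `old_symbol -> new_symbol`
#'   applied to query, sets and background before matching.
#' @param min_overlap Only report sets overlapping the query by at least this
#'   many genes (default 1).
#' @return An `phip_ora` tibble sorted by p: `term`, `set_size`,
#'   `overlap_count`, `overlap_genes` (comma-separated), `p`, `p_adj`,
#'   `odds_ratio`.
#' @export
ora <- function(query, collection,
                background = unique(c(unlist(collection), query)),
                alias = NULL, min_overlap = 1L) {
  canon <- function(x) {
    x <- toupper(x)
    if (!is.null(alias)) {
      names(alias) <- toupper(names(alias))
      hit <- x %in% names(alias)
      x[hit] <- toupper(alias[x[hit]])
    }
    unique(x)
  }
  background <- canon(background)
  query <- canon(query)
  dropped <- setdiff(query, background)
  if (length(dropped)) {
    warn(paste0("Dropping query genes outside the background: ",
                toString(head(dropped, 5))))
    query <- intersect(query, background)
  }
  if (!length(query)) abort("Query is empty after background filtering.")
  collection <- lapply(collection, function(s) intersect(canon(s), background))
  collection <- collection[lengths(collection) > 0]
  if (!length(collection)) abort("No non-empty gene sets after filtering.")

  N <- length(background); n <- length(query)
  res <- purrr::imap_dfr(collection, function(set, term) {
    K <- length(set)
    ov <- intersect(query, set)
    k <- length(ov)
    # upper tail: P(overlap >= k)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    orat <- (k * (N - K - n + k)) / max(1e-12, (K - k) * (n - k))
    tibble::tibble(
      term = term, set_size = K, overlap_count = k,
      overlap_genes = paste(sort(ov), collapse = ","),
      p = p, odds_ratio = orat
    )
  })
  res$p_adj <- p.adjust(res$p, method = "BH")
  res <- res[res$overlap_count >= min_overlap, ]
  res <- dplyr::arrange(res, .data$p, .data$term)
  res <- res[, c("term", "set_size", "overlap_count", "overlap_genes",
                 "p", "p_adj", "odds_ratio")]
  structure(res, class = c("phip_ora", class(tibble::tibble())),
            n_query = n, n_background = N)
}

# default cell types counted as ocular-surface epithelium in the
# expression cross-reference
default_epithelial_types <- function() {
  c("corneal basal", "corneal wing", "corneal superficial",
    "corneal transit-amplifying",
    "limbal basal", "limbal wing", "limbal superficial",
    "conjunctival basal", "conjunctival wing", "conjunctival superficial",
    "goblet")
}

#' Cross-reference antigen genes against a cell-type expression table
#'
#' Annotates each query gene with its maximally expressing cell type and flags
#' whether it is expressed (above `threshold`) in any epithelial cell type
#' under a configurable grouping; genes absent from the table are reported as
#' not detected.
#'
#' @param query Character vector of gene symbols.
#' @param expression Data frame: a `gene` column plus one numeric column per
#'   cell type (e.g. mean expression per cell type).
#' @param threshold Expression cutoff for calling a gene expressed (default 0,
#'   i.e. any positive value).
#' @param epithelial_types Cell-type column names counted as epithelium;
#'   matched case-insensitively against the table's columns. Defaults to the
#'   ocular-surface epithelial populations (corneal / limbal / conjunctival
#'   layers and goblet cells).
#' @return Tibble: `gene`, `detected`, `max_cell_type`, `max_expression`,
#'   `expressed_in_epithelium`.
#' @export
expression_crossref <- function(query, expression, threshold = 0,
                                epithelial_types = default_epithelial_types()) {
  stopifnot("gene" %in% names(expression))
  cell_cols <- setdiff(names(expression), "gene")
  if (!length(cell_cols)) abort("Expression table has no cell-type columns.")
  genes_upper <- toupper(expression$gene)
  query <- unique(toupper(query))
  if (!length(intersect(query, genes_upper))) {
    warn("No query gene found in the expression table.")
  }
  epi_cols <- cell_cols[tolower(cell_cols) %in% tolower(epithelial_types)]
  purrr::map_dfr(query, function(g) {
    i <- match(g, genes_upper)
    if (is.na(i)) {
      return(tibble::tibble(gene = g, detected = FALSE,
                            max_cell_type = NA_character_,
                            max_expression = NA_real_,
                            expressed_in_epithelium = FALSE))
    }
    vals <- as.numeric(expression[i, cell_cols])
    j <- which.max(vals)
    tibble::tibble(
      gene = g,
      detected = any(vals > threshold),
      max_cell_type = cell_cols[j],
      max_expression = vals[j],
      expressed_in_epithelium = length(epi_cols) > 0 &&
        any(as.numeric(expression[i, epi_cols]) > threshold)
    )
  })
}
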