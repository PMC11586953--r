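#' Read a proteome FASTA
#'
#' Reads amino-acid sequences and parses headers of the form
#' `<protein_id><delim><gene_symbol>` (anything after a space is dropped).
#' Headers without the delimiter reuse the protein id as the gene symbol.
#'
#' @param path FASTA file of protein sequences.
#' @param delim Field delimiter inside the header (default `"|"`).
#' @return Tibble with `protein_id`, `gene_symbol`, `sequence`.
#' @export
read_proteome_fasta <- function(path, delim = "|") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(headers, delim, fixed = TRUE)
  tibble::tibble(
    protein_id = vapply(parts, `[[`, character(1), 1),
    gene_symbol = vapply(parts, function(x) if (length(x) > 1) x[[2]] else x[[1]],
                         character(1)),
    sequence = unname(toupper(as.character(aa)))
  )
}

#' Write / read a clone library as TSV
#'
#' The TSV holds one clone per row (`clone_id`, `protein_id`, `gene_symbol`,
#' `start`, `peptide`, `insert_nt`); tiling parameters and flanks travel in a
#' `# key: value` comment header so a round trip restores the `phip_library`
#' attributes.
#'
#' @param library A `phip_library`.
#' @param path Output/input TSV path.
#' @return `write_library()` returns `path` invisibly; `read_library()` returns
#'   a `phip_library`.
#' @export
write_library <- function(library, path) {
  p <- library_params(library)
  hdr <- sprintf("# %s: %s", names(p), unlist(p))
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(library), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), ": ", fixed = TRUE)
  meta <- setNames(
    vapply(kv, `[[`, character(1), 2),
    vapply(kv, `[[`, character(1), 1)
  )
  lib <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  structure(
    lib,
    class = c("phip_library", class(lib)),
    tile_len = as.integer(meta[["tile_len"]]),
    overlap = as.integer(meta[["overlap"]]),
    flank_5p = meta[["flank_5p"]],
    flank_3p = meta[["flank_3p"]]
  )
}

#' Write clone insert sequences as FASTA
#'
#' Emits one record per clone. With `with_flanks = TRUE` the full amplicon
#' template (5' flank + insert + 3' flank) is written, which is what a mapper
#' aligns reads against.
#'
#' @param library A `phip_library`.
#' @param path Output FASTA path.
#' @param with_flanks Include tag flanks (default TRUE).
#' @return `path`, invisibly.
#' @export
library_insert_fasta <- function(library, path, with_flanks = TRUE) {
  seqs <- if (with_flanks) clone_templates(library) else
    setNames(library$insert_nt, library$clone_id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read and write a clones-by-samples count table
#'
#' Counts are stored wide: a `clone_id` column followed by one integer column
#' per sample.
#'
#' @param counts Wide count tibble (see [simulate_phipseq()]).
#' @param path TSV path.
#' @return `write_counts()` returns `path` invisibly; `read_counts()` a tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `group`; `is_control` is derived from
#' `group == "beads"` when absent.
#'
#' @param path TSV path.
#' @return Tibble with `sample_id`, `group`, `is_control`.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("Metadata must have columns `sample_id` and `group`.")
  }
  if (!("is_control" %in% names(meta))) {
    meta$is_control <- meta$group == "beads"
  }
  if (anyDuplicated(meta$sample_id)) abort("sample_ids must be unique.")
  meta
}

# wide count tibble -> integer matrix (clones x samples)
counts_matrix <- function(counts) {
  stopifnot("clone_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "clone_id"), drop = FALSE])
  rownames(m) <- counts$clone_id
  storage.mode(m) <- "double"
  m
}
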