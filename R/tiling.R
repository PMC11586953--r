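#' Most-frequent E. coli codon table
#'
#' A deterministic reverse-translation table mapping each of the 20 standard
#' amino acids to its most frequently used codon in *E. coli* K-12, plus
#' `X -> NNN` for unknown residues. Used as the default by
#' [reverse_translate()]; supply your own named vector to override.
#'
#' @return Named character vector: names are one-letter residues, values are
#'   codons.
#' @export
#' @examples
#' ecoli_codon_table()[["M"]]
ecoli_codon_table <- function() {
  c(
    A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC",
    Q = "CAG", E = "GAA", G = "GGC", H = "CAT", I = "ATT",
    L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
    S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG",
    X = "NNN"
  )
}

# Default tag flanks: FLAG (DYKDDDDK) upstream, STREP-tag II (WSHPQFEK)
# downstream, reverse-translated with the default codon table.
default_flank_5p <- function() "GATTATAAAGATGATGATGATAAA"
default_flank_3p <- function() "TGGAGCCATCCGCAGTTTGAAAAA"

aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

check_protein_tbl <- function(proteins, call = rlang::caller_env()) {
  if (!is.data.frame(proteins) || nrow(proteins) == 0) {
    abort("`proteins` must be a data frame with at least one row.", call = call)
  }
  need <- c("protein_id", "sequence")
  miss <- setdiff(need, names(proteins))
  if (length(miss)) {
    abort(paste0("`proteins` is missing column(s): ", toString(miss)), call = call)
  }
  if (anyDuplicated(proteins$protein_id)) {
    abort("`proteins$protein_id` must be unique.", call = call)
  }
  if (any(!nzchar(proteins$sequence)) || anyNA(proteins$sequence)) {
    abort("Every protein sequence must be non-empty.", call = call)
  }
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", proteins$sequence)
  if (any(bad)) {
    abort(paste0(
      "Sequence of ", proteins$protein_id[bad][1],
      " contains characters outside the 20 standard residues + X."
    ), call = call)
  }
  invisible(proteins)
}

# 0-based tile start offsets for one protein
tile_starts <- function(len, tile_len, step) {
  if (len <= tile_len) return(0L)
  starts <- seq.int(0L, len - tile_len, by = step)
  if (max(starts) + tile_len < len) starts <- c(starts, len - tile_len)
  starts
}

#' Tile proteins into overlapping peptides
#'
#' Cuts each protein into fixed-length peptide tiles with a fixed overlap
#' (default 49-mers overlapping by 25 residues, i.e. a step of 24), the design
#' used by proteome-wide phage display libraries. Tiling starts at residue 0
#' and advances by `tile_len - overlap`; when the tail would be left uncovered,
#' a terminal tile is anchored at `length - tile_len` (overlapping its
#' predecessor by more than `overlap`) so that every residue is covered by a
#' full-length peptide. Proteins shorter than `tile_len` yield one
#' full-length tile.
#'
#' @param proteins Data frame with columns `protein_id`, `sequence`, and
#'   optionally `gene_symbol`.
#' @param tile_len Peptide length in residues (default 49).
#' @param overlap Overlap between consecutive tiles in residues (default 25).
#' @return A tibble with one row per tile: `clone_id` (`<protein_id>_<start>`),
#'   `protein_id`, `gene_symbol`, `start` (0-based residue offset), `peptide`.
#' @seealso [build_library()] for tiling plus reverse translation.
#' @export
#' @examples
#' prot <- tibble::tibble(protein_id = "P1", sequence = strrep("ACDEFGHIKL", 10))
#' tile_proteins(prot)
tile_proteins <- function(proteins, tile_len = 49L, overlap = 25L) {
  check_protein_tbl(proteins)
  tile_len <- as.integer(tile_len)
  overlap <- as.integer(overlap)
  if (!(overlap > 0L && overlap < tile_len)) {
    abort("`overlap` must satisfy 0 < overlap < tile_len.")
  }
  step <- tile_len - overlap
  if (!("gene_symbol" %in% names(proteins))) {
    proteins$gene_symbol <- proteins$protein_id
  }
  purrr::pmap_dfr(
    proteins[, c("protein_id", "gene_symbol", "sequence")],
    function(protein_id, gene_symbol, sequence) {
      len <- nchar(sequence)
      starts <- tile_starts(len, tile_len, step)
      width <- min(tile_len, len)
      tibble::tibble(
        clone_id = paste0(protein_id, "_", starts),
        protein_id = protein_id,
        gene_symbol = gene_symbol,
        start = starts,
        peptide = substring(sequence, starts + 1L, starts + width)
      )
    }
  )
}

#' Reverse-translate peptide tiles into clone inserts
#'
#' Maps each peptide to a nucleotide insert using a deterministic codon table
#' (one codon per residue), so that translating the insert reproduces the
#' peptide exactly.
#'
#' @param tiles Tibble of tiles from [tile_proteins()] (needs `clone_id`,
#'   `peptide`).
#' @param codon_table Named character vector residue -> codon; default
#'   [ecoli_codon_table()].
#' @return The input tibble with an `insert_nt` column appended.
#' @export
reverse_translate <- function(tiles, codon_table = ecoli_codon_table()) {
  stopifnot(is.data.frame(tiles), all(c("clone_id", "peptide") %in% names(tiles)))
  residues <- strsplit(tiles$peptide, "")
  missing <- setdiff(unique(unlist(residues)), names(codon_table))
  if (length(missing)) {
    # report first offending residue with its clone and position
    for (i in seq_along(residues)) {
      pos <- which(residues[[i]] %in% missing)
      if (length(pos)) {
        abort(sprintf(
          "Residue '%s' at position %d of %s has no codon in the table.",
          residues[[i]][pos[1]], pos[1], tiles$clone_id[i]
        ))
      }
    }
  }
  tiles$insert_nt <- vapply(
    residues,
    function(r) paste0(codon_table[r], collapse = ""),
    character(1)
  )
  tiles
}

# Translate a nucleotide string with the standard genetic code (NNN -> X).
# Inverse used by tests and simulation; not exported.
translate_nt <- function(nt) {
  gc_tab <- as.character(Biostrings::GENETIC_CODE)
  names(gc_tab) <- names(Biostrings::GENETIC_CODE)
  gc_tab <- c(gc_tab, NNN = "X")
  vapply(nt, function(s) {
    stopifnot(nchar(s) %% 3 == 0)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- gc_tab[codons]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a phage display tiling library from a proteome
#'
#' Tiles every protein ([tile_proteins()]), reverse-translates each tile
#' ([reverse_translate()]) and attaches the tag-encoding flanks, returning the
#' complete clone library with its clone-to-protein map.
#'
#' @inheritParams tile_proteins
#' @inheritParams reverse_translate
#' @param flank_5p,flank_3p Nucleotide flanks encoding the display tags
#'   (defaults encode FLAG and STREP-tag II).
#' @return A `phip_library`: a tibble with columns `clone_id`, `protein_id`,
#'   `gene_symbol`, `start`, `peptide`, `insert_nt`, carrying the tiling
#'   parameters and flanks as attributes (see [library_params()]).
#' @export
#' @examples
#' prot <- tibble::tibble(protein_id = c("P1", "P2"),
#'                        sequence = c(strrep("ACDEFGHIKL", 10), strrep("MKLV", 13)))
#' lib <- build_library(prot)
#' dplyr::count(lib, protein_id)
build_library <- function(proteins, tile_len = 49L, overlap = 25L,
                          codon_table = ecoli_codon_table(),
                          flank_5p = default_flank_5p(),
                          flank_3p = default_flank_3p()) {
  tiles <- tile_proteins(proteins, tile_len = tile_len, overlap = overlap)
  lib <- reverse_translate(tiles, codon_table = codon_table)
  if (anyDuplicated(lib$clone_id)) {
    abort("Internal error: clone_ids are not unique.")
  }
  structure(
    lib,
    class = c("phip_library", class(tibble::as_tibble(lib))),
    tile_len = as.integer(tile_len),
    overlap = as.integer(overlap),
    flank_5p = flank_5p,
    flank_3p = flank_3p
  )
}

#' Tiling parameters and flanks of a library
#'
#' @param library A `phip_library` from [build_library()].
#' @return A list with `tile_len`, `overlap`, `flank_5p`, `flank_3p`.
#' @export
library_params <- function(library) {
  list(
    tile_len = attr(library, "tile_len"),
    overlap = attr(library, "overlap"),
    flank_5p = attr(library, "flank_5p"),
    flank_3p = attr(library, "flank_3p")
  )
}

# full amplicon template (flank + insert + flank) per clone
clone_templates <- function(library) {
  p <- library_params(library)
  setNames(paste0(p$flank_5p, library$insert_nt, p$flank_3p), library$clone_id)
}
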