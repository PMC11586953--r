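#' Map reads to a clone library
#'
#' Seed-and-extend mapper for PhIP-seq amplicon reads. Exact `k_seed`-mers of
#' each read (taken at non-overlapping offsets plus the read end) are looked up
#' in an index of all clone amplicon templates; every candidate (clone,
#' diagonal) is scored by ungapped local alignment (+1 match / -1 mismatch,
#' best-scoring contiguous segment on the diagonal). A read is counted to the
#' unique best-scoring clone provided that score reaches `min_score`
#' (interpretable as at least 50 net matching positions at the default
#' scoring); ties between distinct clones are discarded as ambiguous, and
#' sub-threshold or unseeded reads are discarded as low-score. Seeds occurring
#' in more than `max_seed_hits` clones (e.g. the shared tag flanks) are
#' skipped.
#'
#' @param reads Tibble with `sample_id`, `read_id`, `sequence` (from
#'   [simulate_reads()] or [read_fastq_dir()]), or a directory of FASTQ files.
#' @param library A `phip_library`.
#' @param min_score Minimum alignment score to accept (default 50).
#' @param match,mismatch Per-base alignment scores.
#' @param k_seed Exact-match seed length (default 25).
#' @param max_seed_hits Skip seeds occurring in more clones than this.
#' @return A wide count tibble (`clone_id` + one column per sample, all library
#'   clones and all samples present) with a per-sample mapping log in
#'   attribute `"mapping_log"`; see [mapping_log()].
#' @export
map_reads <- function(reads, library, min_score = 50L, match = 1L,
                      mismatch = -1L, k_seed = 25L, max_seed_hits = 50L) {
  if (is.character(reads) && length(reads) == 1 && dir.exists(reads)) {
    reads <- read_fastq_dir(reads)
  }
  if (!nrow(library)) abort("`library` has no clones.")
  stopifnot(all(c("sample_id", "read_id", "sequence") %in% names(reads)))

  templates <- clone_templates(library)
  idx <- seed_index(templates, k_seed, max_seed_hits)
  samples <- unique(reads$sample_id)

  assigned_clone <- character(nrow(reads))
  status <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    res <- align_read(reads$sequence[i], templates, idx, k_seed,
                      match, mismatch, min_score)
    assigned_clone[i] <- res$clone
    status[i] <- res$status
  }

  m <- matrix(0, nrow(library), length(samples),
              dimnames = list(library$clone_id, samples))
  ok <- status == "assigned"
  if (any(ok)) {
    tab <- table(factor(assigned_clone[ok], levels = library$clone_id),
                 factor(reads$sample_id[ok], levels = samples))
    m <- m + unclass(tab)
  }
  log <- tibble::tibble(sample_id = reads$sample_id, status = status) |>
    dplyr::count(.data$sample_id, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("assigned", "ambiguous", "low_score")) {
    if (!col %in% names(log)) log[[col]] <- 0L
  }
  log$total <- log$assigned + log$ambiguous + log$low_score

  counts <- dplyr::bind_cols(
    tibble::tibble(clone_id = library$clone_id),
    tibble::as_tibble(m)
  )
  attr(counts, "mapping_log") <- log
  attr(counts, "read_assignments") <- tibble::tibble(
    sample_id = reads$sample_id,
    read_id = reads$read_id,
    clone_id = assigned_clone,
    status = status
  )
  counts
}

#' Per-read assignments of a [map_reads()] result
#'
#' @param counts Value returned by [map_reads()].
#' @return Tibble with one row per input read: `sample_id`, `read_id`,
#'   `clone_id` (`NA` unless assigned) and `status`.
#' @export
read_assignments <- function(counts) attr(counts, "read_assignments")

#' Per-sample mapping log of a [map_reads()] result
#'
#' @param counts Value returned by [map_reads()].
#' @return Tibble with per-sample `assigned`, `ambiguous`, `low_score`, `total`.
#' @export
mapping_log <- function(counts) attr(counts, "mapping_log")

# hash of template k-mers -> integer matrix (template index, 1-based position)
seed_index <- function(templates, k, max_seed_hits) {
  kmers <- character(0); t_idx <- integer(0); t_pos <- integer(0)
  for (ti in seq_along(templates)) {
    s <- templates[[ti]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    pos <- seq_len(n)
    kmers <- c(kmers, substring(s, pos, pos + k - 1L))
    t_idx <- c(t_idx, rep.int(ti, n))
    t_pos <- c(t_pos, pos)
  }
  hits <- split(seq_along(kmers), kmers)
  # drop repetitive seeds (shared flanks and the like)
  n_templates_per_kmer <- vapply(
    hits, function(ii) length(unique(t_idx[ii])), integer(1)
  )
  hits <- hits[n_templates_per_kmer <= max_seed_hits]
  env <- list2env(
    lapply(hits, function(ii) cbind(t_idx[ii], t_pos[ii])),
    hash = TRUE, size = max(29L, 2L * length(hits))
  )
  env
}

# best contiguous segment score of +1/-1 comparisons on one diagonal
diag_local_score <- function(read_raw, tmpl_raw, offset, match, mismatch) {
  # read position i aligns to template position i + offset
  lo <- max(1L, 1L - offset)
  hi <- min(length(read_raw), length(tmpl_raw) - offset)
  if (hi < lo) return(-Inf)
  eq <- read_raw[lo:hi] == tmpl_raw[(lo + offset):(hi + offset)]
  x <- ifelse(eq, match, mismatch)
  s <- cumsum(x)
  max(s - cummin(c(0, s[-length(s)])))
}

align_read <- function(sequence, templates, idx, k, match, mismatch, min_score) {
  L <- nchar(sequence)
  if (L < k) return(list(clone = NA_character_, status = "low_score"))
  seed_at <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
  cand <- NULL
  for (p in seed_at) {
    hit <- idx[[substr(sequence, p, p + k - 1L)]]
    if (!is.null(hit)) {
      cand <- rbind(cand, cbind(hit[, 1], hit[, 2] - p)) # (template, offset)
    }
  }
  if (is.null(cand)) return(list(clone = NA_character_, status = "low_score"))
  cand <- unique(cand)
  read_raw <- charToRaw(sequence)
  tmpl_raws <- lapply(unique(cand[, 1]), function(ti) charToRaw(templates[[ti]]))
  names(tmpl_raws) <- as.character(unique(cand[, 1]))
  scores <- vapply(seq_len(nrow(cand)), function(j) {
    diag_local_score(read_raw, tmpl_raws[[as.character(cand[j, 1])]],
                     cand[j, 2], match, mismatch)
  }, numeric(1))
  best_by_clone <- tapply(scores, cand[, 1], max)
  best <- max(best_by_clone)
  if (best < min_score) return(list(clone = NA_character_, status = "low_score"))
  winners <- names(best_by_clone)[best_by_clone == best]
  if (length(winners) > 1) return(list(clone = NA_character_, status = "ambiguous"))
  list(clone = names(templates)[as.integer(winners)], status = "assigned")
}

#' Library-coverage quality control
#'
#' Coverage of the parent library per sample, defined as mapped reads divided
#' by the number of library clones, with pass flags at the 1x and 5x levels.
#'
#' @param counts Wide count tibble.
#' @param library A `phip_library`.
#' @return Tibble with `sample_id`, `mapped_reads`, `coverage_x`, `pass_1x`,
#'   `pass_5x`.
#' @export
qc_coverage <- function(counts, library) {
  m <- counts_matrix(counts)
  n_clones <- nrow(library)
  mapped <- unname(colSums(m))
  tibble::tibble(
    sample_id = colnames(m),
    mapped_reads = mapped,
    coverage_x = mapped / n_clones,
    pass_1x = mapped / n_clones >= 1,
    pass_5x = mapped / n_clones >= 5
  )
}
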