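#' Simulate sequencing reads from a count matrix
#'
#' Emits, for every clone-sample cell, exactly that many reads of length
#' `read_len` drawn from the clone's amplicon template (5' flank + insert + 3'
#' flank), with independent per-base substitution errors at `error_rate`. With
#' `error_rate = 0` every read is an exact substring of its template. The
#' default `"amplicon"` layout starts every read at the template 5' end, as
#' PCR-amplified display libraries are sequenced from a fixed vector primer;
#' `"random"` draws uniform start offsets instead (note that a random-offset
#' read can fall entirely inside the region a heavily overlapping terminal
#' tile shares with its neighbour and is then legitimately ambiguous to map).
#'
#' @param counts Wide count tibble (`clone_id` + one column per sample).
#' @param library The `phip_library` the counts refer to.
#' @param error_rate Per-base substitution probability.
#' @param read_len Read length in nt; must not exceed the template length.
#' @param seed Integer seed.
#' @param layout `"amplicon"` (fixed start, default) or `"random"`.
#' @return Tibble with `sample_id`, `read_id`, `clone_id` (true origin, for
#'   benchmarking only) and `sequence`.
#' @export
simulate_reads <- function(counts, library, error_rate = 0.001, read_len = 100L,
                           seed = 1L, layout = c("amplicon", "random")) {
  layout <- match.arg(layout)
  templates <- clone_templates(library)
  tlen <- nchar(templates)
  read_len <- as.integer(read_len)
  if (any(read_len > tlen)) {
    abort(sprintf("read_len (%d) exceeds the template length (%d).",
                  read_len, min(tlen)))
  }
  stopifnot(error_rate >= 0, error_rate < 1)
  m <- counts_matrix(counts)
  if (!all(rownames(m) %in% names(templates))) {
    abort("Count matrix contains clones absent from the library.")
  }
  bases <- c("A", "C", "G", "T")

  with_sim_seed(seed, {
    purrr::map_dfr(colnames(m), function(s) {
      n_per_clone <- m[, s]
      n_per_clone <- n_per_clone[n_per_clone > 0]
      if (!length(n_per_clone)) {
        return(tibble::tibble(sample_id = character(), read_id = character(),
                              clone_id = character(), sequence = character()))
      }
      origin <- rep(names(n_per_clone), n_per_clone)
      n_reads <- length(origin)
      starts <- if (layout == "random") {
        floor(runif(n_reads) * (tlen[origin] - read_len + 1)) + 1L
      } else {
        rep(1L, n_reads)
      }
      seqs <- unname(substring(templates[origin], starts, starts + read_len - 1L))
      n_err <- rbinom(n_reads, read_len, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(read_len, n_err[i])
        chars <- strsplit(seqs[i], "")[[1]]
        chars[pos] <- vapply(chars[pos],
                             function(b) sample(setdiff(bases, b), 1),
                             character(1))
        seqs[i] <- paste0(chars, collapse = "")
      }
      tibble::tibble(
        sample_id = s,
        read_id = sprintf("%s_read%06d", s, seq_len(n_reads)),
        clone_id = origin,
        sequence = seqs
      )
    })
  })
}

#' Write simulated reads as per-sample FASTQ files
#'
#' @param reads Tibble from [simulate_reads()].
#' @param dir Output directory (created if needed); one `<sample_id>.fastq`
#'   per sample, constant quality.
#' @return Character vector of written paths, invisibly.
#' @export
write_sample_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(reads, reads$sample_id), function(d) {
    path <- file.path(dir, paste0(d$sample_id[1], ".fastq"))
    qual <- strrep("I", nchar(d$sequence))
    writeLines(
      as.vector(rbind(paste0("@", d$read_id), d$sequence, "+", qual)),
      path
    )
    path
  }, character(1))
  invisible(paths)
}

#' Read a directory of per-sample FASTQ files
#'
#' Loads `*.fastq` files (sample id = file stem) into the tibble layout that
#' [map_reads()] consumes.
#'
#' @param dir Directory of FASTQ files.
#' @return Tibble with `sample_id`, `read_id`, `sequence`.
#' @export
read_fastq_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.fastq$", full.names = TRUE)
  if (!length(files)) abort(paste0("No .fastq files in ", dir))
  purrr::map_dfr(files, function(f) {
    lines <- readLines(f)
    if (length(lines) %% 4 != 0) {
      abort(sprintf("Malformed FASTQ %s: %d lines (not a multiple of 4).",
                    f, length(lines)))
    }
    ids <- lines[seq(1, length(lines), 4)]
    bad <- which(!startsWith(ids, "@"))
    if (length(bad)) {
      abort(sprintf("Malformed FASTQ record %d in %s.", bad[1], f))
    }
    tibble::tibble(
      sample_id = sub("\\.fastq$", "", basename(f)),
      read_id = sub("^@", "", sub("\\s.*$", "", ids)),
      sequence = toupper(lines[seq(2, length(lines), 4)])
    )
  })
}
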