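toy_library <- function() {
  # two proteins, 3 and 2 clones; clone ids follow the <protein>_<start> scheme
  structure(
    tibble::tibble(
      clone_id = c("PA_0", "PA_24", "PA_48", "PB_0", "PB_24"),
      protein_id = c("PA", "PA", "PA", "PB", "PB"),
      gene_symbol = c("GA", "GA", "GA", "GB", "GB"),
      start = c(0, 24, 48, 0, 24),
      peptide = "X", insert_nt = "NNN"
    ),
    class = c("phip_library", class(tibble::tibble())),
    tile_len = 49L, overlap = 25L, flank_5p = "", flank_3p = ""
  )
}

test_that("protein collapse is a Boolean OR over non-blacklisted clone hits", {
  lib <- toy_library()
  enr <- tidyr::expand_grid(clone_id = lib$clone_id,
                            sample_id = c("s1", "s2", "s3"))
  enr$is_hit <- FALSE
  enr$blacklisted <- FALSE
  enr$is_hit[enr$clone_id == "PA_0" & enr$sample_id == "s1"] <- TRUE    # 1 of 3
  enr$is_hit[enr$clone_id == "PA_48" & enr$sample_id == "s2"] <- TRUE   # other epitope
  rx <- collapse_to_protein(enr, lib)
  get <- function(p, s) rx$reactive[rx$protein_id == p & rx$sample_id == s]
  expect_true(get("PA", "s1"))
  expect_true(get("PA", "s2"))   # reactive regardless of which epitope
  expect_false(get("PA", "s3"))
  expect_false(get("PB", "s1"))  # zero hit clones

  # blacklisted hits do not count
  enr$blacklisted[enr$clone_id == "PA_0"] <- TRUE
  rx2 <- collapse_to_protein(enr, lib)
  expect_false(rx2$reactive[rx2$protein_id == "PA" & rx2$sample_id == "s1"])

  expect_error(collapse_to_protein(dplyr::mutate(enr, clone_id = "nope"), lib),
               "Unknown clone_id")
})

test_that("collapsing an already-protein-level matrix is the identity", {
  lib <- toy_library()
  plib <- lib
  plib$clone_id <- plib$protein_id
  plib <- plib[!duplicated(plib$clone_id), ]
  prot_hits <- tidyr::expand_grid(clone_id = c("PA", "PB"),
                                  sample_id = c("s1", "s2"))
  prot_hits$is_hit <- c(TRUE, FALSE, FALSE, TRUE)
  rx <- collapse_to_protein(prot_hits, plib)
  joined <- dplyr::left_join(prot_hits, rx,
                             by = c(clone_id = "protein_id", "sample_id"))
  expect_equal(joined$reactive, joined$is_hit)
})

test_that("two-sided Fisher test reproduces published and enumerated values", {
  expect_equal(round(fisher_exact_2x2(10, 2, 2, 10), 3), 0.003)
  expect_equal(round(fisher_exact_2x2(8, 4, 1, 11), 3), 0.009)
  expect_equal(fisher_exact_2x2(0, 12, 0, 12), 1)
  expect_equal(fisher_exact_2x2(6, 6, 0, 12), oracle_fisher_p(6, 6, 0, 12),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(6, 6, 0, 12), 0.01373, tolerance = 1e-4)
})

test_that("Fisher test equals enumeration and fisher.test on random tables", {
  set.seed(19)
  for (i in 1:200) {
    r1 <- sample(0:50, 1); r2 <- sample(0:50, 1)
    if (r1 + r2 == 0) next
    a <- if (r1 > 0) sample(0:r1, 1) else 0
    c_ <- if (r2 > 0) sample(0:r2, 1) else 0
    p <- fisher_exact_2x2(a, r1 - a, c_, r2 - c_)
    expect_equal(p, oracle_fisher_p(a, r1 - a, c_, r2 - c_), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(c(a, r1 - a, c_, r2 - c_), 2,
                                              byrow = TRUE))$p.value,
                 tolerance = 1e-9)
    # symmetry under swapping the arms
    expect_equal(p, fisher_exact_2x2(c_, r2 - c_, a, r1 - a), tolerance = 1e-12)
  }
  # doubling convention never falls below the one-tailed p
  expect_gte(fisher_exact_2x2(10, 2, 2, 10, method = "doubling"),
             fisher_exact_2x2(10, 2, 2, 10))
})

make_reactivity <- function(tab, groups) {
  # tab: named list protein -> named logical/integer per sample
  samples <- names(groups)
  purrr::imap_dfr(tab, function(v, p) tibble::tibble(
    protein_id = p, sample_id = samples, reactive = as.logical(v)
  ))
}

test_that("group-vs-rest comparison flags distinct antigens at p < 0.05", {
  groups <- c(rep("oMMP", 12), rep("MMP", 6), rep("BP", 3), rep("mcPV", 3))
  meta <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(groups)),
    group = groups, is_control = FALSE
  )
  names(groups) <- meta$sample_id
  rx <- make_reactivity(list(
    ALLPOS = rep(TRUE, 24),
    TNKS = c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 10)),
    HALF  = c(rep(TRUE, 6), rep(FALSE, 6), rep(FALSE, 12))
  ), groups)
  cmp <- group_vs_rest(rx, meta, "oMMP")
  row <- function(p) cmp[cmp$protein_id == p, ]
  expect_equal(row("ALLPOS")$p, 1)
  expect_false(row("ALLPOS")$distinct)
  expect_equal(row("TNKS")[, c("a", "b", "c", "d")],
               tibble::tibble(a = 10L, b = 2L, c = 2L, d = 10L),
               ignore_attr = TRUE)
  expect_true(row("TNKS")$distinct)
  expect_equal(round(row("TNKS")$p, 3), 0.003)
  expect_true(row("HALF")$distinct)   # 6/12 vs 0/12
  expect_equal(row("HALF")$pct_group, 50)   # truncated percentage
  expect_equal(row("TNKS")$pct_rest, 16)    # 2/12 -> 16, truncation not rounding
  expect_error(group_vs_rest(rx, meta, "nonexistent"), "not present")
})

test_that("bead and spike samples are excluded from group comparisons", {
  meta <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2", "bead1", "spike1"),
    group = c("g1", "g1", "g2", "g2", "beads", "spike"),
    is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  rx <- tidyr::expand_grid(protein_id = "P", sample_id = meta$sample_id)
  rx$reactive <- rx$sample_id %in% c("a1", "a2", "bead1", "spike1")
  cmp <- group_vs_rest(rx, meta, "g1")
  expect_equal(cmp$a + cmp$b, 2L)   # only the two g1 serum samples
  expect_equal(cmp$c + cmp$d, 2L)
  expect_equal(cmp$a, 2L)
  expect_equal(cmp$c, 0L)
})

test_that("z-scored proportions follow the sample-sd convention", {
  cmp <- tibble::tibble(
    protein_id = rep(c("P1", "P2", "P3"), each = 4),
    group = rep(c("g1", "g2", "g3", "g4"), 3),
    prop_group = c(1, 0, 0, 0,
                   0.5, 0.5, 0.5, 0.5,
                   0.8, 0.2, 0.2, 0.2)
  )
  z <- proportion_zscores(cmp)
  zm <- as.matrix(z[, -1])
  expect_equal(unname(zm[1, 1]), 1.5)            # (1,0,0,0): symmetric split
  expect_equal(unname(zm[1, 2:4]), rep(-0.5, 3))
  expect_equal(unname(rowMeans(zm)), rep(0, 3))
  expect_equal(unname(zm[2, ]), rep(0, 4))       # zero-spread row -> zeros
  expect_equal(unname(zm[3, ]), c(1.5, -0.5, -0.5, -0.5))
  # population-sd variant scales rows by sqrt((n-1)/n)
  zp <- as.matrix(proportion_zscores(cmp, sd_type = "population")[, -1])
  expect_equal(unname(zp[3, ]), c(1.5, -0.5, -0.5, -0.5) * sqrt(4 / 3))
})

test_that("set overlap partitions antigen lists exactly", {
  a <- c("NCAM2", "ABCB9", "PCDHB3", "PCDH1", "X1")
  b <- c("NCAM2", "ABCB9", "PCDHB3", "PCDH1", "Y1")
  ov <- set_overlap(a, b)
  expect_equal(ov$counts$intersection, 4)
  expect_setequal(ov$intersection, c("NCAM2", "ABCB9", "PCDHB3", "PCDH1"))
  expect_equal(ov$a_only, "X1")
  expect_equal(ov$b_only, "Y1")
  same <- set_overlap(a, a)
  expect_setequal(same$intersection, a)
  expect_length(same$a_only, 0)
  expect_equal(set_overlap(c("p", "q"), c("r"))$counts$intersection, 0)
})

test_that("plots and tidiers produce the expected object types", {
  x <- small_sim(seed = 2)
  enr <- call_enrichment(x$sim$counts, x$sim$meta)
  rx <- collapse_to_protein(enr, x$lib)
  cmp <- compare_groups(rx, x$sim$meta)
  expect_s3_class(autoplot(enr), "ggplot")
  expect_s3_class(autoplot(cmp), "ggplot")
  z <- proportion_zscores(cmp)
  expect_s3_class(autoplot(z), "ggplot")
  qc <- qc_coverage(x$sim$counts, x$lib)
  expect_s3_class(plot_coverage(qc), "ggplot")
  expect_s3_class(glance(cmp), "tbl_df")
  expect_true(all(c("group", "n_distinct_antigens") %in% names(glance(cmp))))
})
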