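test_that("size factors are totals over their geometric mean", {
  mk <- function(totals) {
    tibble::tibble(clone_id = c("a", "b"),
                   !!!setNames(lapply(totals, function(t) c(t * 0.25, t * 0.75)),
                               paste0("s", seq_along(totals))))
  }
  expect_equal(size_factors(mk(c(100, 100, 100)))$size_factor, rep(1, 3))
  expect_equal(size_factors(mk(c(1e6, 4e6)))$size_factor, c(0.5, 2))
  expect_equal(size_factors(mk(5000))$size_factor, 1)
  expect_error(size_factors(mk(c(100, 0))), "zero total")
})

test_that("moment dispersion estimates match the closed formula", {
  # clone 1: variance = mean (Poisson-like); clone 2: mean 100, var 600;
  # clone 3: constant
  set.seed(1)
  n <- 2001
  x1 <- rpois(n, 50)
  x2 <- round(100 + sqrt(600) * as.vector(scale(rnorm(n))))
  # a large constant "ballast" clone keeps all size factors at ~1 so the
  # normalized moments equal the raw ones
  counts <- tibble::tibble(clone_id = c("c0", "c1", "c2", "c3"))
  counts <- dplyr::bind_cols(counts, tibble::as_tibble(
    setNames(as.data.frame(rbind(1e6, x1, x2, 70)), paste0("s", 1:n))
  ))
  disp <- estimate_dispersion(counts, shrinkage_weight = 0)
  expect_equal(disp$phi_raw[2], 0, tolerance = 0.02)
  # raw moment estimate (600 - 100) / 100^2 = 0.05, up to rounding noise
  expect_equal(disp$phi_raw[3], 0.05, tolerance = 0.01)
  expect_equal(disp$phi_raw[4], 0)
  expect_error(estimate_dispersion(counts[, 1:2]), ">= 2")
})

test_that("exact NB test matches brute-force split enumeration", {
  set.seed(7)
  for (phi in c(0, 0.1, 1)) {
    for (m in c(2, 6, 36)) {
      for (rep in 1:25) {
        T_tot <- sample(1:200, 1)
        y <- sample(0:T_tot, 1)
        # controls summing to T - y
        ctrl <- rep((T_tot - y) %/% m, m)
        ctrl[seq_len((T_tot - y) %% m)] <- ctrl[seq_len((T_tot - y) %% m)] + 1
        res <- nb_exact_test(y, ctrl, phi)
        expect_equal(res$p, oracle_nb_split_p(y, T_tot - y, m, phi),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("phi = 0 reduces to the two-sided exact binomial test", {
  res <- nb_exact_test(20, 10, phi = 0)
  expect_equal(res$p, stats::binom.test(20, 30, 0.5)$p.value, tolerance = 1e-12)
  # null case: sample equal to the control mean
  null <- nb_exact_test(10, c(10, 10), phi = 0.1)
  expect_gte(null$p, 0.5)
  expect_equal(null$log2fc, 0, tolerance = 1e-9)
})

test_that("small-dispersion NB test converges to the conditional binomial", {
  # at phi = 1e-8 the conditional NB law agrees with the binomial to a
  # relative error < 1e-6 for small-count cells ...
  for (y in 0:12) {
    for (csum in c(2, 5, 12)) {
      for (m in c(2, 4)) {
        ctrl <- rep(csum %/% m, m); ctrl[1] <- ctrl[1] + csum %% m
        p_nb <- nb_exact_test(y, ctrl, phi = 1e-8)$p
        p_bin <- oracle_binom_split_p(y, csum, m)
        expect_lt(abs(p_nb - p_bin) / p_bin, 1e-6)
      }
    }
  }
  # ... and converges linearly in phi everywhere, including deep tails where
  # the residual model distance at any fixed phi is larger
  rel_err <- function(phi) {
    worst <- 0
    for (y in c(0, 17, 60)) for (csum in c(40, 200)) for (m in c(2, 8)) {
      ctrl <- rep(csum %/% m, m); ctrl[1] <- ctrl[1] + csum %% m
      p_nb <- nb_exact_test(y, ctrl, phi = phi)$p
      p_bin <- oracle_binom_split_p(y, csum, m)
      worst <- max(worst, abs(p_nb - p_bin) / p_bin)
    }
    worst
  }
  e8 <- rel_err(1e-8); e10 <- rel_err(1e-10)
  expect_lt(e8, 1e-4)
  expect_lt(e10, 1.02 * e8 / 100)   # linear decay in phi
})

test_that("p decays monotonically on both sides of its null maximum", {
  # both enrichment and depletion drive the two-sided p down: p as a function
  # of the sample count is unimodal, peaking at the conditional mode
  for (phi in c(0, 0.15)) {
    ctrl <- rep(30, 4)
    ys <- 0:80
    ps <- vapply(ys, function(y) nb_exact_test(y, ctrl, phi)$p, numeric(1))
    peak <- which.max(ps)
    expect_true(all(diff(ps[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(ps[peak:length(ps)]) <= 1e-12))
    # the peak sits near the conditional null expectation csum / m = 30
    expect_lt(abs(ys[peak] - 30), 6)
  }
})

test_that("hit calling applies the dual thresholds with exact boundaries", {
  res <- tibble::tibble(
    log2fc = c(2.0, 1.99, 8, 3),
    p = c(1e-5, 1e-9, 1e-4, 2e-5)
  )
  out <- call_hits(res)
  # log2fc >= 2 is inclusive; -log10 p > 4 is strict (p = 1e-4 fails)
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(hit_thresholds(min_log2fc = 0))
})

test_that("leave-one-out blacklisting flags control-enriched clones", {
  set.seed(33)
  n_ctrl <- 10
  counts <- tibble::tibble(clone_id = sprintf("c%02d", 1:40))
  base <- matrix(rpois(40 * n_ctrl, 50), 40, n_ctrl)
  base[5, 1] <- 5000                       # one control at 100x its peers
  counts <- dplyr::bind_cols(counts, tibble::as_tibble(
    setNames(as.data.frame(base), sprintf("b%02d", 1:n_ctrl))
  ))
  disp0 <- estimate_dispersion(counts)
  disp0$phi <- rep(0.05, nrow(disp0))      # known dispersion for the construct
  bl <- control_blacklist(counts, dispersion = disp0)
  expect_true("c05" %in% bl)
  expect_lte(length(setdiff(bl, "c05")), 1)  # null clones essentially clean

  expect_error(control_blacklist(counts[, 1:3]), ">= 3")
})

test_that("blacklisted hits are excluded from protein pooling", {
  x <- small_sim(seed = 41)
  enr <- call_enrichment(x$sim$counts, x$sim$meta)
  # force-blacklist a hit clone and confirm the protein call disappears
  hit <- dplyr::filter(enr, is_hit)[1, ]
  enr2 <- enr
  enr2$blacklisted[enr2$clone_id == hit$clone_id] <- TRUE
  other_clones <- setdiff(x$lib$clone_id[x$lib$protein_id ==
    x$lib$protein_id[x$lib$clone_id == hit$clone_id]], hit$clone_id)
  rx2 <- collapse_to_protein(enr2, x$lib)
  still_hit <- any(enr2$is_hit[enr2$clone_id %in% other_clones &
                                 enr2$sample_id == hit$sample_id])
  protein <- x$lib$protein_id[x$lib$clone_id == hit$clone_id]
  reactive <- rx2$reactive[rx2$protein_id == protein &
                             rx2$sample_id == hit$sample_id]
  expect_equal(reactive, still_hit)
})

test_that("call_enrichment output is consistent and tidies cleanly", {
  x <- small_sim(seed = 2)
  enr <- call_enrichment(x$sim$counts, x$sim$meta)
  serum <- x$sim$meta$sample_id[!x$sim$meta$is_control]
  expect_setequal(unique(enr$sample_id), serum)
  expect_equal(nrow(enr), nrow(x$lib) * length(serum))
  expect_true(all(enr$p >= 0 & enr$p <= 1))
  expect_true(all(enr$is_hit == (enr$log2fc >= 2 & enr$p < 1e-4)))
  g <- glance(enr)
  expect_equal(g$n_clones, nrow(x$lib))
  expect_s3_class(tidy(enr), "tbl_df")
  expect_error(call_enrichment(x$sim$counts[, 1:5], x$sim$meta), "metadata")
})
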