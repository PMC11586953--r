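#' Per-sample size factors
#'
#' Library-size factors defined as each sample's total count divided by the
#' geometric mean of all totals; dividing a sample's counts by its factor puts
#' every sample on the common (geometric-mean) depth.
#'
#' @param counts Wide count tibble (`clone_id` + one column per sample).
#' @return Tibble with `sample_id`, `total`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    abort(paste0("Sample has zero total count: ",
                 colnames(m)[which(totals <= 0)[1]]))
  }
  tibble::tibble(
    sample_id = colnames(m),
    total = unname(totals),
    size_factor = unname(totals / exp(mean(log(totals))))
  )
}

#' Counts per million
#'
#' @param counts Wide count tibble.
#' @return Wide tibble of the same shape with counts scaled to per-million.
#' @export
cpm <- function(counts) {
  m <- counts_matrix(counts)
  out <- sweep(m, 2, colSums(m) / 1e6, "/")
  dplyr::bind_cols(tibble::tibble(clone_id = counts$clone_id),
                   tibble::as_tibble(out))
}

#' Estimate per-clone negative-binomial dispersion from bead controls
#'
#' Method-of-moments estimation on depth-normalized control counts: for each
#' clone, `phi_raw = max(0, (var - mean) / mean^2)` (so variance =
#' mean + phi * mean^2; 0 is the Poisson limit), then shrinkage toward the
#' trimmed-mean common dispersion:
#' `phi = (1 - w) * phi_raw + w * phi_common`.
#'
#' @param counts Wide count tibble containing (at least) the control samples.
#' @param meta Sample metadata with `sample_id`, `is_control`; only control
#'   samples are used. Pass `NULL` to treat every column as a control.
#' @param shrinkage_weight Weight `w` in `[0, 1]` on the common dispersion.
#' @param trim Trim fraction for the common-dispersion trimmed mean.
#' @return A `phip_dispersion` tibble with `clone_id`, `mu` (normalized control
#'   mean), `phi_raw`, `phi`; the common dispersion and weight are attached as
#'   attributes.
#' @export
estimate_dispersion <- function(counts, meta = NULL, shrinkage_weight = 0.5,
                                trim = 0.1) {
  m <- counts_matrix(counts)
  if (!is.null(meta)) {
    ctrl <- meta$sample_id[meta$is_control]
    m <- m[, colnames(m) %in% ctrl, drop = FALSE]
  }
  if (ncol(m) < 2) abort("Dispersion estimation needs >= 2 control samples.")
  sf <- colSums(m) / exp(mean(log(colSums(m))))
  norm <- sweep(m, 2, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  phi_raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  phi_common <- mean(phi_raw[mu > 0], trim = trim)
  if (!is.finite(phi_common)) phi_common <- 0
  phi <- (1 - shrinkage_weight) * phi_raw + shrinkage_weight * phi_common
  structure(
    tibble::tibble(clone_id = rownames(m), mu = unname(mu),
                   phi_raw = unname(phi_raw), phi = unname(phi)),
    class = c("phip_dispersion", class(tibble::tibble())),
    phi_common = phi_common,
    shrinkage_weight = shrinkage_weight
  )
}

# log pmf (up to a constant) of the split y | y + c = T when the sample count
# is NB(size r1) and the control sum NB(size r2) at a shared success
# probability: negative hypergeometric. A and B are precomputed tables of
#   A[y + 1] = log C(y + r - 1, y) = sum_{j=1..y} log((r + j - 1) / j),
# accumulated as a cumulative sum of moderate logs rather than differences of
# lgamma(), which stays accurate even for very large r (tiny dispersion).
nb_logchoose_table <- function(r, tmax) {
  if (tmax == 0) return(0)
  js <- seq_len(tmax)
  c(0, cumsum(log1p((r - 1) / js)))
}

nb_split_logpmf <- function(T_tot, A, B) {
  A[seq_len(T_tot + 1)] + B[rev(seq_len(T_tot + 1))]
}

# two-sided minimum-likelihood p from a log pmf (up to constant) and the
# observed index (1-based = y + 1)
minlike_p <- function(lp, obs_idx) {
  w <- exp(lp - max(lp))
  sum(w[lp <= lp[obs_idx] + log(1 + 1e-7)]) / sum(w)
}

# p-values for one clone: observed counts y_vec each tested against the same
# set of m controls summing to csum (all counts already depth-equalized and
# rounded). Returns one p per element of y_vec.
nb_exact_clone <- function(y_vec, csum, m, phi) {
  T_vec <- y_vec + csum
  if (phi <= 0) {
    return(vapply(seq_along(y_vec), function(i) {
      T_tot <- T_vec[i]
      if (T_tot == 0) return(1)
      lp <- dbinom(0:T_tot, T_tot, 1 / (1 + m), log = TRUE)
      minlike_p(lp, y_vec[i] + 1L)
    }, numeric(1)))
  }
  r1 <- 1 / phi
  r2 <- m / phi
  tmax <- max(T_vec)
  A <- nb_logchoose_table(r1, tmax)
  B <- nb_logchoose_table(r2, tmax)
  vapply(seq_along(y_vec), function(i) {
    T_tot <- T_vec[i]
    if (T_tot == 0) return(1)
    minlike_p(nb_split_logpmf(T_tot, A, B), y_vec[i] + 1L)
  }, numeric(1))
}

# p-values for all leave-one-out control tests of one clone. Every test
# conditions on the same total (the sum of all controls), so one shared pmf
# serves all m tests.
nb_exact_loo <- function(ctrl_vec, phi) {
  m <- length(ctrl_vec)
  T_tot <- sum(ctrl_vec)
  if (T_tot == 0) return(rep(1, m))
  if (phi <= 0) {
    lp <- dbinom(0:T_tot, T_tot, 1 / m, log = TRUE)
  } else {
    r1 <- 1 / phi
    r2 <- (m - 1) / phi
    A <- nb_logchoose_table(r1, T_tot)
    B <- nb_logchoose_table(r2, T_tot)
    lp <- nb_split_logpmf(T_tot, A, B)
  }
  w <- exp(lp - max(lp))
  tot <- sum(w)
  vapply(ctrl_vec, function(y) {
    sum(w[lp <= lp[y + 1L] + log(1 + 1e-7)]) / tot
  }, numeric(1))
}

#' Exact conditional negative-binomial enrichment test
#'
#' Tests whether a sample's count for one clone is enriched relative to a set
#' of control counts, assuming negative-binomial counts with dispersion `phi`
#' (`variance = mu + phi * mu^2`). Counts are first equalized to the common
#' (geometric-mean) depth via size factors and rounded; conditional on the
#' summed count, the sample/controls split follows a negative hypergeometric
#' law that is free of the unknown mean, and the two-sided p-value sums the
#' probabilities of all splits no more probable than the one observed
#' (minimum-likelihood convention, as in R's `fisher.test`). At `phi = 0` the
#' conditional law is binomial (Poisson limit).
#'
#' @param sample_count Observed count in the tested sample.
#' @param control_counts Vector of counts in the control samples.
#' @param phi Negative-binomial dispersion (>= 0).
#' @param sample_sf,control_sf Size factors for depth equalization (default 1).
#' @param pseudocount Added to both sides of the fold change (default 0.5).
#' @return List with `p` (two-sided exact p-value) and `log2fc`
#'   (`log2((y + 0.5) / (mean(controls) + 0.5))` on the normalized scale).
#' @export
#' @examples
#' nb_exact_test(20, 10, phi = 0)  # equals a two-sided binomial test of 20/30
nb_exact_test <- function(sample_count, control_counts, phi,
                          sample_sf = 1, control_sf = rep(1, length(control_counts)),
                          pseudocount = 0.5) {
  if (sample_count < 0 || any(control_counts < 0)) {
    abort("Counts must be non-negative.")
  }
  if (phi < 0) abort("`phi` must be >= 0.")
  y <- round(sample_count / sample_sf)
  ctrl <- round(control_counts / control_sf)
  p <- nb_exact_clone(y, sum(ctrl), length(ctrl), phi)
  log2fc <- log2((sample_count / sample_sf + pseudocount) /
                   (mean(control_counts / control_sf) + pseudocount))
  list(p = p, log2fc = log2fc)
}

#' Hit-calling thresholds
#'
#' @param min_log2fc Minimum log2 fold change, inclusive (default 2).
#' @param min_neglog10p Minimum -log10 p, exclusive (default 4, i.e. p < 1e-4).
#' @return A `phip_thresholds` list.
#' @export
hit_thresholds <- function(min_log2fc = 2, min_neglog10p = 4) {
  stopifnot(min_log2fc > 0, min_neglog10p > 0)
  structure(list(min_log2fc = min_log2fc, min_neglog10p = min_neglog10p),
            class = "phip_thresholds")
}

#' Apply hit thresholds to enrichment results
#'
#' A clone-sample pair is a hit when `log2fc >= min_log2fc` (inclusive, "at
#' least") and `-log10(p) > min_neglog10p` (strict).
#'
#' @param results Data frame with `log2fc` and `p` columns.
#' @param thresholds A [hit_thresholds()].
#' @return `results` with an `is_hit` logical column (re)computed.
#' @export
call_hits <- function(results, thresholds = hit_thresholds()) {
  results$is_hit <- results$log2fc >= thresholds$min_log2fc &
    results$p < 10^(-thresholds$min_neglog10p)
  results
}

#' Blacklist clones enriched in any bead-only control
#'
#' Each control sample is tested leave-one-out against the remaining controls
#' with the same exact test and thresholds used for serum samples; a clone
#' called a hit in any control joins the blacklist, and blacklisted clones are
#' excluded from protein-level pooling downstream. This guards against clones
#' that bind beads or protein A/G rather than serum antibodies.
#'
#' @param counts Wide count tibble containing the control samples.
#' @param meta Metadata (`sample_id`, `is_control`), or `NULL` to use all
#'   columns as controls.
#' @param dispersion Optional `phip_dispersion`; estimated from the controls
#'   when `NULL`.
#' @param thresholds A [hit_thresholds()].
#' @return Character vector of blacklisted `clone_id`s.
#' @export
control_blacklist <- function(counts, meta = NULL, dispersion = NULL,
                              thresholds = hit_thresholds()) {
  m <- counts_matrix(counts)
  if (!is.null(meta)) {
    m <- m[, colnames(m) %in% meta$sample_id[meta$is_control], drop = FALSE]
  }
  if (ncol(m) < 3) {
    abort("Blacklisting needs >= 3 controls (leave-one-out keeps >= 2).")
  }
  if (is.null(dispersion)) {
    cc <- dplyr::bind_cols(tibble::tibble(clone_id = rownames(m)),
                           tibble::as_tibble(m))
    dispersion <- estimate_dispersion(cc)
  }
  sf <- colSums(m) / exp(mean(log(colSums(m))))
  scaled <- round(sweep(m, 2, sf, "/"))
  norm <- sweep(m, 2, sf, "/")
  phi <- setNames(dispersion$phi, dispersion$clone_id)[rownames(m)]
  n_ctrl <- ncol(m)
  p_cut <- 10^(-thresholds$min_neglog10p)
  black <- logical(nrow(m))
  for (k in seq_len(nrow(m))) {
    ctrl <- scaled[k, ]
    if (sum(ctrl) == 0) next
    loo_means <- (sum(norm[k, ]) - norm[k, ]) / (n_ctrl - 1)
    log2fc <- log2((norm[k, ] + 0.5) / (loo_means + 0.5))
    if (all(log2fc < thresholds$min_log2fc)) next
    p <- nb_exact_loo(ctrl, phi[k])
    black[k] <- any(log2fc >= thresholds$min_log2fc & p < p_cut)
  }
  rownames(m)[black]
}

#' Call enriched clones per sample against bead-only controls
#'
#' The full clone-level enrichment stage: size-factor depth equalization,
#' moment/shrinkage dispersion estimation from the bead controls
#' ([estimate_dispersion()]), an exact conditional negative-binomial test of
#' every non-control sample against the pooled controls ([nb_exact_test()]),
#' dual-threshold hit calling ([call_hits()]) and the leave-one-out control
#' blacklist ([control_blacklist()]).
#'
#' @param counts Wide count tibble (`clone_id` + one column per sample).
#' @param meta Sample metadata with `sample_id`, `group`, `is_control`.
#' @param thresholds A [hit_thresholds()].
#' @param dispersion Optional precomputed `phip_dispersion`.
#' @param pseudocount Fold-change stabilization (default 0.5).
#' @return A `phip_enrichment` tibble, one row per clone and non-control
#'   sample: `clone_id`, `sample_id`, `log2fc`, `p`, `is_hit`, `blacklisted`.
#'   Attributes: `blacklist`, `dispersion`, `thresholds`, `size_factors`.
#' @export
call_enrichment <- function(counts, meta, thresholds = hit_thresholds(),
                            dispersion = NULL, pseudocount = 0.5) {
  m <- counts_matrix(counts)
  missing <- setdiff(meta$sample_id, colnames(m))
  if (length(missing)) {
    abort(paste0("Samples in metadata but not in counts: ",
                 toString(head(missing, 3))))
  }
  ctrl_ids <- meta$sample_id[meta$is_control]
  test_ids <- meta$sample_id[!meta$is_control]
  if (length(ctrl_ids) < 2) abort("Need >= 2 control samples.")
  if (!length(test_ids)) abort("No non-control samples to test.")

  sf_tbl <- size_factors(counts[, c("clone_id", meta$sample_id)])
  sf <- setNames(sf_tbl$size_factor, sf_tbl$sample_id)
  norm <- sweep(m[, meta$sample_id, drop = FALSE], 2, sf[meta$sample_id], "/")
  scaled <- round(norm)

  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts[, c("clone_id", ctrl_ids)])
  }
  phi <- setNames(dispersion$phi, dispersion$clone_id)[rownames(m)]

  ctrl_scaled <- scaled[, ctrl_ids, drop = FALSE]
  ctrl_norm_mean <- rowMeans(norm[, ctrl_ids, drop = FALSE])
  csum <- rowSums(ctrl_scaled)
  n_ctrl <- length(ctrl_ids)

  pmat <- matrix(NA_real_, nrow(m), length(test_ids),
                 dimnames = list(rownames(m), test_ids))
  for (k in seq_len(nrow(m))) {
    pmat[k, ] <- nb_exact_clone(scaled[k, test_ids], csum[k], n_ctrl, phi[k])
  }
  fcmat <- log2((norm[, test_ids, drop = FALSE] + pseudocount) /
                  (ctrl_norm_mean + pseudocount))

  blacklist <- if (n_ctrl >= 3) {
    control_blacklist(counts[, c("clone_id", ctrl_ids)],
                      dispersion = dispersion, thresholds = thresholds)
  } else character(0)

  res <- tibble::tibble(
    clone_id = rep(rownames(m), times = length(test_ids)),
    sample_id = rep(test_ids, each = nrow(m)),
    log2fc = as.vector(fcmat),
    p = as.vector(pmat)
  )
  res <- call_hits(res, thresholds)
  res$blacklisted <- res$clone_id %in% blacklist
  structure(
    res,
    class = c("phip_enrichment", class(tibble::tibble())),
    blacklist = blacklist,
    dispersion = dispersion,
    thresholds = thresholds,
    size_factors = sf_tbl
  )
}
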