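# Independent oracles used across the suite. These deliberately take a
# different computational route from the package internals:
#  - the NB split oracle enumerates dnbinom()/dpois() products and normalizes,
#  - the Fisher oracle enumerates choose() products over the table family.

# Two-sided minimum-likelihood p for the sample/controls split of a total,
# by brute-force enumeration of every split.
oracle_nb_split_p <- function(y, ctrl_sum, m, phi) {
  T_tot <- y + ctrl_sum
  if (T_tot == 0) return(1)
  ys <- 0:T_tot
  lp <- if (phi == 0) {
    stats::dpois(ys, 1, log = TRUE) + stats::dpois(T_tot - ys, m, log = TRUE)
  } else {
    stats::dnbinom(ys, size = 1 / phi, mu = 1, log = TRUE) +
      stats::dnbinom(T_tot - ys, size = m / phi, mu = m, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[y + 1] * (1 + 1e-7)])
}

# Conditional binomial two-sided (minimum-likelihood) p for the same split.
oracle_binom_split_p <- function(y, ctrl_sum, m) {
  T_tot <- y + ctrl_sum
  if (T_tot == 0) return(1)
  pr <- stats::dbinom(0:T_tot, T_tot, 1 / (1 + m))
  sum(pr[pr <= pr[y + 1] * (1 + 1e-7)])
}

# Two-sided Fisher p by direct enumeration with binomial coefficients.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  lpr <- lchoose(r1, support) + lchoose(r2, k - support) - lchoose(N, k)
  pr <- exp(lpr)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# Small deterministic protein table for tiling tests.
fixed_proteins <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seq_of <- function(len, offset = 0) {
    paste0(aa[((seq_len(len) - 1 + offset) %% 20) + 1], collapse = "")
  }
  tibble::tibble(
    protein_id = c("P49", "P97", "P100", "P30"),
    gene_symbol = c("G49", "G97", "G100", "G30"),
    sequence = c(seq_of(49), seq_of(97, 3), seq_of(100, 7), seq_of(30, 11))
  )
}

# Compact experiment used by several downstream tests.
small_sim <- function(seed = 11, fold_change = 16, sporadic_rate = 0.5,
                      n_proteins = 25, depth = 2e4, n_beads = 8,
                      group_sizes = c(oMMP = 4, MMP = 3),
                      spike_doses = numeric(0), ...) {
  cfg <- sim_config(
    seed = seed, n_proteins = n_proteins, protein_len_range = c(60, 200),
    depth_per_sample = depth, group_sizes = group_sizes,
    n_bead_controls = n_beads, signature_proteins_per_group = 2,
    fold_change = fold_change, sporadic_rate = sporadic_rate,
    spike_doses = spike_doses, ...
  )
  lib <- build_library(simulate_proteome(cfg))
  list(cfg = cfg, lib = lib, sim = simulate_phipseq(lib, cfg))
}
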