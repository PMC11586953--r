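#' Configuration for a simulated PhIP-seq experiment
#'
#' Collects every knob of the generative model in one validated list. The
#' defaults emulate the study design the package targets: four autoimmune
#' blistering disease (AIBD) serum groups sized 12 (oMMP), 6 (MMP), 3 (BP) and
#' 3 (mcPV), 36 bead-only mock immunoprecipitations as negative controls, and
#' an antibody spike-in at two dose levels (10 and 2 micrograms).
#'
#' Per-clone baseline abundances are log-normal; counts for a sample are drawn
#' by gamma-multinomial sampling: a gamma-mixed relative abundance per clone
#' (negative-binomial marginally, dispersion `nb_dispersion` where
#' `variance = mu + phi * mu^2`) renormalized multinomially to exactly
#' `depth_per_sample` reads, so column totals equal the sequencing depth.
#' Serum samples multiply the abundances of their reactive clones by
#' `fold_change` before renormalization.
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param n_proteins Number of proteins when simulating a proteome.
#' @param protein_len_range Length range (residues) for simulated proteins.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma Log-scale mean / sd
#'   of baseline clone abundance.
#' @param depth_per_sample Total mapped reads per sample.
#' @param nb_dispersion Negative-binomial dispersion phi (0 = Poisson).
#' @param group_sizes Named integer vector of serum group sizes.
#' @param n_bead_controls Number of bead-only mock IP samples.
#' @param signature_proteins_per_group Group-shared reactive antigens per group.
#' @param epitope_fraction Fraction of a signature protein's clones (its
#'   reactive epitopes) enriched in that group's samples.
#' @param fold_change Multiplicative enrichment of reactive clones (>= 1).
#' @param sporadic_rate Poisson rate of private (per-sample) reactive proteins.
#' @param spike_doses Numeric doses for the spike-in samples; empty to disable.
#' @return A `phip_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 200L,
                       protein_len_range = c(50L, 400L),
                       abundance_lognormal_mu = 0,
                       abundance_lognormal_sigma = 1,
                       depth_per_sample = 1e5,
                       nb_dispersion = 0.2,
                       group_sizes = c(oMMP = 12L, MMP = 6L, BP = 3L, mcPV = 3L),
                       n_bead_controls = 36L,
                       signature_proteins_per_group = 5L,
                       epitope_fraction = 0.5,
                       fold_change = 16,
                       sporadic_rate = 1,
                       spike_doses = c(10, 2)) {
  cfg <- list(
    seed = as.integer(seed),
    n_proteins = as.integer(n_proteins),
    protein_len_range = as.integer(protein_len_range),
    abundance_lognormal_mu = abundance_lognormal_mu,
    abundance_lognormal_sigma = abundance_lognormal_sigma,
    depth_per_sample = depth_per_sample,
    nb_dispersion = nb_dispersion,
    group_sizes = group_sizes,
    n_bead_controls = as.integer(n_bead_controls),
    signature_proteins_per_group = as.integer(signature_proteins_per_group),
    epitope_fraction = epitope_fraction,
    fold_change = fold_change,
    sporadic_rate = sporadic_rate,
    spike_doses = spike_doses
  )
  stopifnot(
    cfg$n_proteins > 0, all(cfg$protein_len_range > 0),
    cfg$depth_per_sample > 0, cfg$nb_dispersion >= 0,
    all(cfg$group_sizes >= 0), cfg$n_bead_controls >= 0,
    cfg$epitope_fraction > 0, cfg$epitope_fraction <= 1,
    cfg$fold_change >= 1, cfg$sporadic_rate >= 0
  )
  structure(cfg, class = "phip_sim_config")
}

# run code with a locally seeded RNG, restoring global state afterwards
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a toy proteome
#'
#' Uniform-random amino-acid sequences with lengths drawn uniformly from
#' `protein_len_range`; stands in for a real proteome so the whole pipeline is
#' testable offline.
#'
#' @param config A [sim_config()].
#' @return Tibble with `protein_id`, `gene_symbol`, `sequence`.
#' @export
simulate_proteome <- function(config = sim_config()) {
  with_sim_seed(config$seed, {
    n <- config$n_proteins
    lens <- sample(config$protein_len_range[1]:config$protein_len_range[2],
                   n, replace = TRUE)
    aa <- setdiff(aa_alphabet(), "X")
    tibble::tibble(
      protein_id = sprintf("PROT%04d", seq_len(n)),
      gene_symbol = sprintf("GENE%04d", seq_len(n)),
      sequence = vapply(lens, function(l)
        paste0(sample(aa, l, replace = TRUE), collapse = ""), character(1))
    )
  })
}

# draw one sample column: gamma-mixed NB abundances renormalized to fixed depth
draw_column <- function(weights, depth, phi) {
  g <- if (phi > 0) {
    rgamma(length(weights), shape = 1 / phi, scale = phi) * weights
  } else {
    weights
  }
  if (all(g == 0)) abort("All clone abundances are zero.")
  as.numeric(rmultinom(1, size = depth, prob = g))
}

#' Simulate a full PhIP-seq experiment with known ground truth
#'
#' Generates a clones-by-samples count matrix, sample metadata and a
#' ground-truth table of reactive clones, following the assay layout described
#' in [sim_config()]: bead-only controls draw from baseline abundances; each
#' serum group shares `signature_proteins_per_group` reactive antigens in which
#' an `epitope_fraction` of clones is enriched `fold_change`-fold in every
#' group member; sporadic private reactivities are added per sample; spike-in
#' samples enrich all clones of one target protein, dose-proportionally.
#'
#' @param library A `phip_library` from [build_library()].
#' @param config A [sim_config()].
#' @param spike_target `protein_id` to use for the spike-in samples; defaults
#'   to the library's first protein. Ignored when `spike_doses` is empty.
#' @return A `phip_sim` list with elements `counts` (wide tibble, `clone_id` +
#'   one column per sample; column sums equal `depth_per_sample`), `meta`
#'   (`sample_id`, `group`, `is_control`, `dose`) and `truth` (long tibble
#'   `sample_id`, `protein_id`, `clone_id`, `fold`).
#' @export
simulate_phipseq <- function(library, config = sim_config(), spike_target = NULL) {
  if (!nrow(library)) abort("`library` has no clones.")
  n_samples <- sum(config$group_sizes) + config$n_bead_controls +
    length(config$spike_doses)
  if (n_samples == 0) abort("Configuration yields zero samples.")
  if (length(config$spike_doses)) {
    spike_target <- spike_target %||% library$protein_id[1]
    if (!spike_target %in% library$protein_id) {
      abort(paste0("Unknown spike target protein: ", spike_target))
    }
  }

  clones_by_protein <- split(library$clone_id, library$protein_id)

  with_sim_seed(config$seed, {
    n_clones <- nrow(library)
    lambda <- rlnorm(n_clones, config$abundance_lognormal_mu,
                     config$abundance_lognormal_sigma)
    names(lambda) <- library$clone_id

    groups <- names(config$group_sizes)[config$group_sizes > 0]
    meta <- dplyr::bind_rows(
      tibble::tibble(
        sample_id = sprintf("beads_%02d", seq_len(config$n_bead_controls)),
        group = "beads", is_control = TRUE, dose = NA_real_
      ),
      purrr::map_dfr(groups, function(g) tibble::tibble(
        sample_id = sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]])),
        group = g, is_control = FALSE, dose = NA_real_
      )),
      if (length(config$spike_doses)) tibble::tibble(
        sample_id = sprintf("spike_%02d", seq_along(config$spike_doses)),
        group = "spike", is_control = FALSE, dose = config$spike_doses
      )
    )

    # group-shared signature antigens, disjoint across groups
    protein_ids <- names(clones_by_protein)
    sig_needed <- config$signature_proteins_per_group * length(groups)
    if (sig_needed > length(protein_ids)) {
      abort("Not enough proteins for the requested signature antigens.")
    }
    sig_pool <- setdiff(protein_ids,
                        if (length(config$spike_doses)) spike_target else NULL)
    sig_proteins <- sample(sig_pool, sig_needed)
    sig_by_group <- split(
      sig_proteins,
      rep(groups, each = config$signature_proteins_per_group)
    )
    pick_epitopes <- function(protein_id) {
      cl <- clones_by_protein[[protein_id]]
      k <- max(1L, round(config$epitope_fraction * length(cl)))
      sort(sample(cl, k))
    }
    sig_epitopes <- lapply(
      setNames(sig_proteins, sig_proteins), pick_epitopes
    )

    truth <- list()
    fold_of <- matrix(1, n_clones, nrow(meta),
                      dimnames = list(library$clone_id, meta$sample_id))
    for (i in seq_len(nrow(meta))) {
      s <- meta$sample_id[i]; g <- meta$group[i]
      if (g == "beads") next
      if (g == "spike") {
        cl <- clones_by_protein[[spike_target]]
        fold <- 1 + (config$fold_change - 1) * meta$dose[i] / max(config$spike_doses)
        fold_of[cl, i] <- fold
        if (fold > 1) {
          truth[[length(truth) + 1L]] <- tibble::tibble(
            sample_id = s, protein_id = spike_target, clone_id = cl, fold = fold
          )
        }
        next
      }
      reactive <- sig_by_group[[g]]
      n_priv <- rpois(1, config$sporadic_rate)
      if (n_priv > 0) {
        priv_pool <- setdiff(protein_ids, c(sig_proteins,
                                            if (length(config$spike_doses)) spike_target))
        reactive <- c(reactive, sample(priv_pool, min(n_priv, length(priv_pool))))
      }
      for (p in reactive) {
        cl <- sig_epitopes[[p]] %||% pick_epitopes(p)
        fold_of[cl, i] <- config$fold_change
        if (config$fold_change > 1) {
          truth[[length(truth) + 1L]] <- tibble::tibble(
            sample_id = s, protein_id = p, clone_id = cl, fold = config$fold_change
          )
        }
      }
    }

    counts <- matrix(0, n_clones, nrow(meta),
                     dimnames = list(library$clone_id, meta$sample_id))
    for (i in seq_len(nrow(meta))) {
      counts[, i] <- draw_column(lambda * fold_of[, i],
                                 config$depth_per_sample, config$nb_dispersion)
    }

    structure(
      list(
        counts = dplyr::bind_cols(
          tibble::tibble(clone_id = library$clone_id),
          tibble::as_tibble(counts)
        ),
        meta = meta,
        truth = if (length(truth)) dplyr::bind_rows(truth) else
          tibble::tibble(sample_id = character(), protein_id = character(),
                         clone_id = character(), fold = numeric())
      ),
      class = "phip_sim",
      baseline = lambda,
      config = config,
      spike_target = if (length(config$spike_doses)) spike_target else NULL
    )
  })
}

#' Add spike-in sample columns to a simulated experiment
#'
#' Appends one sample per dose in which every clone of `target_protein` — and
#' only those clones — is enriched, with fold proportional to dose
#' (`1 + (fold_change - 1) * dose / max(doses)`; dose 0 gives fold 1, i.e. a
#' bead-like column). Uses the experiment's stored baseline abundances so the
#' new columns are comparable with its bead controls.
#'
#' @param sim A `phip_sim` from [simulate_phipseq()].
#' @param target_protein `protein_id` present in `library`.
#' @param library The `phip_library` the experiment was simulated from.
#' @param doses Numeric vector of doses (default from the sim's config).
#' @param seed Seed for the new columns (default derived from the config seed).
#' @return A new `phip_sim` with the extra columns, metadata rows and truth.
#' @export
spike_in <- function(sim, target_protein, library,
                     doses = attr(sim, "config")$spike_doses,
                     seed = attr(sim, "config")$seed + 1L) {
  if (!target_protein %in% library$protein_id) {
    abort(paste0("Unknown spike target protein: ", target_protein))
  }
  config <- attr(sim, "config")
  lambda <- attr(sim, "baseline")
  cl <- library$clone_id[library$protein_id == target_protein]
  max_dose <- max(doses, 1e-12)
  with_sim_seed(seed, {
    new_cols <- list()
    meta_new <- sim$meta
    truth_new <- sim$truth
    for (k in seq_along(doses)) {
      fold <- 1 + (config$fold_change - 1) * doses[k] / max_dose
      w <- lambda
      w[cl] <- w[cl] * fold
      s <- sprintf("spikeadd_%02d", k)
      new_cols[[s]] <- draw_column(w, config$depth_per_sample, config$nb_dispersion)
      meta_new <- dplyr::bind_rows(meta_new, tibble::tibble(
        sample_id = s, group = "spike", is_control = FALSE, dose = doses[k]
      ))
      if (fold > 1) {
        truth_new <- dplyr::bind_rows(truth_new, tibble::tibble(
          sample_id = s, protein_id = target_protein, clone_id = cl, fold = fold
        ))
      }
    }
    out <- sim
    out$counts <- dplyr::bind_cols(sim$counts, tibble::as_tibble(new_cols))
    out$meta <- meta_new
    out$truth <- truth_new
    out
  })
}

#' @export
print.phip_sim <- function(x, ...) {
  cat("<phip_sim> ", nrow(x$counts), " clones x ", nrow(x$meta), " samples (",
      sum(x$meta$is_control), " bead controls); ",
      nrow(x$truth), " ground-truth reactive clone-sample pairs\n", sep = "")
  invisible(x)
}
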