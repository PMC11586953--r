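Package: phipkit
Title: Phage Immunoprecipitation Sequencing (PhIP-Seq) Autoantibody Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for PhIP-seq autoantibody profiling:
    design of overlapping-peptide (49-mer, 25-residue overlap) phage display
    tiling libraries from a proteome, simulation of mock-IP and serum
    immunoprecipitation experiments with known ground truth, read mapping and
    clone counting with coverage quality control, per-clone enrichment calling
    against bead-only negative controls with an exact conditional
    negative-binomial test and a leave-one-out control blacklist, Boolean
    protein-level reactivity pooling, Fisher exact group-versus-rest antigen
    comparisons with z-scored proportion matrices, and offline hypergeometric
    over-representation analysis against user-supplied gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
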