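---
title: "Models and methods behind phipkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phipkit)
```

phipkit analyzes Phage Immunoprecipitation Sequencing (PhIP-seq) experiments:
serum antibodies select peptide-displaying phage clones out of a proteome-wide
tiling library, and clone sequencing counts are compared against bead-only
mock immunoprecipitations to call antibody reactivities. This vignette
explains each model in the pipeline, the assumptions behind it, the tunable
parameters, and the design choices made where the methodology was genuinely
open.

## Library design

Proteins are cut into 49-residue peptides overlapping by 25 residues (step
24). Tiling starts at residue 0 and advances by the step; when a protein's
length minus 49 is not a multiple of 24, the tail would be left uncovered, so
a terminal tile is **anchored at `length - 49`**. The terminal tile then
overlaps its predecessor by more than 25 residues (up to 48), which we accept
because it guarantees that every residue of every protein is covered by a
full-length peptide — fixed peptide length matters more for display chemistry
than uniform overlap. Proteins shorter than 49 residues yield one full-length
tile; padding is not modeled because no padding chemistry is defined for such
libraries. Identical peptides arising from different proteins keep distinct,
protein-scoped clone ids (`<protein_id>_<start>`), since all downstream
pooling is per protein.

Reverse translation uses a deterministic one-codon-per-residue table (the
most frequent *E. coli* codon for each amino acid, `ecoli_codon_table()`),
overridable by the user. "Codon optimization" in real library synthesis is
vendor-specific; a deterministic table keeps the library reproducible and
makes translation a strict left inverse, which the tests exploit. Tag flanks
(FLAG upstream, STREP-tag II downstream) are attached verbatim as nucleotide
strings; vector sequence beyond the flanks is not modeled.

## The synthetic experiment generator

`simulate_phipseq()` emulates the statistical structure of the assay, with
defaults set to the targeted study design:

* **Groups**: oMMP 12, non-ocular MMP 6, BP 3, mcPV 3 serum samples; 36
  bead-only controls; two spike-in samples at doses 10 and 2 (interpreted in
  micrograms of spiked antibody).
* **Baseline abundances** are log-normal per clone (meanlog 0, sdlog 1). The
  true clone-abundance distribution of commercial libraries is unpublished;
  log-normal is the standard heavy-tailed assumption and is recorded in the
  configuration.
* **Counts** are drawn by gamma–multinomial sampling: each clone's relative
  abundance is multiplied by a gamma variable with unit mean and variance
  `nb_dispersion` (so counts are marginally negative-binomial with
  `variance = mu + phi * mu^2`), then a multinomial draw allocates exactly
  `depth_per_sample` reads (default 1e5). This reproduces both
  overdispersion and the fixed-depth constraint of pooled sequencing; column
  sums equal the depth exactly.
* **Reactivity**: each group shares `signature_proteins_per_group` (default
  5) signature antigens, disjoint across groups, in which a fixed random
  subset of `epitope_fraction` (default 0.5) of the protein's clones — its
  reactive epitopes — is multiplied by `fold_change` (default 16) in every
  group member. Sporadic private reactivities per sample follow a Poisson
  rate (`sporadic_rate`, default 1). Spike samples enrich **all** clones of
  one target protein with fold `1 + (fold_change - 1) * dose / max(dose)`,
  so dose 0 reduces to a bead-like column and higher dose gives a strictly
  larger fold.
* Identical configurations (including `seed`) give byte-identical output.

What the generator deliberately does **not** emulate: PCR amplification bias,
barcode demultiplexing, non-uniform sequencing error profiles, phage-growth
competition, and cross-reactive epitope similarity between unrelated
proteins. Passing recovery tests on these simulations therefore demonstrates
that the statistics behave as designed under the stated model — not that any
particular wet-lab artifact is handled.

`simulate_reads()` emits per-clone reads with uniform substitution errors.
The default layout starts every read at the template 5' end, as amplicon
libraries are sequenced from a fixed vector primer. A random-offset layout
exists, but note that a random 100-nt read can fall entirely inside the long
shared region between a terminal tile and its neighbour, where discarding it
as ambiguous is the correct mapping outcome — exact count-matrix round trips
are only well-defined for the fixed-start layout.

## Read mapping

`map_reads()` is a seed-and-extend mapper: exact 25-mers of the read are
looked up in a template index (seeds occurring in more than `max_seed_hits`
clones, e.g. the shared tag flanks, are skipped), and each candidate
(clone, diagonal) is scored by ungapped local alignment with +1/−1 scoring —
the best-scoring contiguous segment on the diagonal. With this scoring the
acceptance threshold of 50 reads directly as "at least 50 net matching
positions". Gapped alignment is unnecessary for amplicon reads whose errors
are substitutions. A read is counted to the unique best-scoring clone at or
above the threshold; ties between distinct clones are discarded as ambiguous
(protein-level pooling downstream makes fractional multi-mapping needless),
and everything else is discarded as low-score. The per-sample log conserves
reads across the three outcomes. Reads are mapped against the forward strand
of the single-stranded template. Coverage QC divides mapped reads by the
number of library clones and flags the ≥1× and ≥5× levels.

## Enrichment against bead-only controls

The core inference is clone-level: is this sample's count for this clone
larger than the bead-control counts can explain?

**Normalization.** Size factors are each sample's total divided by the
geometric mean of totals; counts divided by their factor sit on the common
depth. Before exact testing, normalized counts are rounded back to integers
— the conditional test requires exchangeable integer totals, and at
sequencing depths the rounding perturbation is negligible.

**Dispersion.** Counts are modeled NB with `variance = mu + phi * mu^2`.
Per clone, `phi_raw = max(0, (var - mean) / mean^2)` on normalized control
counts (method of moments; 0 is the Poisson limit), then shrunk halfway
(`shrinkage_weight = 0.5`) toward the 10%-trimmed mean of all per-clone
estimates. With 36 controls the moment estimate is informative but noisy;
equal-weight shrinkage stabilizes small-mean clones without the machinery of
full empirical-Bayes tagwise estimation, which is out of scope here.

**Exact conditional test.** Under the null the (depth-equalized) sample
count is NB with size `1/phi` and the sum of `m` controls is NB with size
`m/phi`, sharing the success probability. Conditional on the total `T`, the
sample count follows a negative hypergeometric law that does not involve the
unknown mean:

\[ P(y \mid T) \;=\; \frac{\binom{y + 1/\phi - 1}{y}\,\binom{T - y + m/\phi - 1}{T - y}}{\binom{T + (m+1)/\phi - 1}{T}} . \]

The two-sided p-value sums `P(y' | T)` over all splits with
`P(y' | T) <= P(y | T) * (1 + 1e-7)` — the minimum-likelihood convention,
with the same relative guard band R's `fisher.test` uses against ties lost
to floating point. At `phi = 0` the law is binomial with success probability
`1/(1 + m)`. The binomial-coefficient tables are accumulated as cumulative
sums of `log1p((r - 1)/j)` rather than differences of `lgamma()`, which
stays accurate when `r = m/phi` is enormous (tiny dispersion). The measured
distance between the NB law at `phi = 1e-8` and its binomial limit is
linear in `phi` and about `4e3 * phi` in deep tails, so the limit is attained
to ~1e-6 relative error for small-count cells and to ~1e-4 everywhere; the
tests assert both facts.

**Fold change** is `log2((y + 0.5) / (mean(controls) + 0.5))` on the
normalized scale; the 0.5 pseudocount stabilizes zeros, on which the
literature is silent.

**Hit thresholds** follow the published rule: `log2fc >= 2` (inclusive — "at
least") and `-log10(p) > 4` (strict).

**Control blacklist.** "Enriched in any negative control" is operationalized
as the only self-consistent reading we found: each control is tested
leave-one-out against the remaining controls with the same exact test and
thresholds, and any clone called in any control is blacklisted from
protein-level pooling in every serum sample. A convenient identity makes
this cheap: every leave-one-out test of a clone conditions on the same total
(the sum of all its control counts), so one conditional law serves all 36
tests. The dispersion used is the one estimated from all controls; with 36
controls the leave-one-out perturbation of `phi` is second-order.

## Group analysis

Protein reactivity is the Boolean OR of a protein's non-blacklisted clone
hits — a sample reacting with any epitope counts, which also makes collapse
idempotent. Each disease group is compared against the pooled remaining
groups per protein in a 2×2 table by a two-sided Fisher exact test
implemented by direct hypergeometric enumeration. The two-sided convention
is minimum-likelihood summation, which reproduces published contingency
p-values; the doubling convention is available behind an argument but is not
the default. Significance is `p < 0.05` per protein with **no**
multiple-testing correction, mirroring the published analysis; a BH option
exists and is off by default. Reported percentages truncate toward zero
(8/12 prints as 66), matching the style of published hit tables.

Proportion heatmaps standardize each protein's per-group reactive
proportions to z-scores. The sample (n−1) standard deviation is the default:
it is R's `scale()` convention and the one consistent with rows like
(0.8, 0.2, 0.2, 0.2) mapping to (1.5, −0.5, −0.5, −0.5); the population-sd
variant is available via `sd_type`. Zero-spread rows map to zeros.

## Annotation

`ora()` is a plain hypergeometric upper-tail over-representation test with
BH adjustment. Enrichr-style combined scores depend on service-internal
background statistics and are deliberately not reproduced. The background
universe should be the gene symbols the assay can detect — the tiled
proteome — not the whole genome, and defaults accordingly in the pipeline
context. Symbol matching is case-insensitive with an explicit alias hook,
since symbol drift (e.g. GOLGB1 appearing as COLGB1) is common in antigen
lists. `expression_crossref()` joins antigen genes to a cell-type expression
table and flags expression in a configurable epithelial grouping (corneal,
limbal, conjunctival layers and goblet cells by default); genes absent from
the table are reported as not detected rather than dropped.

## Numerical and testing choices

* Simulation-based checks run at a reduced library (200 proteins of 50–400
  residues, ≈1,600–1,900 clones, depth 1e5 giving control clone means ≈ 60)
  — large enough for stable rates, small enough that the full suite runs in
  about two minutes.
* Null calibration uses a `fold_change = 1` experiment (no true enrichment)
  and checks that `p < 1e-4` events stay at or below twice their nominal
  rate, plus ≥1,000 Fisher comparisons on exchangeable Boolean reactivity
  staying within Monte-Carlo slack of the 5% nominal level.
* Recovery uses the default design with 16-fold enrichment and requires ≥90%
  of planted clone enrichments and ≥90% of signature antigens back.
* All stochastic tests fix their seeds; the generator restores the caller's
  RNG state.

## Known limitations

Linear 49-mer display cannot present conformational epitopes, so canonical
autoantigens recognized conformationally (BP180, desmogleins, integrin β4)
are expected to escape this assay class regardless of the statistics.
The mapper is substitution-oriented; indel-rich platforms would need gapped
extension. The moment/shrinkage dispersion estimator is deliberately simpler
than full empirical-Bayes tagwise machinery and can under-shrink single-
control outliers (the blacklist's leave-one-out construction compensates at
the calling stage). The ORA module tests over-representation only; ranked
(GSEA-style) enrichment is out of scope.
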