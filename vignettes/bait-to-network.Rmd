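---
title: "From bait IPs to risk-gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bait IPs to risk-gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

baitnet implements a complete analysis route for bait-centric interaction
proteomics and its integration with human genetics: immunoprecipitation
mass-spectrometry (IP-MS) quantification tables are turned into per-dataset
interactor calls, the calls are combined into cell-type-specific
protein-protein interaction (PPI) networks, the networks are tested for
gene-set and tissue enrichment, and finally used to prioritize candidate
disease genes inside GWAS risk loci. This vignette explains the statistical
model at each stage, the tunable parameters and their defaults, the
synthetic-data generator that stands in for deposited raw data, and the
design choices made where more than one reasonable convention exists.

## The IP-MS model and the five processing steps

One experiment compares bait IPs (pull-downs of an index protein) against
control IPs, with matched replicates of each. Processing follows five steps:

1. **Log2 transformation and median normalization** per sample
   (`normalize_log2_median()`). Each sample's observed intensities are
   log2-transformed and shifted so the sample median is 0. Centering at 0
   (rather than at a global constant) makes the downstream log2 fold changes
   invariant to the choice of target; the operation is idempotent.
2. **Evidence filtering** (`filter_proteins()`): non-human and
   uncharacterized entries, contaminants (keratins, keratin-associated
   proteins, trypsins — a configurable regex list, since no exhaustive
   catalogue exists), *unresolved isoforms* (two or more accessions for the
   same gene with bitwise-identical intensity vectors; all group members are
   removed because the quantification cannot attribute the signal), and
   proteins supported by fewer than two unique peptides. The surviving set
   is the complement of the union of violations, so rule order is
   irrelevant; the removal report counts a protein under every rule it
   violates.
3. **Gene-symbol mapping**: gene symbols are the join key throughout the
   package; an accession-to-symbol mapping is accepted at the I/O boundary.
4. **Imputation of missing values** (`impute_missing()`): per sample,
   missing cells are drawn from `Normal(mu - 1.8*sigma, (0.3*sigma)^2)`
   where `mu` and `sigma` are the sample's observed mean and SD. This is
   the standard left-censoring model for label-free MS: proteins are mostly
   missing because they sit below the detection limit, so imputed values
   are placed in the left tail (downshift 1.8 SD) with a narrow spread
   (width 0.3 SD). Moments are computed per sample, not pooled.
5. **Replicate log2 fold changes** (`compute_replicate_logfc()`):
   `log2FC[g, i] = bait[g, i] - control[g, i]`, paired by replicate index
   (the IP mixtures are split into matched replicates, so pairing by index
   is the natural design). Unequal replicate counts are an error because the
   pairing would be undefined.

## Interactor calling

`moderated_one_sample_test()` tests whether each protein's mean replicate
log2FC exceeds zero, using empirical-Bayes variance shrinkage: per-protein
sample variances `s2_g` (df `d = R - 1`) are squeezed toward a prior
`s0^2` with prior df `d0`, estimated by moment matching on
`e_g = log(s2_g) - digamma(d/2) + log(d/2)`: solve
`trigamma(d0/2) = var(e) - trigamma(d/2)` (infinite `d0` when the right side
is non-positive) and `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
The moderated t statistic `mean_g / (s_tilde_g / sqrt(R))` is referred to a
t distribution on `d0 + d` df (standard normal when `d0` is infinite). Two
limits anchor the implementation and are tested exactly: `d0 = 0` recovers
the classical one-sample t-test, and homoskedastic rows drive `d0` to
infinity (a z-statistic against the pooled variance). Rows with zero sample
variance are retained — shrinkage defines their statistic — but excluded
from the hyperparameter moments.

P-values are two-sided, with the directional gate applied afterwards:
a protein is called an **interactor** when `log2FC > 0` (strict) and
BH FDR `<= 0.1` (inclusive). Sidedness is configurable. The bait itself is
flagged separately and never reported as its own interactor.

**QC gate** (`qc_dataset()`): a dataset passes when the Pearson correlation
of replicate log2FCs exceeds 0.6 (mean of pairwise correlations when more
than two replicates) *and* the bait is itself called significant. The QC
metrics table also reports detected/significant counts, ribosomal-protein
counts (`RPL`/`RPS` gene-symbol prefixes, a non-specific-binding indicator),
and overlap of the significant set with known bait partners when a
reference edge list is available. Metric distributions across experimental
conditions are compared with two-tailed Wilcoxon rank-sum tests.

## Networks

`build_network()` combines QC-passing datasets: significant in at least one
dataset means interactor; detected in at least one but significant in none
means non-interactor; index proteins are excluded from both lists. An edge
from one index protein to another is kept as an index-index interaction
(it appears in network plots and the social Manhattan table) even though
the prey index gene is excluded from the lists used as enrichment
backgrounds — excluding baits keeps backgrounds free of genes whose presence
is guaranteed by the experimental design rather than by biology.

For index proteins assayed in two cell types, `celltype_partition()` splits
interactors into exclusive, shared, and union sets. The non-interactor
background of a partition is the union of the contributing cell types'
non-interactors minus the union of their interactors. The subtraction uses
the union of interactors — not just the partition's — because a gene
significant in any contributing dataset must never serve as a
non-interactor of a network containing that dataset; for the exclusive
partitions this reduces to the single cell type's own background. The
source defines backgrounds per network but not per partition, so this is
the package's own (minimal consistent) extension.

## Enrichment statistics

All overlap tests are one-tailed hypergeometric upper tails including the
observed count (`hypergeometric_test()`), with four population
constructions:

* **global**: the population is every gene annotated in at least one set of
  the collection (or a supplied universe); successes are the network's
  interactors; the sample is the gene set.
* **global, non-interactor companion**: the same test run for the
  non-interactor list, as a specificity control.
* **conditional**: the population is further restricted to the network's
  interactors plus non-interactors — an expression-matched background that
  asks whether a set is enriched *given what the assay detects in that cell
  type*.
* **dataset overlap**: for two IPs, the population is the genes detected in
  both.

Bonferroni adjustment always uses the number of tests actually run in the
family, computed from the collection, never hard-coded.

## Genetics

`annotate_genes_to_snps()` assigns a SNP to a gene when its position falls
within the gene body extended by a ±50 kb flanking window (strand ignored:
the window is symmetric); variants in the MHC region, treated as the closed
interval chr6:28,500,000–33,400,000, are excluded globally because its LD
structure inflates gene-based statistics.

`gene_based_test()` implements the SNP-wise mean model: the gene statistic
is the mean association chi-square of the gene's SNPs, and its null
accounts for LD — `m*T` is distributed as a weighted sum of 1-df
chi-squares with weights equal to the eigenvalues of the SNP correlation
matrix from the reference panel. Tail probabilities come from Imhof's
characteristic-function inversion (numerical integration with a cascade of
tolerances), with a Satterthwaite scaled-chi-square fallback if integration
fails; equal eigenvalues (one SNP, or an identity correlation) short-circuit
to the exact scaled chi-square, so a single-SNP gene returns the SNP
p-value exactly. Eigenvalues are floored at zero (and the MVN simulator
floors at 1e-8) for stability under near-perfect LD. This is a principled
reimplementation of the published approach, not a bit-compatible clone of
the external tool: the covariate set is reduced to log gene length and log
SNP count, and gene-gene correlation of Z-scores is ignored in the analytic
competitive test (a permutation mode is offered instead); calibration is
demonstrated by simulation in the test suite.

`competitive_geneset_test()` regresses gene Z-scores (probit of the
gene-based p, clamped to `[1e-300, 1 - 1e-16]` so Z stays finite) on set
membership plus covariates over a background — the whole scan (global) or
interactors plus non-interactors (conditional) — reporting the one-tailed
p-value for a positive membership effect. Permutation mode re-draws
membership labels within the background (`B` permutations of the
residualized design), giving an empirical null that is robust to
distributional misspecification.

`ld_clump_locus()` defines a risk locus as all panel variants with genotype
`r^2 > 0.6` to the index variant (squared Pearson correlation of unphased
dosages — the phasing-free convention of standard clumping tools), padded
by 50 kb on each side and floored at position 1. Overlapping loci are *not*
merged: each index variant keeps its own locus, and genes are deduplicated
only in the unique-gene summary. `prioritize_locus_genes()` intersects the
protein-coding genes overlapping each locus with the index genes and
network interactors; `social_manhattan_table()` lays the prioritized genes
out by genomic position against the `-log10` p-value of each locus's
tagging SNP, with protein-interaction edges drawn among the plotted genes.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes; it emulates study *structure*,
not any particular deposited dataset.

* **IP-MS** (`simulate_ipms_dataset()`): per-protein log2 baselines
  `Normal(25, 2)` (a typical MS1 magnitude, which exercises median
  normalization); spiked interactors and the bait shifted by `effect_size`
  in bait samples; per-cell noise `noise_sd/sqrt(2)` so that a replicate
  log2FC has SD exactly `noise_sd` — the package defines `noise_sd` on the
  fold-change scale because that is the scale on which calling power is
  specified and measured. Missingness is logistic in the underlying log2
  intensity with slope `mnar_steepness` (default 2 per log2 unit — MS
  detection limits are sharp), with the midpoint calibrated by root-finding
  so the expected overall missing fraction equals `missing_rate` (default
  0.2, typical for single-shot label-free IP-MS). Contaminant rows carry
  keratin-style symbols; low-evidence rows carry a single unique peptide.
  An optional `background_logfc_sd` (default 0) adds reproducible
  per-protein non-specific background enrichment with mean zero. Real IP-MS
  replicates correlate strongly because background binders deviate
  reproducibly from controls; with only 50 spiked proteins in 5,000 and no
  background structure, replicate correlation is near zero by construction
  and the correlation QC gate would reject everything. The pipeline demo
  therefore sets `background_logfc_sd = 1`; calibration and spike-recovery
  tests keep it at 0 so that non-spiked proteins are exactly null.
* **Reference panel** (`simulate_reference_panel()`): haplotypes are latent
  Gaussian AR(1) processes (adjacent correlation `rho`) thresholded at the
  allele-frequency quantile; diploid dosage is the sum of two independent
  haplotypes. Thresholding attenuates the latent correlation (a latent 0.9
  yields dosage correlation near 0.6), which the tests account for. This is
  deliberately not coalescent-accurate; it provides cheap, controllable LD.
* **GWAS summary statistics** (`simulate_gwas_summary()`): z-scores drawn
  per chromosome from a multivariate normal with covariance equal to the
  panel's SNP correlation matrix, mean lifted by `effect_size` inside
  causal genes.
* **Annotation, gene sets, reference edges**: sorted non-overlapping gene
  intervals on synthetic chromosomes; uniformly sampled sets with optional
  exact forced overlaps; reference PPI edge lists with an exact forced edge
  overlap against a given network.

Every generator is deterministic given its seed, and a single top-level
pipeline seed derives per-component substreams (`derive_seed()`) so partial
reruns reproduce exactly.

**What passing tests do and do not show.** The generator matches the
analysis assumptions by construction (normal noise, logistic left-censoring,
AR(1) LD, normal gene effects). Passing calibration on it demonstrates
internal correctness — the implemented statistics control their error rates
under their own model — not robustness to real-data pathologies such as
peptide-level interference, batch structure, shared contaminant bursts, or
long-range LD, none of which the generator emulates.

## Numerical choices and operating characteristics

* Imhof integration tolerance cascade `1e-8 → 1e-6 → default`, then
  Satterthwaite; gene p clamped to `[1e-300, 1]`.
* Trigamma inversion by Newton iteration; `var(e) - trigamma(d/2) <= 0`
  maps to infinite prior df.
* The BH step is `stats::p.adjust`; ties and input order cannot change the
  result.
* Degenerate inputs: all-identical rank-sum samples give p = 1 with a
  warning; constant covariates are dropped from the competitive design with
  a warning; a constant dosage vector is an error for `r^2`.
* Measured at the reference conditions (in the acceptance suite): spike
  recovery at 2 log2 units on complete data has recall ≈ 0.93 and precision
  ≈ 0.92; with 20% MNAR missingness and downshifted imputation the same
  effect size drops to recall ≈ 0.2, because rows mixing observed and
  imputed cells inflate the variance prior and shrink the prior df. This
  power cost of imputation is a real property of the procedure — interactor
  effects in practice are typically larger than 2 log2 units — and is why
  the spike-recovery benchmark isolates calling power on complete data
  while null calibration is verified under the full missingness model.
* Problem sizes in the test suite (5,000-protein simulations, hundreds of
  null replicates, 10-SNP genes, 1,000–2,000-gene calibrations) were chosen
  as the smallest sizes at which the Monte-Carlo checks are stable.

## Limitations

Accession-to-symbol mapping is taken as input rather than resolved against
a genome annotation service; the gene-based test is not bit-compatible with
the external tool it reimplements; the competitive test's analytic mode
ignores gene-gene LD correlation (use permutation mode when loci overlap
heavily); haplotype simulation is AR(1), so long-range LD and recombination
hotspots are out of scope; and the pipeline's orchestration covers the
synthetic route end-to-end while real datasets enter through the readers
(`read_quant_table()`, `read_gwas_summary()`, `read_panel()`, `read_gmt()`,
`read_edge_list()`, `read_gene_annotation()`) and the same stage functions.
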