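# Fixture builders and independent oracles shared across the test files.
# All fixtures are built in code; nothing is read from disk unless a test
# writes it first.

# A small quant table with explicit numbers (2 bait + 2 control replicates).
make_toy_quant <- function(intensities = NULL, n_proteins = 3,
                           bait_gene = "BAITG", genes = NULL,
                           unique_peptides = NULL) {
  if (is.null(intensities)) {
    intensities <- matrix(2^(5 + seq_len(n_proteins * 4) %% 7),
                          nrow = n_proteins)
  }
  n <- nrow(intensities)
  if (is.null(genes)) genes <- c(bait_gene, sprintf("G%03d", seq_len(n - 1)))
  proteins <- data.frame(
    protein_id = sprintf("ACC%03d", seq_len(n)),
    gene_symbol = genes,
    unique_peptides = unique_peptides %||% rep(5L, n),
    species_flag = "human",
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("b1", "b2", "c1", "c2"),
    role = c("bait", "bait", "control", "control"),
    replicate = c(1L, 2L, 1L, 2L),
    dataset_id = "toy", cell_type = "EC",
    ip_method = "endogenous", facility = "lab",
    stringsAsFactors = FALSE)
  quant_table(proteins, intensities, samples, bait_gene = bait_gene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal interactor_stats object for tests of downstream set logic.
make_stats <- function(genes, sig_genes, bait = "BAITX",
                       dataset_id = "dsX", cell_type = "EC") {
  n <- length(genes)
  d <- data.frame(
    protein_id = sprintf("P%03d", seq_len(n)),
    gene_symbol = genes,
    logFC = ifelse(genes %in% sig_genes, 2, 0),
    t = 0, pvalue = ifelse(genes %in% sig_genes, 1e-4, 0.8),
    s2 = 1, df_total = 10, stringsAsFactors = FALSE)
  d$fdr <- ifelse(genes %in% sig_genes, 0.01, 0.9)
  d$is_bait <- genes == bait
  d$significant <- genes %in% sig_genes & !d$is_bait
  structure(d, class = c("interactor_stats", "data.frame"),
            bait_gene = bait, dataset_id = dataset_id, cell_type = cell_type,
            thresholds = c(lfc_min = 0, fdr_max = 0.1),
            replicate_logfc = matrix(rnorm(2 * n), n, 2))
}

# Brute-force upper-tail hypergeometric by full enumeration of all C(N, n)
# draws; independent of phyper.
enumerate_hyper_tail <- function(N, k, n, x) {
  if (n == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= k)  # successes are items 1..k
  mean(overlaps >= x)
}

# Independent coding of the moderated one-sample test (same moment-matching
# estimator, different code path: explicit loops + uniroot trigamma solve).
brute_force_moderated <- function(m) {
  R <- ncol(m)
  d <- R - 1
  means <- numeric(nrow(m))
  s2 <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    means[i] <- sum(m[i, ]) / R
    s2[i] <- sum((m[i, ] - means[i])^2) / d
  }
  e <- log(s2[s2 > 0]) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    half_d0 <- stats::uniroot(function(y) trigamma(y) - evar,
                              c(1e-8, 1e8), tol = 1e-14)$root
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
    st <- (d0 * s02 + d * s2) / (d0 + d)
    tt <- means / sqrt(st / R)
    p <- 2 * stats::pt(-abs(tt), df = d0 + d)
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
    tt <- means / sqrt(s02 / R)
    p <- 2 * stats::pnorm(-abs(tt))
  }
  list(t = tt, p = p, d0 = d0, s02 = s02)
}

# Direct per-pair r2 scan, used as the LD-clumping oracle.
brute_force_locus_members <- function(index_variant, panel, r2_min) {
  idx <- match(index_variant, panel$map$snp)
  x <- panel$dosage[, idx]
  members <- character(0)
  for (j in seq_len(ncol(panel$dosage))) {
    if (panel$map$chrom[j] != panel$map$chrom[idx]) next
    if (j == idx) { members <- c(members, panel$map$snp[j]); next }
    y <- panel$dosage[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    if (stats::cor(x[ok], y[ok])^2 > r2_min) {
      members <- c(members, panel$map$snp[j])
    }
  }
  members
}

# Aligned panel + annotation: one gene per consecutive block of SNPs.
make_gene_panel <- function(n_genes = 20, snps_per_gene = 5, n_samples = 200,
                            rho = 0.5, bp_spacing = 1000, seed = 1) {
  n_snps <- n_genes * snps_per_gene
  panel <- simulate_reference_panel(panel_sim_config(
    n_samples = n_samples, n_snps = n_snps, rho = rho,
    bp_spacing = bp_spacing, chrom = "1", seed = seed))
  starts <- (seq_len(n_genes) - 1) * snps_per_gene * bp_spacing + 1
  annotation <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(n_genes)),
    chrom = "1",
    start = starts,
    end = starts + snps_per_gene * bp_spacing - 1,
    strand = "+", biotype = "protein_coding",
    stringsAsFactors = FALSE)
  list(panel = panel, annotation = annotation)
}
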