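# Generators: determinism, generating-parameter recovery, MNAR structure,
# LD structure, annotation geometry, and forced-overlap constructions.

test_that("ipms generator is deterministic and validates its configuration", {
  cfg <- ipms_sim_config(n_proteins = 300, seed = 11)
  a <- simulate_ipms_dataset(cfg)
  b <- simulate_ipms_dataset(cfg)
  expect_identical(a, b)
  c2 <- simulate_ipms_dataset(ipms_sim_config(n_proteins = 300, seed = 12))
  expect_false(identical(a$table$intensities, c2$table$intensities))

  expect_error(ipms_sim_config(n_proteins = 50, n_true_interactors = 30,
                               n_contaminants = 15, n_low_peptide = 10),
               "leave room")
  expect_error(ipms_sim_config(missing_rate = 1), "missing_rate")
  expect_error(ipms_sim_config(n_bait_reps = 0), "n_bait_reps")
})

test_that("null configuration gives a complete pure-null matrix", {
  cfg <- ipms_sim_config(n_proteins = 5000, n_true_interactors = 0,
                         effect_size = 0, missing_rate = 0, seed = 21)
  sim <- simulate_ipms_dataset(cfg)
  x <- sim$table$intensities
  expect_false(anyNA(x))
  lfc <- log2(x[, 1:2]) - log2(x[, 3:4])
  mu <- mean(rowMeans(lfc))
  se <- sd(rowMeans(lfc)) / sqrt(nrow(lfc))
  expect_lt(abs(mu), 3 * se + 1e-12)
})

test_that("spiked rows recover the generating enrichment", {
  cfg <- ipms_sim_config(n_proteins = 2000, n_true_interactors = 50,
                         effect_size = 2, noise_sd = 0.5, missing_rate = 0,
                         seed = 31)
  sim <- simulate_ipms_dataset(cfg)
  spiked <- sim$truth$protein_id[sim$truth$is_interactor]
  x <- log2(sim$table$intensities)
  lfc <- rowMeans(x[spiked, 1:2] - x[spiked, 3:4])
  # per-protein mean logFC has SD noise_sd/sqrt(2); 50 spiked rows
  se <- 0.5 / sqrt(2) / sqrt(length(spiked))
  expect_lt(abs(mean(lfc) - 2), 3 * se)
})

test_that("missingness is intensity-dependent and hits the target rate", {
  cfg <- ipms_sim_config(n_proteins = 4000, missing_rate = 0.25,
                         mnar_steepness = 2, seed = 41)
  sim <- simulate_ipms_dataset(cfg)
  x <- sim$table$intensities
  expect_lt(abs(mean(is.na(x)) - 0.25), 0.05)
  # rows with lower observed intensity lose more cells
  row_mean <- rowMeans(log2(x), na.rm = TRUE)
  row_miss <- rowMeans(is.na(x))
  ok <- !is.na(row_mean) & row_miss < 1
  expect_lt(cor(row_mean[ok], row_miss[ok], method = "spearman"), -0.3)
})

test_that("contaminant and low-evidence rows carry their marks", {
  cfg <- ipms_sim_config(n_proteins = 500, n_contaminants = 8,
                         n_low_peptide = 6, seed = 51)
  sim <- simulate_ipms_dataset(cfg)
  p <- sim$table$proteins
  expect_equal(sum(grepl("^KRT", p$gene_symbol)), 8)
  expect_equal(sum(p$unique_peptides == 1), 6)
})

test_that("reference panel has valid dosages, spacing, and determinism", {
  cfg <- panel_sim_config(n_samples = 100, n_snps = 50, rho = 0.5, seed = 61)
  pan <- simulate_reference_panel(cfg)
  expect_true(all(pan$dosage %in% 0:2))
  expect_equal(diff(pan$map$pos), rep(cfg$bp_spacing, 49))
  expect_identical(pan, simulate_reference_panel(cfg))
  expect_error(panel_sim_config(n_samples = 1), "n_samples")
  expect_error(panel_sim_config(rho = 1), "rho")
  expect_error(panel_sim_config(maf_range = c(0.6, 0.7)), "maf_range")
})

test_that("rho = 0 panels show the independence r2 baseline", {
  pan <- simulate_reference_panel(panel_sim_config(
    n_samples = 100, n_snps = 1001, rho = 0, seed = 71))
  r2 <- vapply(seq_len(1000), function(j) {
    suppressWarnings(cor(pan$dosage[, j], pan$dosage[, j + 1])^2)
  }, numeric(1))
  # E[r^2] under independence is ~ 1/(n_samples - 1)
  expect_lt(abs(mean(r2, na.rm = TRUE) - 1 / 99), 0.004)
})

test_that("LD decays monotonically with distance in AR(1) panels", {
  pan <- simulate_reference_panel(panel_sim_config(
    n_samples = 2000, n_snps = 60, rho = 0.9, seed = 81))
  mean_abs_cor_at_lag <- function(lag) {
    mean(vapply(seq_len(60 - lag), function(j) {
      abs(cor(pan$dosage[, j], pan$dosage[, j + lag]))
    }, numeric(1)))
  }
  c1 <- mean_abs_cor_at_lag(1)
  c3 <- mean_abs_cor_at_lag(3)
  c6 <- mean_abs_cor_at_lag(6)
  # thresholding a latent Gaussian attenuates rho = 0.9 to ~0.6 on dosages
  expect_gt(c1, 0.5)
  expect_gt(c1, c3)
  expect_gt(c3, c6)
})

test_that("single-SNP panels are valid and r2 on a constant errors", {
  pan <- simulate_reference_panel(panel_sim_config(
    n_samples = 50, n_snps = 1, seed = 91))
  expect_equal(ncol(pan$dosage), 1L)
  expect_error(compute_r2(rep(1, 50), pan$dosage[, 1]), "constant")
})

test_that("null GWAS z-scores are marginally uniform in p", {
  ps <- unlist(lapply(1:5, function(k) {
    pan <- simulate_reference_panel(panel_sim_config(
      n_samples = 120, n_snps = 2000, rho = 0.4, seed = 100 + k))
    simulate_gwas_summary(pan, effect_size = 0, seed = 200 + k)$p
  }))
  expect_gt(length(ps), 9999)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("GWAS simulation is deterministic and lifts causal-gene SNPs", {
  gp <- make_gene_panel(n_genes = 10, snps_per_gene = 4, n_samples = 150,
                        rho = 0.3, seed = 7)
  g1 <- simulate_gwas_summary(gp$panel, causal_gene_ids = "GENE00003",
                              gene_annotation = gp$annotation,
                              effect_size = 4, seed = 5)
  g2 <- simulate_gwas_summary(gp$panel, causal_gene_ids = "GENE00003",
                              gene_annotation = gp$annotation,
                              effect_size = 4, seed = 5)
  expect_identical(g1, g2)
  inside <- gp$panel$map$pos >= gp$annotation$start[3] &
    gp$panel$map$pos <= gp$annotation$end[3]
  expect_gt(mean(g1$z[inside]), mean(g1$z[!inside]) + 1)
  expect_error(simulate_gwas_summary(gp$panel, causal_gene_ids = "NOPE",
                                     gene_annotation = gp$annotation,
                                     effect_size = 1), "absent")
})

test_that("a strongly causal gene wins the gene-based scan in most replicates", {
  gp <- make_gene_panel(n_genes = 15, snps_per_gene = 5, n_samples = 150,
                        rho = 0.5, seed = 9)
  wins <- vapply(1:60, function(k) {
    gw <- simulate_gwas_summary(gp$panel, causal_gene_ids = "GENE00008",
                                gene_annotation = gp$annotation,
                                effect_size = 3, seed = 1000 + k)
    res <- gene_based_scan(gw, gp$panel, gp$annotation, window = 0, mhc = NULL)
    res$gene_id[which.min(res$p)] == "GENE00008"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("gene annotation intervals are sorted and non-overlapping", {
  out <- simulate_gene_annotation_and_sets(100, n_sets = 5, n_chrom = 2,
                                           seed = 13)
  ann <- out$annotation
  expect_true(all(ann$start <= ann$end))
  for (chr in unique(ann$chrom)) {
    a <- ann[ann$chrom == chr, ]
    expect_true(all(diff(a$start) > 0))
    expect_true(all(a$start[-1] > a$end[-nrow(a)]))
  }
  expect_true(all(lengths(out$sets) >= 5))
})

test_that("forced set overlap is exact by construction", {
  target <- sprintf("GENE%05d", 1:30)
  out <- simulate_gene_annotation_and_sets(
    100, n_sets = 5, set_size_range = c(20, 20),
    enrichment_spec = list(list(set = 2, target = target, overlap = 12)),
    seed = 17)
  expect_equal(length(intersect(out$sets[[2]], target)), 12)
  expect_error(simulate_gene_annotation_and_sets(
    100, n_sets = 2, set_size_range = c(10, 10),
    enrichment_spec = list(list(set = 1, target = target, overlap = 11)),
    seed = 1), "exceeds set size")
})

test_that("reference-interaction overlap with a network is exact", {
  stats <- make_stats(c("BAITX", "A", "B", "C", "D", "E", "F"),
                      sig_genes = c("A", "B", "C", "D", "E"))
  net <- build_network(list(stats))
  expect_equal(nrow(net$edges), 5)
  ref <- simulate_reference_interactions(
    gene_ids = sprintf("G%03d", 1:40), n_edges = 10, network = net,
    n_overlap = 3, seed = 19)
  expect_equal(nrow(ref), 10)
  expect_false(any(duplicated(paste(ref$gene_a, ref$gene_b))))
  annotated <- annotate_known_edges(net, list(inref = ref))
  expect_equal(sum(annotated$edges$known_inref), 3)
  expect_equal(sum(!annotated$edges$known_inref), 2)
  expect_error(simulate_reference_interactions(
    letters, n_edges = 10, network = net, n_overlap = 6, seed = 1),
    "exceeds")
})
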