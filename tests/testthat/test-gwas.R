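# SNP-to-gene annotation, LD arithmetic, the quadratic-form gene test, the
# competitive gene-set test, and locus prioritization.

test_that("SNP-to-gene windows and the MHC exclusion behave exactly", {
  ann <- data.frame(gene_id = c("G1", "G2"), chrom = c("1", "6"),
                    start = c(100000, 30000000), end = c(110000, 30010000),
                    stringsAsFactors = FALSE)
  gw <- data.frame(
    snp = c("s_in", "s_edge", "s_out", "s_mhc"),
    chrom = c("1", "1", "1", "6"),
    pos = c(60000, 50000, 49999, 30000000),
    p = c(0.5, 0.5, 0.5, 0.5), stringsAsFactors = FALSE)
  res <- annotate_genes_to_snps(ann, gw, window = 50000)
  expect_setequal(res$gene_snps$G1, c("s_in", "s_edge"))
  expect_equal(res$n_mhc_excluded, 1L)   # chr6:30M sits inside the MHC
  expect_null(res$gene_snps$G2)

  # disabled exclusion assigns the chr6 SNP to its gene
  res2 <- annotate_genes_to_snps(ann, gw, window = 50000, mhc = NULL)
  expect_equal(res2$gene_snps$G2, "s_mhc")

  # assignment totals are invariant to gene order
  res3 <- annotate_genes_to_snps(ann[2:1, ], gw, window = 50000)
  expect_equal(sum(lengths(res3$gene_snps)), sum(lengths(res$gene_snps)))
})

test_that("r2 matches hand calculations and rejects degenerate input", {
  expect_equal(compute_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(compute_r2(c(0, 1, 2, 1), c(2, 1, 0, 1)), 1)  # r = -1
  expect_equal(compute_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(compute_r2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_error(compute_r2(1:3, 1:4), "equal length")
})

test_that("a lone index variant yields the pad-only locus", {
  pan <- simulate_reference_panel(panel_sim_config(
    n_samples = 200, n_snps = 21, rho = 0, bp_spacing = 100000, seed = 401))
  idx <- pan$map$snp[11]  # at 1,100,000
  loc <- ld_clump_locus(idx, pan, r2_min = 0.6, pad = 50000)
  expect_equal(loc$members, idx)
  expect_equal(loc$start, pan$map$pos[11] - 50000)
  expect_equal(loc$end, pan$map$pos[11] + 50000)
  expect_equal(loc$end - loc$start + 1, 100001)
})

test_that("a tight LD block is clumped together with exact padding", {
  # equal allele frequencies so thresholding attenuates the latent
  # correlation as little as possible; spacing keeps the pad above position 1
  pan <- simulate_reference_panel(panel_sim_config(
    n_samples = 1000, n_snps = 5, rho = 0.995, maf_range = c(0.3, 0.3),
    bp_spacing = 60000, seed = 402))
  loc <- ld_clump_locus(pan$map$snp[3], pan)
  expect_setequal(loc$members, pan$map$snp)
  expect_equal(loc$start, min(pan$map$pos) - 50000)
  expect_equal(loc$end, max(pan$map$pos) + 50000)
})

test_that("clump membership equals the brute-force r2 scan", {
  for (seed in c(403, 404, 405)) {
    pan <- simulate_reference_panel(panel_sim_config(
      n_samples = 150, n_snps = 40, rho = 0.8, seed = seed))
    idx <- pan$map$snp[20]
    loc <- ld_clump_locus(idx, pan, r2_min = 0.6)
    expect_setequal(loc$members,
                    brute_force_locus_members(idx, pan, 0.6))
  }
  pan <- simulate_reference_panel(panel_sim_config(
    n_samples = 100, n_snps = 5, seed = 406))
  expect_error(ld_clump_locus("nope", pan), "absent")
})

test_that("gene-based test: single-SNP identity and chi-square closed form", {
  for (p1 in c(0.73, 0.01, 1)) {
    expect_identical(gene_based_test(p1), p1)
  }
  # R = I, z = (1.96, 0): q = 3.8416, upper chi2_2 tail = exp(-q/2)
  p <- c(2 * pnorm(-1.96), 1)
  got <- gene_based_test(p, diag(2))
  expect_equal(got, exp(-qchisq(p[1], 1, lower.tail = FALSE) / 2),
               tolerance = 1e-10)
  expect_equal(got, 0.1465, tolerance = 1e-3)
  expect_error(gene_based_test(numeric(0)), "no SNPs")
  expect_error(gene_based_test(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("Imhof tail matches an empirical quadratic-form null", {
  rho <- 0.8; m <- 10
  R <- matrix(rho, m, m); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  set.seed(407)
  L <- ev$vectors %*% diag(sqrt(ev$values))
  draws <- matrix(rnorm(1e5 * m), 1e5, m) %*% t(L)
  qnull <- rowSums(draws^2)
  for (targ in c(0.2, 0.05, 0.01)) {
    q <- quantile(qnull, 1 - targ)
    # analytic tail at the empirical quantile, via the package path
    z <- sqrt(q / m)  # build p-vector with equal z so sum z^2 = q
    pv <- pchisq(rep(q / m, m), df = 1, lower.tail = FALSE)
    analytic <- gene_based_test(pv, R)
    mc_se <- sqrt(targ * (1 - targ) / 1e5)
    expect_lt(abs(analytic - targ), 4 * mc_se + 0.002)
  }
})

test_that("Satterthwaite fallback is a sane approximation to Imhof", {
  lam <- c(3, 1, 0.5, 0.2)
  q <- 8
  a <- baitnet:::imhof_upper_tail(q, lam)
  b <- baitnet:::satterthwaite_upper_tail(q, lam)
  expect_lt(abs(a - b), 0.02)
})

test_that("gene-based p-values are uniform under the null", {
  m <- 10
  R <- matrix(0.5, m, m); diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(ev$values))
  set.seed(408)
  n_genes <- 500
  z <- matrix(rnorm(n_genes * m), n_genes, m) %*% t(L)
  pv <- apply(z, 1, function(zi) {
    gene_based_test(2 * pnorm(-abs(zi)), R)
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("competitive test handles degenerate and consistency cases", {
  d <- data.frame(gene_id = sprintf("G%02d", 1:20), z = 1,
                  log_length = log(1000 + 1:20), log_nsnps = log(2 + 1:20))
  res <- competitive_geneset_test(d, members = d$gene_id[1:5])
  expect_equal(res$beta, 0)
  expect_equal(res$p, 0.5)

  set.seed(409)
  d$z <- rnorm(20)
  full <- competitive_geneset_test(d, members = d$gene_id[1:5])
  cond <- competitive_geneset_test(d, members = d$gene_id[1:5],
                                   background = d$gene_id)
  expect_equal(full$p, cond$p)

  d$log_length <- 1  # constant covariate is dropped, not fatal
  expect_warning(res2 <- competitive_geneset_test(d, members = d$gene_id[1:5]),
                 "constant covariate")
  expect_true(is.finite(res2$p))
  expect_error(competitive_geneset_test(d, members = d$gene_id[1:19][1:1]),
               ">= 2 member")
})

test_that("permutation mode agrees with the analytic tail on plain data", {
  set.seed(410)
  d <- data.frame(gene_id = sprintf("G%03d", 1:200),
                  z = rnorm(200), log_length = rnorm(200, 10),
                  log_nsnps = rnorm(200, 2))
  d$z[1:30] <- d$z[1:30] + 0.8
  res <- competitive_geneset_test(d, members = d$gene_id[1:30],
                                  mode = "permutation", B = 2000, seed = 5)
  expect_lt(abs(res$p - res$p_analytic), 0.02)
  expect_lt(res$p, 0.05)
})

test_that("injected interactor signal is detected end to end", {
  gp <- make_gene_panel(n_genes = 30, snps_per_gene = 4, n_samples = 150,
                        rho = 0.4, seed = 411)
  members <- gp$annotation$gene_id[seq(1, 30, by = 3)]
  gw <- simulate_gwas_summary(gp$panel, causal_gene_ids = members,
                              gene_annotation = gp$annotation,
                              effect_size = 2, seed = 412)
  scan <- gene_based_scan(gw, gp$panel, gp$annotation, window = 0, mhc = NULL)
  res <- competitive_geneset_test(scan, members = members,
                                  covariates = character(0))
  expect_lt(res$p, 0.05)
})

test_that("locus genes intersect the networks into a prioritized table", {
  ann <- data.frame(
    gene_id = c("G1", "G2", "G3", "BX"),
    chrom = "1", start = c(100, 5000, 90000, 20000),
    end = c(1000, 9000, 95000, 21000),
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "protein_coding"),
    stringsAsFactors = FALSE)
  net <- build_network(list(make_stats(c("BX", "G2", "Q1"), c("G2"),
                                       bait = "BX")))
  loc <- structure(list(index_variant = "rs1", index_pos = 6000, chrom = "1",
                        start = 1, end = 95000, members = "rs1"),
                   class = "locus")
  pri <- prioritize_locus_genes(list(loc), ann, list(EC = net))
  tab <- pri$table
  expect_false("G3" %in% tab$gene_id)   # non-coding genes are dropped
  expect_true(tab$prioritized[tab$gene_id == "G2"])
  expect_equal(tab$linked_baits[tab$gene_id == "G2"], "BX")
  expect_true(tab$is_index[tab$gene_id == "BX"])
  expect_false(tab$prioritized[tab$gene_id == "G1"])
  expect_equal(pri$summary$n_prioritized[pri$summary$network == "combined"], 2)

  # a locus with no interactor overlap prioritizes nothing
  far <- structure(list(index_variant = "rs2", index_pos = 999000,
                        chrom = "2", start = 990000, end = 999999,
                        members = "rs2"), class = "locus")
  pri2 <- prioritize_locus_genes(list(far), ann, list(EC = net))
  expect_equal(nrow(pri2$table), 0)
})

test_that("prioritized genes deduplicate across loci and cell types", {
  ann <- data.frame(gene_id = c("G1", "G2"), chrom = "1",
                    start = c(100, 200000), end = c(1000, 201000),
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  net_ec <- build_network(list(make_stats(c("BX", "G1", "G2"),
                                          c("G1", "G2"), bait = "BX")), "EC")
  net_smc <- build_network(list(make_stats(c("BY", "G1", "G2"),
                                           c("G1", "G2"), bait = "BY")), "SMC")
  mkloc <- function(id, s, e) structure(
    list(index_variant = id, index_pos = s, chrom = "1", start = s, end = e,
         members = id), class = "locus")
  loci <- list(mkloc("rs1", 1, 2000), mkloc("rs2", 500, 1500),
               mkloc("rs3", 199000, 202000))
  pri <- prioritize_locus_genes(loci, ann,
                                list(EC = net_ec, SMC = net_smc))
  expect_equal(sum(pri$table$gene_id == "G1"), 2)  # loci are not merged
  expect_equal(pri$summary$n_prioritized[pri$summary$network == "combined"],
               2)
})

test_that("the social Manhattan table is plot-ready and edge-consistent", {
  ann <- data.frame(gene_id = c("BX", "G2"), chrom = "1",
                    start = c(100, 5000), end = c(1000, 9000),
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  net <- build_network(list(make_stats(c("BX", "G2"), c("G2"), bait = "BX")))
  loc <- structure(list(index_variant = "rs1", index_pos = 500, chrom = "1",
                        start = 1, end = 10000, members = "rs1"),
                   class = "locus")
  gw <- data.frame(snp = "rs1", chrom = "1", pos = 500, p = 1e-8)
  pri <- prioritize_locus_genes(list(loc), ann, list(EC = net))
  smt <- social_manhattan_table(pri, gw, list(EC = net))
  expect_setequal(smt$nodes$gene_id, c("BX", "G2"))
  expect_equal(smt$nodes$minus_log10_p, c(8, 8))
  expect_equal(nrow(smt$edges), 1)
  # every plotted edge exists in a source network
  key <- paste(smt$edges$bait, smt$edges$prey)
  expect_true(all(key %in% paste(net$edges$bait, net$edges$prey)))

  # a missing tagging SNP drops the gene with a warning
  gw2 <- data.frame(snp = "other", chrom = "1", pos = 1, p = 0.5)
  expect_warning(smt2 <- social_manhattan_table(pri, gw2, list(EC = net)),
                 "without a tagging SNP")
  expect_equal(nrow(smt2$nodes), 0)
})

test_that("single index gene with no interactors plots one point, no edges", {
  ann <- data.frame(gene_id = "BX", chrom = "1", start = 100, end = 1000,
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  net <- build_network(list(make_stats(c("BX", "Q"), character(0),
                                       bait = "BX")))
  loc <- structure(list(index_variant = "rs1", index_pos = 500, chrom = "1",
                        start = 1, end = 2000, members = "rs1"),
                   class = "locus")
  gw <- data.frame(snp = "rs1", chrom = "1", pos = 500, p = 1e-6)
  pri <- prioritize_locus_genes(list(loc), ann, list(EC = net))
  smt <- social_manhattan_table(pri, gw, list(EC = net))
  expect_equal(nrow(smt$nodes), 1)
  expect_equal(smt$nodes$role, "index")
  expect_equal(nrow(smt$edges), 0)
})
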