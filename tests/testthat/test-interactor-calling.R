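# Moderated one-sample test (limits, oracle, limma cross-check), BH FDR,
# significance calls, QC gate, and dataset comparisons.

test_that("forcing d0 = 0 reproduces the classical one-sample t-test", {
  set.seed(101)
  m <- matrix(rnorm(150), 50, 3)
  st <- moderated_one_sample_test(m, d0_override = 0)
  classical <- t(apply(m, 1, function(r) {
    ht <- t.test(r)
    c(ht$statistic, ht$p.value)
  }))
  expect_equal(st$t, unname(classical[, 1]), tolerance = 1e-10)
  expect_equal(st$pvalue, unname(classical[, 2]), tolerance = 1e-10)
})

test_that("identical row variances drive the prior df to infinity (z branch)", {
  set.seed(102)
  means <- rnorm(30)
  # every row is mean + c(-1, 1): identical sample variance 2
  m <- t(vapply(means, function(mu) mu + c(-1, 1), numeric(2)))
  st <- moderated_one_sample_test(m)
  expect_identical(attr(st, "d0"), Inf)
  s0 <- sqrt(attr(st, "s02"))
  expect_equal(st$t, means / (s0 / sqrt(2)), tolerance = 1e-10)
  expect_equal(st$pvalue, 2 * pnorm(-abs(st$t)), tolerance = 1e-12)
})

test_that("moderated test matches an independently coded oracle to 1e-6", {
  for (seed in c(7, 8)) {
    set.seed(seed)
    m <- matrix(rnorm(40, sd = rep(runif(20, 0.5, 2), 2)), 20, 2)
    st <- moderated_one_sample_test(m)
    oracle <- brute_force_moderated(m)
    expect_equal(attr(st, "d0"), oracle$d0, tolerance = 1e-6)
    expect_equal(attr(st, "s02"), oracle$s02, tolerance = 1e-6)
    expect_equal(st$t, oracle$t, tolerance = 1e-6)
    expect_equal(st$pvalue, oracle$p, tolerance = 1e-6)
  }
})

test_that("moderated test agrees with limma's empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  set.seed(103)
  m <- matrix(rnorm(600, sd = rep(runif(200, 0.3, 3), 3)), 200, 3)
  st <- moderated_one_sample_test(m)
  fit <- limma::eBayes(limma::lmFit(m, design = matrix(1, 3, 1)))
  expect_equal(attr(st, "d0"), unname(fit$df.prior), tolerance = 1e-6)
  expect_equal(attr(st, "s02"), unname(fit$s2.prior), tolerance = 1e-6)
  expect_equal(st$t, unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(st$pvalue, unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("zero-variance rows are retained and get a shrinkage statistic", {
  set.seed(104)
  m <- rbind(matrix(rnorm(58), 29, 2), c(1.5, 1.5))
  st <- moderated_one_sample_test(m)
  expect_equal(nrow(st), 30)
  expect_true(is.finite(st$t[30]))
  expect_gt(st$t[30], 0)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  p <- c(0.4, 0.01, 0.2, 0.01, 0.9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
})

test_that("interactor calls use strict logFC > 0 and inclusive FDR <= 0.1", {
  mk <- function(lfc, p) {
    structure(data.frame(protein_id = "P1", gene_symbol = "G1", logFC = lfc,
                         t = 1, pvalue = p, s2 = 1, df_total = 5),
              class = c("interactor_stats", "data.frame"),
              bait_gene = "BAIT1", dataset_id = "ds", cell_type = "EC")
  }
  expect_true(call_interactors(mk(0.5, 0.09))$significant)
  expect_false(call_interactors(mk(-1.0, 0.001))$significant)
  expect_false(call_interactors(mk(0.5, 0.11))$significant)
  expect_false(call_interactors(mk(0, 0.01))$significant)   # strict on logFC
  expect_true(call_interactors(mk(0.5, 0.1))$significant)   # inclusive on FDR
})

test_that("the bait is flagged and never returned as its own interactor", {
  sim <- simulate_ipms_dataset(ipms_sim_config(n_proteins = 400,
                                               effect_size = 3,
                                               missing_rate = 0, seed = 6))
  st <- analyze_ipms_dataset(sim$table)
  expect_equal(sum(st$is_bait), 1L)
  expect_false(sim$table$bait_gene %in% significant_genes(st))
  expect_true(st$significant[st$is_bait])  # enriched, but reported separately
})

test_that("QC passes on correlated replicates with a significant bait", {
  cfg <- ipms_sim_config(n_proteins = 1500, background_logfc_sd = 1,
                         effect_size = 3, seed = 31)
  st <- analyze_ipms_dataset(simulate_ipms_dataset(cfg)$table, seed = 32)
  qc <- qc_dataset(st)
  expect_true(qc$pass)
  expect_gt(qc$metrics$replicate_correlation, 0.6)
  expect_lte(qc$metrics$bait_fdr, 0.1)
})

test_that("QC fails on low correlation or a missing bait", {
  st <- make_stats(c("BAITX", "A", "B", "C"), c("A"))
  attr(st, "replicate_logfc") <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  qc <- qc_dataset(st)
  expect_false(qc$pass)
  expect_true("low_replicate_correlation" %in% qc$reasons)

  st2 <- make_stats(c("A", "B", "C"), c("A"), bait = "ABSENT")
  qc2 <- qc_dataset(st2)
  expect_false(qc2$pass)
  expect_true("bait_not_detected" %in% qc2$reasons)
})

test_that("duplicated replicate columns give correlation exactly 1", {
  st <- make_stats(c("BAITX", "A", "B", "C", "D"), c("A"))
  v <- c(0.2, 1.5, -0.3, 0.7, 2.0)
  attr(st, "replicate_logfc") <- cbind(v, v)
  qc <- qc_dataset(st)
  expect_equal(qc$metrics$replicate_correlation, 1)
})

test_that("QC counts ribosomal proteins and known-partner overlap", {
  st <- make_stats(c("BAITX", "RPL3", "RPS6", "A", "B"), c("RPL3", "A"))
  qc <- qc_dataset(st, known_partners = c("A", "B", "ZZZ"))
  expect_equal(qc$metrics$n_ribosomal_detected, 2)
  expect_equal(qc$metrics$n_ribosomal_significant, 1)
  expect_equal(qc$metrics$n_known_detected, 2)
  expect_equal(qc$metrics$n_known_significant, 1)
  # N=4 detected (bait excluded), k=2 known, n=2 significant, x=1
  expect_equal(qc$metrics$known_overlap_p,
               hypergeometric_test(4, 2, 2, 1))
})

test_that("dataset overlap uses the detected-in-both population", {
  genes <- sprintf("G%02d", 1:10)
  a <- make_stats(c("BAITX", genes), sig_genes = genes[1:5])
  b <- make_stats(c("BAITY", genes), sig_genes = genes[1:5], bait = "BAITY",
                  dataset_id = "dsY")
  res <- compare_datasets_overlap(a, b)
  expect_equal(res[c("N", "k", "n", "x")], list(N = 10, k = 5, n = 5, x = 5))
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  b2 <- make_stats(c("BAITY", genes), sig_genes = genes[6:10], bait = "BAITY")
  res2 <- compare_datasets_overlap(a, b2)
  expect_equal(res2$x, 0)
  expect_equal(res2$p, 1)
})

test_that("QC metric comparisons delegate to the rank-sum test", {
  metrics <- data.frame(n_significant = c(10, 12, 30, 31, 33),
                        replicate_correlation = c(.7, .72, .8, .81, .82))
  cond <- c("endo", "endo", "flag", "flag", "flag")
  res <- compare_qc_across_conditions(metrics, cond)
  expect_equal(nrow(res), 2)
  ref <- wilcox.test(c(10, 12), c(30, 31, 33))$p.value
  expect_equal(res$p[res$metric == "n_significant"], ref)
  expect_error(compare_qc_across_conditions(metrics, rep("x", 5)),
               "two levels")
})
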