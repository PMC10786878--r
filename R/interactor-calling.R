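# Per-dataset interactor statistics: empirical-Bayes moderated one-sample
# t-test on replicate log2FCs, BH FDR, significance calls at logFC > 0 and
# FDR <= 0.1, and the QC gate (replicate correlation > 0.6 plus a significant
# bait).

#' Empirical-Bayes moderated one-sample t-test
#'
#' Tests, per protein, whether the mean replicate log2FC differs from zero,
#' shrinking per-protein variances toward a prior estimated across all
#' proteins (Smyth's moment-matching on the log sample variances). With
#' `R` replicates and residual df `d = R - 1`:
#' posterior variance `s2_tilde = (d0*s0^2 + d*s^2) / (d0 + d)`, moderated
#' `t = mean / (s_tilde / sqrt(R))` on `d0 + d` df (standard normal when the
#' prior df are infinite). The hyperparameters solve
#' `trigamma(d0/2) = var(e) - trigamma(d/2)` and
#' `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))` where
#' `e_g = log(s2_g) - digamma(d/2) + log(d/2)`; zero-variance rows are
#' retained (their statistic is defined by shrinkage) and excluded from the
#' hyperparameter moments.
#'
#' @param logfc A [compute_replicate_logfc()] result, or a bare numeric
#'   matrix of per-replicate log2FCs.
#' @param d0_override Force the prior df (0 recovers the classical one-sample
#'   t-test; `Inf` forces the normal-reference limit).
#' @param sided `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return An `interactor_stats` data.frame with columns `gene_symbol`,
#'   `protein_id`, `logFC` (mean), `t`, `pvalue`, `s2`, `df_total`;
#'   hyperparameters `d0`, `s02`, the replicate logFC matrix, bait and
#'   dataset id are carried as attributes.
#' @export
moderated_one_sample_test <- function(logfc, d0_override = NULL,
                                      sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  if (inherits(logfc, "logfc_matrix")) {
    m <- logfc$logfc
    proteins <- logfc$proteins
    bait <- logfc$bait_gene
    dataset_id <- logfc$dataset_id
    cell_type <- logfc$cell_type
  } else {
    m <- as.matrix(logfc)
    proteins <- data.frame(protein_id = rownames(m) %||%
                             sprintf("P%05d", seq_len(nrow(m))),
                           gene_symbol = rownames(m) %||%
                             sprintf("P%05d", seq_len(nrow(m))),
                           stringsAsFactors = FALSE)
    bait <- NA_character_
    dataset_id <- "dataset1"
    cell_type <- NA_character_
  }
  R <- ncol(m)
  if (R < 2) stopf("need >= 2 replicates per protein")
  if (nrow(m) < 10 && is.null(d0_override)) {
    stopf("need >= 10 proteins to estimate shrinkage hyperparameters")
  }
  d <- R - 1
  mean_g <- rowMeans(m)
  s2 <- apply(m, 1, stats::var)

  pos <- s2 > 0
  if (!any(pos) && is.null(d0_override)) {
    stopf("all rows have zero variance; hyperparameters undefined")
  }
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  if (is.null(d0_override)) {
    evar <- if (length(e) > 1) stats::var(e) - trigamma(d / 2) else 0
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(mean(e))
    }
  } else {
    d0 <- d0_override
    s02 <- if (length(e)) exp(mean(e) + if (is.finite(d0) && d0 > 0)
      digamma(d0 / 2) - log(d0 / 2) else 0) else NA_real_
  }

  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_tilde <- s2
    df_total <- d
  } else {
    s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  tstat <- mean_g / (sqrt(s2_tilde) / sqrt(R))
  pt_upper <- if (is.infinite(df_total)) {
    stats::pnorm(tstat, lower.tail = FALSE)
  } else {
    stats::pt(tstat, df = df_total, lower.tail = FALSE)
  }
  p <- switch(sided,
              two.sided = 2 * pmin(pt_upper, 1 - pt_upper),
              greater = pt_upper,
              less = 1 - pt_upper)
  out <- data.frame(
    protein_id = proteins$protein_id,
    gene_symbol = proteins$gene_symbol,
    logFC = mean_g, t = tstat, pvalue = p, s2 = s2,
    df_total = df_total, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out,
            class = c("interactor_stats", "data.frame"),
            d0 = d0, s02 = s02, n_reps = R, sided = sided,
            replicate_logfc = m, bait_gene = bait, dataset_id = dataset_id,
            cell_type = cell_type)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) min(1, p_(j) * m / j)`, stable
#' under ties and invariant to input order. Validates the inputs and
#' delegates the arithmetic to [stats::p.adjust()].
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must be numeric in [0, 1] with no NAs")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call significant interactors
#'
#' A protein is called an interactor when its mean log2FC exceeds `lfc_min`
#' (strict) and its BH FDR is at most `fdr_max` (inclusive) — higher
#' abundance in the bait IPs than the controls. The bait protein itself is
#' flagged but never returned as its own interactor.
#'
#' @param stats An `interactor_stats` object.
#' @param lfc_min log2FC threshold (strict; default 0).
#' @param fdr_max FDR threshold (inclusive; default 0.1).
#' @return `stats` with added columns `fdr`, `significant`, `is_bait`.
#' @export
call_interactors <- function(stats, lfc_min = 0, fdr_max = 0.1) {
  stopifnot(inherits(stats, "interactor_stats"))
  stats$fdr <- benjamini_hochberg(stats$pvalue)
  bait <- attr(stats, "bait_gene")
  stats$is_bait <- !is.na(bait) & stats$gene_symbol == bait
  stats$significant <- stats$logFC > lfc_min & stats$fdr <= fdr_max
  attr(stats, "thresholds") <- c(lfc_min = lfc_min, fdr_max = fdr_max)
  stats
}

#' Significant interactor genes of a dataset
#' @param stats A [call_interactors()] result.
#' @return Character vector of significant gene symbols, bait excluded.
#' @export
significant_genes <- function(stats) {
  unique(stats$gene_symbol[stats$significant & !stats$is_bait])
}

#' All detected genes of a dataset
#' @param stats An `interactor_stats` object.
#' @return Character vector of detected gene symbols.
#' @export
detected_genes <- function(stats) unique(stats$gene_symbol)

#' QC gate for one IP-MS dataset
#'
#' A dataset passes when the replicate log2FC Pearson correlation (mean of
#' pairwise correlations if more than two replicates) exceeds `corr_min` and
#' the bait protein itself is called significant. Also reports the standard
#' QC metrics: detected / significant protein counts, ribosomal-protein
#' counts (RPL-/RPS- gene-symbol prefixes), and — when a reference edge list
#' for the bait is supplied — the overlap of significant proteins with known
#' bait partners, with a one-tailed hypergeometric enrichment p against the
#' detected background.
#'
#' @param stats A [call_interactors()] result.
#' @param corr_min Replicate-correlation threshold (strict; default 0.6).
#' @param known_partners Optional character vector of known partner genes of
#'   the bait.
#' @return List with `pass`, `reasons`, and `metrics` (one-row data.frame).
#' @export
qc_dataset <- function(stats, corr_min = 0.6, known_partners = NULL) {
  stopifnot(inherits(stats, "interactor_stats"))
  if (is.null(stats$significant)) stopf("run call_interactors() first")
  m <- attr(stats, "replicate_logfc")
  if (is.null(m) || ncol(m) < 2) stopf("need >= 2 replicate logFC columns")
  cors <- stats::cor(m)
  rep_cor <- mean(cors[upper.tri(cors)])
  bait <- attr(stats, "bait_gene")
  reasons <- character(0)
  bait_rows <- which(stats$is_bait)
  if (is.na(bait) || !length(bait_rows)) {
    bait_sig <- FALSE
    bait_lfc <- NA_real_
    bait_fdr <- NA_real_
    reasons <- c(reasons, "bait_not_detected")
  } else {
    thr <- attr(stats, "thresholds")
    bait_lfc <- stats$logFC[bait_rows[1]]
    bait_fdr <- stats$fdr[bait_rows[1]]
    bait_sig <- bait_lfc > thr[["lfc_min"]] & bait_fdr <= thr[["fdr_max"]]
    if (!bait_sig) reasons <- c(reasons, "bait_not_significant")
  }
  if (!(rep_cor > corr_min)) reasons <- c(reasons, "low_replicate_correlation")

  ribo <- grepl("^RP[LS]", stats$gene_symbol, ignore.case = TRUE)
  sig <- stats$significant & !stats$is_bait
  metrics <- data.frame(
    dataset_id = attr(stats, "dataset_id"),
    bait_gene = bait,
    replicate_correlation = rep_cor,
    n_detected = nrow(stats),
    n_significant = sum(sig),
    n_ribosomal_detected = sum(ribo),
    n_ribosomal_significant = sum(ribo & sig),
    bait_logFC = bait_lfc, bait_fdr = bait_fdr,
    stringsAsFactors = FALSE)
  if (!is.null(known_partners)) {
    detected <- setdiff(detected_genes(stats), bait)
    known_det <- intersect(known_partners, detected)
    sig_genes <- significant_genes(stats)
    x <- length(intersect(sig_genes, known_det))
    metrics$n_known_detected <- length(known_det)
    metrics$n_known_significant <- x
    metrics$known_overlap_p <- if (length(known_det)) {
      hypergeometric_test(N = length(detected), k = length(known_det),
                          n = length(sig_genes), x = x)
    } else NA_real_
  }
  list(pass = length(reasons) == 0, reasons = reasons, metrics = metrics)
}

#' Interactor overlap between two datasets
#'
#' The population `N` is the genes detected in both datasets; successes are
#' the significant interactors of each dataset within `N`; the one-tailed
#' hypergeometric upper tail gives the overlap significance.
#'
#' @param stats_a,stats_b [call_interactors()] results.
#' @return List with `N`, `k`, `n`, `x`, `p`, and the overlapping genes.
#' @export
compare_datasets_overlap <- function(stats_a, stats_b) {
  det_a <- detected_genes(stats_a)
  det_b <- detected_genes(stats_b)
  N <- intersect(det_a, det_b)
  if (!length(N)) stopf("no genes detected in both datasets")
  k <- intersect(significant_genes(stats_a), N)
  n <- intersect(significant_genes(stats_b), N)
  x <- intersect(k, n)
  p <- hypergeometric_test(N = length(N), k = length(k), n = length(n),
                           x = length(x))
  list(N = length(N), k = length(k), n = length(n), x = length(x), p = p,
       overlap_genes = sort(x))
}

#' Compare QC metrics across experimental conditions
#'
#' Two-tailed Wilcoxon rank-sum test per metric, asking whether its
#' distribution differs between datasets generated under two conditions
#' (e.g. IP method, MS facility, or cell type).
#'
#' @param metrics data.frame of per-dataset QC metrics (as rbind-ed from
#'   [qc_dataset()]).
#' @param condition Factor/character vector (length `nrow(metrics)`) with
#'   exactly two levels.
#' @param which_metrics Metric columns to test (default: all numeric).
#' @return data.frame with columns `metric`, `p`.
#' @export
compare_qc_across_conditions <- function(metrics, condition,
                                         which_metrics = NULL) {
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) != 2) stopf("'condition' must have exactly two levels")
  if (any(table(condition) < 1)) stopf("each condition group needs >= 1 value")
  if (is.null(which_metrics)) {
    which_metrics <- names(metrics)[vapply(metrics, is.numeric, TRUE)]
  }
  res <- lapply(which_metrics, function(mc) {
    a <- metrics[[mc]][condition == lv[1]]
    b <- metrics[[mc]][condition == lv[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stopf("empty group for metric '%s'", mc)
    data.frame(metric = mc, p = wilcoxon_rank_sum(a, b)$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' One-shot analysis of a raw quantification table
#'
#' Convenience wrapper chaining the five processing steps and the moderated
#' test: normalize, filter, impute, per-replicate log2FC, moderated
#' one-sample t-test, BH FDR and significance calls.
#'
#' @param table A raw [quant_table()].
#' @param impute_width,impute_shift Imputation parameters (see
#'   [impute_missing()]).
#' @param lfc_min,fdr_max Significance thresholds (see [call_interactors()]).
#' @param seed Seed for the imputation draws.
#' @param contaminant_patterns Passed to [filter_proteins()].
#' @return A [call_interactors()] result with the filter report attached as
#'   attribute `"filter_report"`.
#' @export
analyze_ipms_dataset <- function(table, impute_width = 0.3,
                                 impute_shift = 1.8, lfc_min = 0,
                                 fdr_max = 0.1, seed = 1L,
                                 contaminant_patterns = default_contaminant_patterns()) {
  norm <- normalize_log2_median(table)
  filt <- filter_proteins(norm, contaminant_patterns = contaminant_patterns)
  imp <- impute_missing(filt$table, width = impute_width, shift = impute_shift,
                        seed = seed)
  lfc <- compute_replicate_logfc(imp)
  stats <- moderated_one_sample_test(lfc)
  stats <- call_interactors(stats, lfc_min = lfc_min, fdr_max = fdr_max)
  attr(stats, "filter_report") <- filt$report
  stats
}
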