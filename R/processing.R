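# The five-step route from a raw quantification report to per-replicate
# log2 fold changes: (1) log2 + per-sample median normalization, (2) evidence
# and contaminant filtering, (3) gene-symbol mapping (carried on the table),
# (4) downshifted-normal imputation of missing values, (5) paired
# bait-vs-control replicate log2FC.

#' Log2-transform and median-normalize each sample
#'
#' Observed intensities in each sample are log2-transformed and shifted so the
#' sample median equals 0; missing cells stay missing. The operation is
#' idempotent: re-applying it to a normalized table only re-centres (a no-op).
#'
#' @param table A [quant_table()] with positive intensities where observed.
#' @return The normalized [quant_table()] (log2 scale, `normalized = TRUE`),
#'   with per-sample shifts in attribute `"norm_shifts"`.
#' @export
normalize_log2_median <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  x <- table$intensities
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2)) {
    stopf("sample(s) with < 2 observed values: %s",
          paste(colnames(x)[n_obs < 2], collapse = ", "))
  }
  if (!table$log_scale) {
    if (any(x <= 0, na.rm = TRUE)) stopf("intensities must be positive where observed")
    x <- log2(x)
  }
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  x <- sweep(x, 2, med)
  out <- table
  out$intensities <- x
  out$log_scale <- TRUE
  out$normalized <- TRUE
  attr(out, "norm_shifts") <- med
  out
}

default_contaminant_patterns <- function() {
  c(keratin = "^KRT[0-9]", keratin_associated = "^KRTAP",
    trypsin = "^TRY(P|[0-9])|TRYPSIN")
}

#' Filter proteins on evidence and contamination rules
#'
#' Removes (i) non-human and uncharacterized proteins, (ii) contaminants
#' matching the configurable pattern list (keratins, keratin-associated
#' proteins and trypsins by default), (iii) unresolved isoforms — groups of
#' two or more accessions mapping to the same gene whose intensity vectors
#' are identical across all samples (all group members removed) — and
#' (iv) proteins supported by fewer than two unique peptides. The surviving
#' set is the complement of the union of violations, so it does not depend
#' on rule order.
#'
#' @param table A [quant_table()].
#' @param contaminant_patterns Named character vector of regular expressions
#'   matched (case-insensitively) against gene symbols and protein ids.
#' @param min_unique_peptides Minimum unique-peptide support (default 2).
#' @return List with `table` (filtered) and `report` (data.frame of per-reason
#'   removal counts; a protein failing several rules is counted under each).
#' @export
filter_proteins <- function(table,
                            contaminant_patterns = default_contaminant_patterns(),
                            min_unique_peptides = 2) {
  stopifnot(inherits(table, "quant_table"))
  p <- table$proteins
  x <- table$intensities

  non_human <- !is.na(p$species_flag) & p$species_flag != "human"
  uncharacterized <- is.na(p$gene_symbol) | p$gene_symbol == "" |
    (!is.na(p$species_flag) & p$species_flag == "uncharacterized")
  contaminant <- rep(FALSE, nrow(p))
  for (pat in contaminant_patterns) {
    contaminant <- contaminant |
      grepl(pat, p$gene_symbol, ignore.case = TRUE) |
      grepl(pat, p$protein_id, ignore.case = TRUE)
  }
  low_peptide <- !is.na(p$unique_peptides) &
    p$unique_peptides < min_unique_peptides

  # unresolved isoforms: same gene, bitwise-identical intensity vectors
  unresolved <- rep(FALSE, nrow(p))
  key <- apply(x, 1, function(r) paste(r, collapse = "|"))
  grp <- paste(p$gene_symbol, key, sep = "\r")
  counts <- table(grp)
  multi <- names(counts)[counts >= 2]
  unresolved[grp %in% multi & !is.na(p$gene_symbol) & p$gene_symbol != ""] <- TRUE

  drop <- non_human | uncharacterized | contaminant | unresolved | low_peptide
  report <- data.frame(
    reason = c("non_human", "uncharacterized", "contaminant",
               "unresolved_isoform", "low_peptide", "total_removed"),
    n = c(sum(non_human), sum(uncharacterized), sum(contaminant),
          sum(unresolved), sum(low_peptide), sum(drop)),
    stringsAsFactors = FALSE)
  if (all(drop)) warnf("all proteins removed by filters")

  out <- table
  out$proteins <- p[!drop, , drop = FALSE]
  out$intensities <- x[!drop, , drop = FALSE]
  rownames(out$proteins) <- NULL
  list(table = out, report = report)
}

#' Impute missing intensities from a downshifted normal
#'
#' Per sample, missing cells are replaced by draws from
#' `Normal(mu_s - shift * sigma_s, (width * sigma_s)^2)` where `mu_s` and
#' `sigma_s` are that sample's observed mean and SD — the standard
#' left-censoring model for proteins below the detection limit. Observed
#' values are untouched.
#'
#' @param table A normalized [quant_table()] (log2 scale).
#' @param width Imputation width as a fraction of the observed SD (default
#'   0.3).
#' @param shift Downshift in observed-SD units (default 1.8).
#' @param seed Integer seed; imputation is deterministic given it.
#' @return The imputed [quant_table()] (`imputed = TRUE`), with the imputed
#'   mask in attribute `"imputed_mask"`.
#' @export
impute_missing <- function(table, width = 0.3, shift = 1.8, seed = 1L) {
  stopifnot(inherits(table, "quant_table"))
  if (!table$normalized) stopf("impute_missing expects a normalized log2 table")
  x <- table$intensities
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stopf("sample(s) with all values missing: %s",
          paste(colnames(x)[all_missing], collapse = ", "))
  }
  mask <- is.na(x)
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      nmiss <- sum(mask[, j])
      if (nmiss == 0) next
      obs <- x[!mask[, j], j]
      mu <- mean(obs)
      sigma <- stats::sd(obs)
      x[mask[, j], j] <- stats::rnorm(nmiss, mean = mu - shift * sigma,
                                      sd = width * sigma)
    }
  })
  out <- table
  out$intensities <- x
  out$imputed <- TRUE
  attr(out, "imputed_mask") <- mask
  attr(out, "imputation") <- list(width = width, shift = shift, seed = seed)
  out
}

#' Per-replicate bait-vs-control log2 fold changes
#'
#' `log2FC[g, i] = bait log2 intensity[g, i] - control log2 intensity[g, i]`,
#' paired by replicate index. Requires an imputed (complete) table and equal
#' bait and control replicate counts.
#'
#' @param table An imputed [quant_table()].
#' @return A `logfc_matrix` object: `logfc` (proteins x replicates),
#'   `proteins`, `bait_gene`, `dataset_id`.
#' @export
compute_replicate_logfc <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (anyNA(table$intensities)) {
    stopf("table still has missing values; run impute_missing() first")
  }
  s <- table$samples
  bait <- s[s$role == "bait", , drop = FALSE]
  ctrl <- s[s$role == "control", , drop = FALSE]
  if (nrow(bait) != nrow(ctrl)) {
    stopf("unequal bait (%d) and control (%d) replicate counts: pairing undefined",
          nrow(bait), nrow(ctrl))
  }
  bait <- bait[order(bait$replicate), , drop = FALSE]
  ctrl <- ctrl[order(ctrl$replicate), , drop = FALSE]
  if (!all(bait$replicate == ctrl$replicate)) {
    stopf("bait and control replicate indices do not match")
  }
  lfc <- table$intensities[, bait$sample_id, drop = FALSE] -
    table$intensities[, ctrl$sample_id, drop = FALSE]
  colnames(lfc) <- sprintf("rep%d", bait$replicate)
  structure(list(
    logfc = lfc,
    proteins = table$proteins,
    bait_gene = table$bait_gene,
    dataset_id = s$dataset_id[1] %||% "dataset1",
    cell_type = s$cell_type[1] %||% NA_character_),
    class = "logfc_matrix")
}

#' @export
print.logfc_matrix <- function(x, ...) {
  cat(sprintf("logfc_matrix: %d proteins x %d replicate log2FCs (bait %s, dataset %s)\n",
              nrow(x$logfc), ncol(x$logfc), x$bait_gene, x$dataset_id))
  invisible(x)
}
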