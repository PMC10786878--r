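#' Construct a protein quantification table
#'
#' The central container for one IP-MS experiment: a protein x sample
#' intensity matrix plus protein evidence metadata and sample roles. Bait
#' (index-protein) IP samples are compared against control IP samples;
#' replicate indices pair them.
#'
#' @param proteins data.frame with columns `protein_id`, `gene_symbol`,
#'   `unique_peptides`, `species_flag` (one of `"human"`, `"non-human"`,
#'   `"uncharacterized"`).
#' @param intensities Numeric matrix (proteins x samples), non-negative where
#'   observed, `NA` for missing. Raw scale unless `log_scale = TRUE`.
#' @param samples data.frame with columns `sample_id`, `role`
#'   (`"bait"`/`"control"`), `replicate` (1..R), and optional `dataset_id`,
#'   `cell_type`, `ip_method`, `facility`.
#' @param bait_gene Gene symbol of the index protein used as bait.
#' @param log_scale Are intensities already log2-transformed?
#' @param normalized Have samples been median-centred (implies `log_scale`)?
#' @param imputed Have missing values been imputed?
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(proteins, intensities, samples, bait_gene = NA_character_,
                        log_scale = FALSE, normalized = FALSE, imputed = FALSE) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  intensities <- as.matrix(intensities)
  need_p <- c("protein_id", "gene_symbol", "unique_peptides", "species_flag")
  miss <- setdiff(need_p, names(proteins))
  if (length(miss)) stopf("proteins table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  need_s <- c("sample_id", "role", "replicate")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stopf("samples table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(proteins) != nrow(intensities) ||
      nrow(samples) != ncol(intensities)) {
    stopf("intensity matrix dimensions (%d x %d) do not match %d proteins / %d samples",
          nrow(intensities), ncol(intensities), nrow(proteins), nrow(samples))
  }
  dup <- proteins$protein_id[duplicated(proteins$protein_id)]
  if (length(dup)) stopf("duplicate protein id(s): %s",
                         paste(unique(dup), collapse = ", "))
  if (!all(samples$role %in% c("bait", "control"))) {
    stopf("sample roles must be 'bait' or 'control'")
  }
  bait_reps <- sort(samples$replicate[samples$role == "bait"])
  ctrl_reps <- sort(samples$replicate[samples$role == "control"])
  if (!length(bait_reps) || !length(ctrl_reps)) {
    stopf("both bait and control samples are required")
  }
  if (!log_scale && any(intensities < 0, na.rm = TRUE)) {
    stopf("raw intensities must be non-negative")
  }
  rownames(intensities) <- proteins$protein_id
  colnames(intensities) <- samples$sample_id
  structure(
    list(proteins = proteins, intensities = intensities, samples = samples,
         bait_gene = bait_gene, log_scale = log_scale,
         normalized = normalized, imputed = imputed),
    class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  nb <- sum(x$samples$role == "bait")
  nc <- sum(x$samples$role == "control")
  cat(sprintf("quant_table: %d proteins, %d bait + %d control samples\n",
              nrow(x$proteins), nb, nc))
  cat(sprintf("  bait gene: %s | scale: %s%s%s | missing: %.1f%%\n",
              x$bait_gene,
              if (x$log_scale) "log2" else "raw",
              if (x$normalized) ", median-normalized" else "",
              if (x$imputed) ", imputed" else "",
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensities)
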