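# Readers/writers for the external formats the pipeline touches.
# All tables are tab-delimited text; coordinates are 1-based inclusive
# internally, with BED-style 0-based half-open input converted at the
# boundary.

# MS quantification reports commonly encode non-detection as 0 or a blank;
# all of "", NA, NaN and 0 map to missing on ingestion.
missingify <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  x[!is.finite(x) | x == 0] <- NA_real_
  x
}

#' Read a protein quantification table
#'
#' @param path Tab-delimited file: one row per protein, columns `protein_id`,
#'   `gene_symbol`, `unique_peptides`, `species_flag`, then one column per
#'   sample.
#' @param metadata_spec data.frame mapping sample columns to roles: columns
#'   `sample_id` (matching file column names), `role` (`bait`/`control`),
#'   `replicate`, plus optional `dataset_id`, `cell_type`, `ip_method`,
#'   `facility`.
#' @param bait_gene Gene symbol of the bait (index) protein.
#' @return A [quant_table()]. Blank, `NA`, `NaN` and `0` intensity cells are
#'   recorded as missing.
#' @export
read_quant_table <- function(path, metadata_spec, bait_gene = NA_character_) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  metadata_spec <- as.data.frame(metadata_spec, stringsAsFactors = FALSE)
  miss <- setdiff(metadata_spec$sample_id, names(raw))
  if (length(miss)) stopf("sample column(s) absent from file: %s",
                          paste(miss, collapse = ", "))
  dup <- raw$protein_id[duplicated(raw$protein_id)]
  if (length(dup)) stopf("duplicate protein id(s): %s",
                         paste(unique(dup), collapse = ", "))
  prot_cols <- intersect(c("protein_id", "gene_symbol", "unique_peptides",
                           "species_flag"), names(raw))
  if (!all(c("protein_id") %in% prot_cols)) stopf("missing 'protein_id' column")
  proteins <- raw[prot_cols]
  if (is.null(proteins$gene_symbol)) proteins$gene_symbol <- NA_character_
  if (is.null(proteins$unique_peptides)) proteins$unique_peptides <- NA_integer_
  if (is.null(proteins$species_flag)) proteins$species_flag <- "human"
  intens <- vapply(metadata_spec$sample_id, function(s) missingify(raw[[s]]),
                   numeric(nrow(raw)))
  quant_table(proteins, intens, metadata_spec, bait_gene = bait_gene)
}

#' Write a quantification table to tab-delimited text
#'
#' @param table A [quant_table()].
#' @param path Output file.
#' @return `path`, invisibly. Round-trips with [read_quant_table()].
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  out <- cbind(table$proteins, as.data.frame(table$intensities))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT dialect: `name TAB description TAB member1 TAB member2 ...` per line.
#' Duplicate members within a set are removed with a warning; empty sets are
#' rejected.
#'
#' @param path GMT file.
#' @return Named list of character vectors; descriptions in attribute
#'   `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d: expected name, description and >=1 member", i)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stopf("malformed GMT line %d: empty set '%s'", i, f[1])
    if (anyDuplicated(members)) {
      warnf("GMT line %d ('%s'): duplicate members removed", i, f[1])
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||%
      stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' @param path Tab-delimited file with columns `SNP`, `CHR`, `BP`, `P` and
#'   optional `Z`, `N` (case-insensitive).
#' @return `gwas_summary` data.frame sorted by chromosome and position;
#'   p-values validated to lie in `(0, 1]`.
#' @export
read_gwas_summary <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("snp", "chr", "bp", "p")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stopf("GWAS file lacks column(s): %s",
                          paste(toupper(miss), collapse = ", "))
  if (any(raw$p <= 0 | raw$p > 1 | is.na(raw$p))) {
    stopf("GWAS p-values must lie in (0, 1]; offending SNP(s): %s",
          paste(utils::head(raw$snp[raw$p <= 0 | raw$p > 1 | is.na(raw$p)], 5),
                collapse = ", "))
  }
  dup <- raw$snp[duplicated(raw$snp)]
  if (length(dup)) stopf("duplicate SNP id(s): %s",
                         paste(unique(utils::head(dup, 5)), collapse = ", "))
  out <- data.frame(snp = as.character(raw$snp), chrom = as.character(raw$chr),
                    pos = as.integer(raw$bp), p = raw$p,
                    stringsAsFactors = FALSE)
  if (!is.null(raw$z)) out$z <- raw$z
  if (!is.null(raw$n)) out$n <- raw$n
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Write GWAS summary statistics
#' @param gwas A `gwas_summary` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  out <- data.frame(SNP = gwas$snp, CHR = gwas$chrom, BP = gwas$pos, P = gwas$p)
  if (!is.null(gwas$z)) out$Z <- gwas$z
  if (!is.null(gwas$n)) out$N <- gwas$n
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference panel from dosage TSV (or VCF)
#'
#' The TSV dialect is samples x variants with a header of variant ids and a
#' first column `sample_id`, accompanied by a variant map (`snp`, `chrom`,
#' `pos`, optional `ref`, `alt`). A `.vcf` path is ingested via the vcfR
#' package: GT fields are converted to dosages and only biallelic SNPs are
#' kept (skips are reported in attribute `"n_skipped"`).
#'
#' @param path Dosage TSV or VCF file.
#' @param map_path Variant map TSV (TSV mode only).
#' @return A [reference_panel()].
#' @export
read_panel <- function(path, map_path = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_panel_vcf(path))
  if (is.null(map_path)) stopf("map_path is required for dosage-TSV panels")
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  sample_ids <- d[[1]]
  dos <- as.matrix(d[, -1, drop = FALSE])
  map <- map[match(colnames(dos), map$snp), , drop = FALSE]
  if (anyNA(map$snp)) stopf("variant map does not cover all dosage columns")
  map$chrom <- as.character(map$chrom)
  reference_panel(dos, map, sample_ids = sample_ids)
}

read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("VCF ingestion requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1
  n_skipped <- sum(!biallelic)
  if (n_skipped) message(sprintf("read_panel: skipped %d non-biallelic record(s)",
                                 n_skipped))
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  dose <- apply(gt, 2, function(col) {
    vapply(strsplit(gsub("\\|", "/", col), "/", fixed = FALSE), function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) NA_real_ else sum(a > 0)
    }, numeric(1))
  })
  dose <- t(dose)  # samples x variants
  fix <- fix[biallelic, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  map <- data.frame(snp = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  out <- reference_panel(dose, map, sample_ids = colnames(gt))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a reference panel as dosage TSV plus variant map
#' @param panel A [reference_panel()].
#' @param path Dosage TSV output path.
#' @param map_path Variant map output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, map_path) {
  out <- data.frame(sample_id = panel$sample_ids,
                    panel$dosage, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Two whitespace/tab-delimited columns of gene symbols. Edges are
#' canonicalized (unordered pairs), deduplicated, and self-loops dropped.
#'
#' @param path Edge-list file (optional header `gene_a`/`gene_b`).
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1)
  header <- grepl("gene_a", first)
  d <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("edge list must have two columns")
  e <- canonical_pairs(as.character(d[[1]]), as.character(d[[2]]))
  e <- e[e$gene_a != e$gene_b, , drop = FALSE]
  e <- unique(e)
  rownames(e) <- NULL
  e
}

#' Write an edge list
#' @param edges data.frame with two gene columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path Tab-delimited file with columns `gene_id`, `chrom`, `start`,
#'   `end`, optional `strand`, `biotype`.
#' @param zero_based_half_open Set `TRUE` for BED-style coordinates; they are
#'   converted to the package's 1-based inclusive convention on load.
#' @return Validated annotation data.frame.
#' @export
read_gene_annotation <- function(path, zero_based_half_open = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("annotation lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (zero_based_half_open) d$start <- d$start + 1L
  if (any(d$start > d$end)) stopf("annotation has start > end")
  if (anyDuplicated(d$gene_id)) stopf("duplicate gene id(s) in annotation")
  if (is.null(d$strand)) d$strand <- "*"
  if (is.null(d$biotype)) d$biotype <- "protein_coding"
  d$chrom <- as.character(d$chrom)
  d
}

#' Write a gene annotation table
#' @param annotation Annotation data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a PPI network as node and edge tables
#'
#' Writes `<stem>_edges.tsv` (bait, prey, supporting dataset ids, known flag
#' if annotated) and `<stem>_nodes.tsv` (gene, role, frequency), with
#' deterministic column order and row sort so reruns are byte-identical.
#'
#' @param network A [ppi_network] object.
#' @param stem Output path stem.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network <- function(network, stem) {
  edges <- network$edges[order(network$edges$bait, network$edges$prey), ,
                         drop = FALSE]
  freq <- interactor_frequency(network)$frequency
  nodes <- rbind(
    data.frame(gene = sort(network$baits), role = "index",
               stringsAsFactors = FALSE),
    data.frame(gene = sort(network$interactors), role = "interactor",
               stringsAsFactors = FALSE),
    data.frame(gene = sort(network$noninteractors), role = "non-interactor",
               stringsAsFactors = FALSE))
  nodes$frequency <- freq$n_baits[match(nodes$gene, freq$gene)]
  p_edges <- paste0(stem, "_edges.tsv")
  p_nodes <- paste0(stem, "_nodes.tsv")
  utils::write.table(edges, p_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nodes, p_nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(p_edges, p_nodes))
}

#' Read a serialized PPI network back
#' @param stem Path stem used by [write_network()].
#' @param scope Scope label to attach.
#' @return A [ppi_network] object.
#' @export
read_network <- function(stem, scope = "combined") {
  edges <- utils::read.delim(paste0(stem, "_edges.tsv"),
                             stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(stem, "_nodes.tsv"),
                             stringsAsFactors = FALSE, na.strings = "")
  new_ppi_network(
    baits = nodes$gene[nodes$role == "index"],
    edges = edges,
    interactors = nodes$gene[nodes$role == "interactor"],
    noninteractors = nodes$gene[nodes$role == "non-interactor"],
    scope = scope)
}

#' Write a named list of result tables
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_results <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
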