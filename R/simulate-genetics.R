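# Synthetic genetics: LD-structured reference panels, GWAS summary statistics
# with gene-concentrated signal, gene annotations, gene-set collections, and
# reference PPI edge lists.

#' Configuration for a simulated reference genotype panel
#'
#' Haplotypes are latent Gaussian AR(1) processes thresholded at the
#' allele-frequency quantile, so adjacent-SNP latent correlation decays as
#' `rho^|i-j|`; diploid dosages are sums of two independent haplotypes. This
#' gives cheap, controllable linkage disequilibrium at desk scale.
#'
#' @param n_samples Number of diploid samples (>= 2).
#' @param n_snps Number of variants.
#' @param rho Adjacent-SNP latent correlation in `[0, 1)`.
#' @param maf_range Minor-allele-frequency bounds, each in `(0, 0.5]`.
#' @param chrom Chromosome label.
#' @param bp_spacing Base-pair distance between adjacent variants.
#' @param seed Integer seed.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_samples = 500, n_snps = 100, rho = 0.8,
                             maf_range = c(0.05, 0.5), chrom = "1",
                             bp_spacing = 1000, seed = 1L) {
  assert_count(n_samples, "n_samples", min = 2)
  assert_count(n_snps, "n_snps", min = 1)
  assert_prob(rho, "rho", hi_open = TRUE)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stopf("'maf_range' must be ordered bounds within (0, 0.5]")
  }
  assert_count(bp_spacing, "bp_spacing", min = 1)
  structure(list(n_samples = n_samples, n_snps = n_snps, rho = rho,
                 maf_range = maf_range, chrom = as.character(chrom),
                 bp_spacing = bp_spacing, seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Construct a reference panel object
#'
#' @param dosage Sample x variant matrix with entries in `{0, 1, 2}` (or `NA`);
#'   column names are variant ids.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (+ optional
#'   `ref`, `alt`).
#' @param sample_ids Optional sample identifiers.
#' @return A `reference_panel` object.
#' @export
reference_panel <- function(dosage, map, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (ncol(dosage) != nrow(map)) {
    stopf("dosage has %d variants but map has %d rows", ncol(dosage), nrow(map))
  }
  if (anyDuplicated(map$snp)) stopf("duplicate variant ids in map")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stopf("dosages must lie in {0, 1, 2}")
  colnames(dosage) <- map$snp
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(nrow(dosage)))
  rownames(dosage) <- sample_ids
  structure(list(dosage = dosage, map = map, sample_ids = sample_ids),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d samples x %d variants (chrom %s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$map$chrom), collapse = ",")))
  invisible(x)
}

# One haplotype matrix: latent AR(1) Gaussians thresholded at qnorm(maf).
simulate_haplotypes <- function(n_hap, n_snps, rho, maf) {
  z <- matrix(stats::rnorm(n_hap * n_snps), n_hap, n_snps)
  if (rho > 0 && n_snps > 1) {
    for (j in 2:n_snps) {
      z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
  }
  thr <- stats::qnorm(maf)
  (z < rep(thr, each = n_hap)) + 0L
}

#' Simulate an LD-structured reference genotype panel
#'
#' @param config A [panel_sim_config()].
#' @return A [reference_panel()] with dosages in `{0, 1, 2}` and variants at
#'   `bp_spacing` intervals along `chrom`.
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  with_seed(config$seed, {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    h1 <- simulate_haplotypes(config$n_samples, config$n_snps, config$rho, maf)
    h2 <- simulate_haplotypes(config$n_samples, config$n_snps, config$rho, maf)
    map <- data.frame(
      snp = sprintf("rs%s_%d", config$chrom, seq_len(config$n_snps)),
      chrom = config$chrom,
      pos = seq_len(config$n_snps) * config$bp_spacing,
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    reference_panel(h1 + h2, map)
  })
}

# SNP correlation matrix of a panel (pairwise-complete), with constant
# columns yielding NA guarded by the caller.
panel_correlation <- function(panel, snps = NULL) {
  d <- panel$dosage
  if (!is.null(snps)) d <- d[, snps, drop = FALSE]
  suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
}

#' Simulate GWAS summary statistics over a reference panel
#'
#' Per-SNP z-scores are drawn from a multivariate normal whose covariance is
#' the panel's SNP correlation matrix (eigenvalues floored at 1e-8 for
#' numerical stability under tight LD). Under the null the mean is zero;
#' otherwise SNPs falling inside causal genes have their mean lifted by
#' `effect_size`. Two-sided p-values are attached.
#'
#' @param panel A [reference_panel()].
#' @param causal_gene_ids Character vector of causal gene ids (may be empty).
#' @param gene_annotation data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param effect_size Mean z-score lift inside causal genes.
#' @param seed Integer seed.
#' @return A data.frame of class `gwas_summary` with columns
#'   `snp`, `chrom`, `pos`, `p`, `z`.
#' @export
simulate_gwas_summary <- function(panel, causal_gene_ids = character(),
                                  gene_annotation = NULL, effect_size = 0,
                                  seed = 1L) {
  stopifnot(inherits(panel, "reference_panel"))
  mu <- numeric(ncol(panel$dosage))
  if (length(causal_gene_ids)) {
    if (is.null(gene_annotation)) stopf("gene_annotation required for causal genes")
    missing_genes <- setdiff(causal_gene_ids, gene_annotation$gene_id)
    if (length(missing_genes)) {
      stopf("causal gene(s) absent from annotation: %s",
            paste(missing_genes, collapse = ", "))
    }
    ann <- gene_annotation[gene_annotation$gene_id %in% causal_gene_ids, ,
                           drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      inside <- panel$map$chrom == ann$chrom[i] &
        panel$map$pos >= ann$start[i] & panel$map$pos <= ann$end[i]
      mu[inside] <- effect_size
    }
  }
  # LD is intra-chromosomal: sample the MVN per chromosome block
  z <- numeric(ncol(panel$dosage))
  with_seed(seed, {
    for (chr in unique(panel$map$chrom)) {
      idx <- which(panel$map$chrom == chr)
      R <- panel_correlation(panel, idx)
      R[is.na(R)] <- 0; diag(R) <- 1
      ed <- eigen(R, symmetric = TRUE)
      lam <- pmax(ed$values, 1e-8)
      z[idx] <- mu[idx] +
        as.vector(ed$vectors %*% (sqrt(lam) * stats::rnorm(length(lam))))
    }
  })
  out <- data.frame(snp = panel$map$snp, chrom = panel$map$chrom,
                    pos = panel$map$pos,
                    p = 2 * stats::pnorm(-abs(z)), z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Simulate a gene annotation and a gene-set collection
#'
#' Genes are laid out as sorted, non-overlapping intervals on synthetic
#' chromosomes. Sets are sampled uniformly from the gene universe, except
#' sets named in `enrichment_spec`, whose overlap with a designated target
#' gene list is forced to an exact count.
#'
#' @param n_genes Number of genes.
#' @param n_sets Number of gene sets.
#' @param set_size_range Integer bounds on set sizes.
#' @param enrichment_spec Optional list of lists with fields `set` (index or
#'   name), `target` (character vector of gene ids), `overlap` (forced count).
#' @param seed Integer seed.
#' @param n_chrom Number of synthetic chromosomes.
#' @param gene_length,gap_length Bounds (bp) for gene and inter-gene sizes.
#' @return List with `annotation` (gene_id, chrom, start, end, strand,
#'   biotype) and `sets` (named list of gene-id vectors).
#' @export
simulate_gene_annotation_and_sets <- function(n_genes, n_sets = 10,
                                              set_size_range = c(10, 50),
                                              enrichment_spec = list(),
                                              seed = 1L, n_chrom = 2,
                                              gene_length = c(5e3, 5e4),
                                              gap_length = c(1e4, 1e5)) {
  assert_count(n_genes, "n_genes", min = 1)
  assert_count(n_sets, "n_sets")
  if (max(set_size_range) > n_genes) stopf("set sizes must be <= n_genes")
  with_seed(seed, {
    gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
    chrom <- sort(rep_len(as.character(seq_len(n_chrom)), n_genes))
    len <- round(stats::runif(n_genes, gene_length[1], gene_length[2]))
    gap <- round(stats::runif(n_genes, gap_length[1], gap_length[2]))
    start <- integer(n_genes)
    cur <- stats::setNames(rep(1, n_chrom), as.character(seq_len(n_chrom)))
    for (i in seq_len(n_genes)) {
      cur_chr <- chrom[i]
      start[i] <- cur[cur_chr] + gap[i]
      cur[cur_chr] <- start[i] + len[i]
    }
    annotation <- data.frame(
      gene_id = gene_ids, chrom = chrom, start = start,
      end = start + len - 1,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = "protein_coding", stringsAsFactors = FALSE)

    sets <- list()
    size_choices <- seq(set_size_range[1], set_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_sets,
                                     replace = TRUE)]
    set_names <- sprintf("SET_%02d", seq_len(n_sets))
    for (s in seq_len(n_sets)) sets[[set_names[s]]] <- sample(gene_ids, sizes[s])
    for (spec in enrichment_spec) {
      idx <- if (is.character(spec$set)) match(spec$set, set_names) else spec$set
      if (is.na(idx) || idx < 1 || idx > n_sets) stopf("enrichment_spec names unknown set")
      size <- sizes[idx]
      target <- intersect(spec$target, gene_ids)
      if (spec$overlap > size) stopf("requested overlap %d exceeds set size %d",
                                     spec$overlap, size)
      if (spec$overlap > length(target)) {
        stopf("requested overlap %d exceeds target list size %d",
              spec$overlap, length(target))
      }
      inside <- sample(target, spec$overlap)
      outside <- sample(setdiff(gene_ids, target), size - spec$overlap)
      sets[[idx]] <- sample(c(inside, outside))
    }
    list(annotation = annotation, sets = sets)
  })
}

#' Simulate a reference PPI edge list
#'
#' Produces unique, undirected, canonically-ordered edges over `gene_ids`.
#' When a `network` is supplied, exactly `n_overlap` of the edges coincide
#' with that network's bait-prey edges and the remainder avoid them, so the
#' known/novel split after [annotate_known_edges()] is exact by construction.
#'
#' @param gene_ids Gene universe for random edges.
#' @param n_edges Total number of edges.
#' @param network Optional [ppi_network] whose edges the overlap refers to.
#' @param n_overlap Number of edges shared with `network`.
#' @param seed Integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
simulate_reference_interactions <- function(gene_ids, n_edges,
                                            network = NULL, n_overlap = 0,
                                            seed = 1L) {
  assert_count(n_edges, "n_edges")
  assert_count(n_overlap, "n_overlap")
  net_edges <- if (!is.null(network)) {
    canonical_pairs(network$edges$bait, network$edges$prey)
  } else {
    data.frame(gene_a = character(), gene_b = character())
  }
  net_keys <- unique(paste(net_edges$gene_a, net_edges$gene_b))
  if (n_overlap > length(net_keys)) {
    stopf("n_overlap (%d) exceeds the network's %d edges", n_overlap,
          length(net_keys))
  }
  n_universe <- length(unique(gene_ids))
  if (n_edges > choose(n_universe, 2) + length(net_keys)) {
    stopf("n_edges exceeds the number of possible pairs")
  }
  with_seed(seed, {
    keep <- sample(net_keys, n_overlap)
    chosen <- character(0)
    avoid <- c(net_keys, keep)
    guard <- 0
    while (length(chosen) < n_edges - n_overlap) {
      pair <- sort(sample(unique(gene_ids), 2))
      key <- paste(pair[1], pair[2])
      if (!(key %in% avoid) && !(key %in% chosen)) chosen <- c(chosen, key)
      guard <- guard + 1
      if (guard > 1e6) stopf("could not place %d non-overlapping edges", n_edges)
    }
    keys <- c(keep, chosen)
    parts <- strsplit(keys, " ", fixed = TRUE)
    data.frame(gene_a = vapply(parts, `[`, "", 1),
               gene_b = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  })
}
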