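# Genetic-risk enrichment and locus prioritization: SNP-to-gene annotation
# with MHC exclusion, the SNP-wise mean gene-based association test with an
# LD-aware quadratic-form null, a competitive gene-set test, LD clumping of
# index variants, and PPI-guided prioritization of locus genes.

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Annotate SNPs to genes with a flanking window
#'
#' A SNP is assigned to a gene iff its position lies within
#' `[start - window, end + window]`; a SNP may belong to several genes.
#' Variants inside the major histocompatibility complex (MHC) interval —
#' closed `chr6:28,500,000-33,400,000` by default — are excluded globally
#' because of its extreme LD structure.
#'
#' @param annotation Gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param gwas `gwas_summary` data.frame (`snp`, `chrom`, `pos`, `p`).
#' @param window Flanking window in bp (default 50,000).
#' @param mhc `list(chrom, start, end)` or `c(chrom, start, end)`; `NULL`
#'   disables the exclusion.
#' @return List with `gene_snps` (named list of SNP-id vectors), `genes`
#'   (annotation rows with `n_snps`), and `n_mhc_excluded`.
#' @export
annotate_genes_to_snps <- function(annotation, gwas, window = 50000,
                                   mhc = list(chrom = "6", start = 28500000,
                                              end = 33400000)) {
  ann_chr <- normalize_chrom(annotation$chrom)
  gw_chr <- normalize_chrom(gwas$chrom)
  keep <- rep(TRUE, nrow(gwas))
  n_mhc <- 0L
  if (!is.null(mhc)) {
    mhc <- as.list(mhc)
    if (is.null(names(mhc)) || !all(c("chrom", "start", "end") %in% names(mhc))) {
      names(mhc) <- c("chrom", "start", "end")
    }
    in_mhc <- gw_chr == normalize_chrom(mhc$chrom) &
      gwas$pos >= as.numeric(mhc$start) & gwas$pos <= as.numeric(mhc$end)
    n_mhc <- sum(in_mhc)
    keep <- !in_mhc
  }
  gw <- gwas[keep, , drop = FALSE]
  gw_chr <- gw_chr[keep]
  if (!nrow(gw)) stopf("no SNPs remain after MHC exclusion")

  gene_gr <- GenomicRanges::GRanges(
    seqnames = ann_chr,
    ranges = IRanges::IRanges(start = pmax(1, annotation$start - window),
                              end = annotation$end + window))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = gw_chr,
    ranges = IRanges::IRanges(start = gw$pos, width = 1))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (!length(hits)) stopf("no SNPs annotated to any gene")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  gene_snps <- split(gw$snp[qh], annotation$gene_id[sh])
  gene_snps <- lapply(gene_snps, unique)
  genes <- annotation
  genes$n_snps <- 0L
  counted <- vapply(gene_snps, length, 0L)
  genes$n_snps[match(names(gene_snps), genes$gene_id)] <- counted
  list(gene_snps = gene_snps, genes = genes, n_mhc_excluded = n_mhc)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' @param dosages_a,dosages_b Equal-length numeric vectors; missing entries
#'   are dropped pairwise.
#' @return `r^2`.
#' @export
compute_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) {
    stopf("dosage vectors must have equal length")
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2) stopf("need >= 2 complete sample pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stopf("constant dosage vector: r2 undefined")
  }
  stats::cor(a, b)^2
}

#' Define the LD locus around a GWAS index variant
#'
#' Members are the same-chromosome panel variants whose genotype `r^2` with
#' the index variant exceeds `r2_min` (the index variant is always a member);
#' the locus spans the members padded by `pad` bp on either end, floored
#' at position 1.
#'
#' @param index_variant Variant id present in the panel.
#' @param panel A [reference_panel()].
#' @param r2_min LD threshold (strict; default 0.6).
#' @param pad Flank in bp (default 50,000).
#' @return A `locus` object: `index_variant`, `index_pos`, `chrom`, `start`,
#'   `end`, `members` (SNP ids), `member_r2`.
#' @export
ld_clump_locus <- function(index_variant, panel, r2_min = 0.6, pad = 50000) {
  stopifnot(inherits(panel, "reference_panel"))
  idx <- match(index_variant, panel$map$snp)
  if (is.na(idx)) stopf("index variant '%s' absent from panel", index_variant)
  x <- panel$dosage[, idx]
  if (length(unique(x[!is.na(x)])) < 2) {
    stopf("index variant '%s' is monomorphic in the panel", index_variant)
  }
  chrom <- panel$map$chrom[idx]
  same <- which(panel$map$chrom == chrom)
  r2 <- vapply(same, function(j) {
    if (j == idx) return(1)
    y <- panel$dosage[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
  member_idx <- same[!is.na(r2) & (r2 > r2_min | same == idx)]
  pos <- panel$map$pos[member_idx]
  structure(list(
    index_variant = index_variant,
    index_pos = panel$map$pos[idx],
    chrom = chrom,
    start = max(1, min(pos) - pad),
    end = max(pos) + pad,
    members = panel$map$snp[member_idx],
    member_r2 = r2[match(member_idx, same)]),
    class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s @ %s:%d [%d-%d], %d member SNP(s)\n",
              x$index_variant, x$chrom, x$index_pos, x$start, x$end,
              length(x$members)))
  invisible(x)
}

# Imhof's characteristic-function inversion for P(sum lambda_i chi2_1 >= q).
imhof_upper_tail <- function(q, lambda) {
  theta <- function(u) {
    0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
  }
  rho <- function(u) {
    exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
  }
  integrand <- function(u) {
    out <- sin(theta(u)) / (u * rho(u))
    out[!is.finite(out)] <- 0
    out
  }
  for (rtol in c(1e-8, 1e-6, .Machine$double.eps^0.25)) {
    val <- try(stats::integrate(integrand, lower = 0, upper = Inf,
                                subdivisions = 2000L, rel.tol = rtol)$value,
               silent = TRUE)
    if (!inherits(val, "try-error")) return(0.5 + val / pi)
  }
  NA_real_
}

# Satterthwaite moment-matching fallback: scaled chi-square with
# scale = sum(lambda^2)/sum(lambda), df = sum(lambda)^2/sum(lambda^2).
satterthwaite_upper_tail <- function(q, lambda) {
  sc <- sum(lambda^2) / sum(lambda)
  df <- sum(lambda)^2 / sum(lambda^2)
  stats::pchisq(q / sc, df = df, lower.tail = FALSE)
}

#' SNP-wise mean gene-based association test
#'
#' The gene statistic is the mean association chi-square of the gene's SNPs:
#' `T = mean(z_j^2)` with `z_j^2` the upper-tail chi-square(1) quantile of
#' SNP p-value `p_j`. Under the null, `m * T` is distributed as
#' `sum_i lambda_i chi2_1` where `lambda` are the eigenvalues of the SNP
#' correlation matrix `R` from the reference panel — SNPs in LD contribute
#' correlated chi-squares, and the quadratic-form null accounts for that.
#' The tail probability is computed by numerical inversion of the
#' characteristic function (Imhof integration), falling back to
#' Satterthwaite moment matching if the integration fails; when all
#' eigenvalues are equal (e.g. a single SNP, or `R = I` up to flooring) the
#' exact scaled chi-square tail is used, so a one-SNP gene returns the SNP
#' p-value exactly.
#'
#' @param p Per-SNP p-values for the gene's SNPs (in `(0, 1]`).
#' @param R SNP correlation matrix for those SNPs (ignored for one SNP).
#' @return The gene-based p-value, clamped to `[1e-300, 1]`.
#' @export
gene_based_test <- function(p, R = NULL) {
  m <- length(p)
  if (m == 0) stopf("gene has no SNPs")
  if (any(p <= 0 | p > 1)) stopf("SNP p-values must lie in (0, 1]")
  z2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  q <- sum(z2)
  if (m == 1) return(p)
  if (is.null(R)) stopf("R is required for multi-SNP genes")
  R <- as.matrix(R)
  if (!all(dim(R) == m)) stopf("R must be %d x %d", m, m)
  lambda <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(lambda < -1e-6)) warnf("negative eigenvalue(s) floored at 0")
  lambda <- pmax(lambda, 0)
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) stopf("correlation matrix has no positive eigenvalues")
  if (max(lambda) - min(lambda) < 1e-10) {
    pv <- stats::pchisq(q / lambda[1], df = length(lambda),
                        lower.tail = FALSE)
  } else {
    pv <- imhof_upper_tail(q, lambda)
    if (is.na(pv) || pv <= 0 || pv > 1) pv <- satterthwaite_upper_tail(q, lambda)
  }
  min(max(pv, 1e-300), 1)
}

clamp_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)

#' Gene-based association scan over a GWAS
#'
#' Runs [annotate_genes_to_snps()] and then [gene_based_test()] for every
#' gene with at least one annotated SNP, using the reference panel for the
#' LD structure. Gene Z-scores are the probit of the gene p-value
#' (clamped away from 0/1) and the covariates used by the competitive test
#' (log gene length, log SNP count) are attached.
#'
#' @param gwas `gwas_summary` data.frame.
#' @param panel A [reference_panel()].
#' @param annotation Gene annotation data.frame.
#' @param window Flanking window in bp (default 50,000).
#' @param mhc MHC exclusion interval (see [annotate_genes_to_snps()]).
#' @return `gene_results` data.frame: `gene_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `p`, `z`, `length`, `log_length`, `log_nsnps`.
#' @export
gene_based_scan <- function(gwas, panel, annotation, window = 50000,
                            mhc = list(chrom = "6", start = 28500000,
                                       end = 33400000)) {
  ann <- annotate_genes_to_snps(annotation, gwas, window = window, mhc = mhc)
  psnp <- stats::setNames(gwas$p, gwas$snp)
  rows <- lapply(names(ann$gene_snps), function(g) {
    snps <- intersect(ann$gene_snps[[g]], panel$map$snp)
    snps <- intersect(snps, gwas$snp)
    if (!length(snps)) return(NULL)
    R <- if (length(snps) > 1) {
      Rm <- panel_correlation(panel, snps)
      Rm[is.na(Rm)] <- 0; diag(Rm) <- 1
      Rm
    } else NULL
    gi <- match(g, annotation$gene_id)
    data.frame(gene_id = g, chrom = annotation$chrom[gi],
               start = annotation$start[gi], end = annotation$end[gi],
               n_snps = length(snps),
               p = gene_based_test(psnp[snps], R),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stopf("no genes with annotated SNPs")
  out$z <- stats::qnorm(clamp_p(out$p), lower.tail = FALSE)
  out$length <- out$end - out$start + 1
  out$log_length <- log(out$length)
  out$log_nsnps <- log(out$n_snps)
  rownames(out) <- NULL
  class(out) <- c("gene_results", "data.frame")
  out
}

#' Competitive gene-set test for genetic risk enrichment
#'
#' Regresses gene Z-scores on set membership plus covariates (log gene
#' length and log SNP count by default) over the background genes, and
#' reports the one-tailed p-value for a positive membership coefficient —
#' i.e. whether the member genes carry stronger association signal than the
#' background. The background is either the full gene-results table
#' (global: interactors vs. the rest of the genome) or a supplied subset
#' (conditional: interactors vs. non-interactors). Permutation mode re-draws
#' membership labels within the background to form an empirical null for the
#' coefficient, sidestepping distributional assumptions.
#'
#' @param gene_results A [gene_based_scan()] result (or data.frame with
#'   `gene_id`, `z`, covariate columns).
#' @param members Character vector of member gene ids.
#' @param background Optional character vector of background gene ids
#'   (must include at least 2 members and 2 non-members); default all genes.
#' @param covariates Covariate column names (constant columns dropped with a
#'   warning).
#' @param mode `"analytic"` (t-test on the coefficient) or `"permutation"`.
#' @param B Number of permutations (permutation mode).
#' @param seed Seed for the permutations.
#' @return List with `beta`, `se`, `p` (one-tailed), `n_members`,
#'   `n_background`, `mode`, and `p_analytic` alongside `p` in permutation
#'   mode.
#' @export
competitive_geneset_test <- function(gene_results, members, background = NULL,
                                     covariates = c("log_length", "log_nsnps"),
                                     mode = c("analytic", "permutation"),
                                     B = 1000, seed = 1L) {
  mode <- match.arg(mode)
  d <- as.data.frame(gene_results)
  if (!is.null(background)) {
    if (length(background) < length(intersect(members, background))) {
      stopf("background smaller than the member set")
    }
    d <- d[d$gene_id %in% background, , drop = FALSE]
  }
  d$member <- as.integer(d$gene_id %in% members)
  if (sum(d$member) < 2 || sum(!d$member) < 2) {
    stopf("need >= 2 member and >= 2 non-member genes in the background")
  }
  keep <- character(0)
  for (cv in covariates) {
    if (is.null(d[[cv]])) next
    if (stats::sd(d[[cv]]) == 0) {
      warnf("constant covariate '%s' dropped", cv)
    } else keep <- c(keep, cv)
  }
  if (stats::sd(d$z) == 0) {
    return(list(beta = 0, se = NA_real_, p = 0.5, n_members = sum(d$member),
                n_background = nrow(d), mode = mode))
  }
  fml <- stats::reformulate(c("member", keep), response = "z")
  fit <- stats::lm(fml, data = d)
  co <- summary(fit)$coefficients
  beta <- co["member", "Estimate"]
  se <- co["member", "Std. Error"]
  tt <- co["member", "t value"]
  p_analytic <- stats::pt(tt, df = fit$df.residual, lower.tail = FALSE)
  res <- list(beta = beta, se = se, p = p_analytic,
              n_members = sum(d$member), n_background = nrow(d),
              mode = mode)
  if (mode == "permutation") {
    X <- stats::model.matrix(stats::reformulate(c("1", keep)), data = d)
    Q <- diag(nrow(d)) - X %*% solve(crossprod(X)) %*% t(X)
    y_res <- as.vector(Q %*% d$z)
    g_obs <- d$member
    beta_of <- function(gmat) {
      gq <- Q %*% gmat
      colSums(gq * y_res) / colSums(gq * gq)
    }
    b_obs <- beta_of(matrix(g_obs, ncol = 1))
    G <- with_seed(seed, {
      vapply(seq_len(B), function(b) sample(g_obs), numeric(length(g_obs)))
    })
    b_perm <- beta_of(G)
    res$p_analytic <- p_analytic
    res$p <- (1 + sum(b_perm >= b_obs)) / (B + 1)
    res$B <- B
  }
  res
}

#' Prioritize candidate genes in GWAS risk loci via the PPI networks
#'
#' For each LD locus, extracts the protein-coding genes overlapping it
#' (1-based inclusive interval overlap) and flags each as an index gene, an
#' interactor (with the linking baits and network scopes), or unflagged.
#' Prioritized genes are locus genes that are index genes or interactors in
#' at least one supplied network.
#'
#' @param loci List of `locus` objects from [ld_clump_locus()].
#' @param annotation Gene annotation data.frame (`biotype` filtered to
#'   `protein_coding` when the column exists).
#' @param networks Named list of `ppi_network` objects.
#' @return List with `table` (one row per locus x gene) and `summary`
#'   (unique prioritized gene counts per network and combined).
#' @export
prioritize_locus_genes <- function(loci, annotation, networks) {
  if (inherits(networks, "ppi_network")) networks <- list(network = networks)
  if (is.null(names(networks))) {
    names(networks) <- sprintf("network%d", seq_along(networks))
  }
  ann <- annotation
  if (!is.null(ann$biotype)) {
    ann <- ann[ann$biotype == "protein_coding", , drop = FALSE]
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(ann$chrom),
    ranges = IRanges::IRanges(start = ann$start, end = ann$end))
  rows <- list()
  for (loc in loci) {
    loc_gr <- GenomicRanges::GRanges(
      seqnames = normalize_chrom(loc$chrom),
      ranges = IRanges::IRanges(start = loc$start, end = loc$end))
    hit <- suppressWarnings(
      S4Vectors::subjectHits(GenomicRanges::findOverlaps(loc_gr, gene_gr)))
    if (!length(hit)) next
    for (gi in hit) {
      g <- ann$gene_id[gi]
      is_index <- any(vapply(networks, function(nw) g %in% nw$baits, TRUE))
      linked <- lapply(networks, function(nw) {
        sort(unique(nw$edges$bait[nw$edges$prey == g &
                                    g %in% nw$interactors]))
      })
      in_nets <- names(networks)[vapply(linked, length, 0L) > 0]
      baits <- sort(unique(unlist(linked)))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loc$index_variant, chrom = loc$chrom,
        locus_start = loc$start, locus_end = loc$end,
        gene_id = g, gene_start = ann$start[gi], gene_end = ann$end[gi],
        is_index = is_index,
        is_interactor = length(baits) > 0,
        linked_baits = paste(baits, collapse = ","),
        networks = paste(in_nets, collapse = ","),
        prioritized = is_index || length(baits) > 0,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), chrom = character(),
               locus_start = integer(), locus_end = integer(),
               gene_id = character(), gene_start = integer(),
               gene_end = integer(), is_index = logical(),
               is_interactor = logical(), linked_baits = character(),
               networks = character(), prioritized = logical())
  per_net <- vapply(names(networks), function(nm) {
    length(unique(tab$gene_id[tab$prioritized &
                                (grepl(nm, tab$networks, fixed = TRUE) |
                                   tab$is_index)]))
  }, 0L)
  summary <- data.frame(
    network = c(names(networks), "combined"),
    n_prioritized = c(per_net,
                      length(unique(tab$gene_id[tab$prioritized]))),
    stringsAsFactors = FALSE)
  list(table = tab, summary = summary)
}

#' Build the social Manhattan table
#'
#' One row per prioritized gene: chromosomal position (gene midpoint),
#' `-log10` GWAS p-value of the tagging index SNP of its locus, and role
#' (index / interactor); plus an edge table of index-interactor links among
#' the plotted genes drawn from the networks. Genes whose locus index SNP is
#' absent from the GWAS are excluded with a warning.
#'
#' @param prioritized A [prioritize_locus_genes()] result.
#' @param gwas `gwas_summary` data.frame (for the tagging SNP p-values).
#' @param networks Named list of `ppi_network` objects.
#' @return List with `nodes` and `edges` data.frames.
#' @export
social_manhattan_table <- function(prioritized, gwas, networks) {
  if (inherits(networks, "ppi_network")) networks <- list(network = networks)
  tab <- prioritized$table
  tab <- tab[tab$prioritized, , drop = FALSE]
  psnp <- stats::setNames(gwas$p, gwas$snp)
  tag_p <- psnp[tab$locus]
  if (anyNA(tag_p)) {
    warnf("%d prioritized gene(s) without a tagging SNP in the GWAS excluded",
          sum(is.na(tag_p)))
    tab <- tab[!is.na(tag_p), , drop = FALSE]
    tag_p <- tag_p[!is.na(tag_p)]
  }
  nodes <- data.frame(
    gene_id = tab$gene_id, chrom = tab$chrom,
    pos = (tab$gene_start + tab$gene_end) / 2,
    tag_snp = tab$locus,
    minus_log10_p = -log10(as.numeric(tag_p)),
    role = ifelse(tab$is_index, "index", "interactor"),
    stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  plotted <- nodes$gene_id
  edges <- do.call(rbind, lapply(names(networks), function(nm) {
    e <- networks[[nm]]$edges
    e <- e[e$bait %in% plotted & e$prey %in% plotted,
           c("bait", "prey"), drop = FALSE]
    if (!nrow(e)) return(NULL)
    e$network <- nm
    e
  }))
  if (is.null(edges)) {
    edges <- data.frame(bait = character(), prey = character(),
                        network = character())
  } else {
    edges <- edges[!duplicated(paste(edges$bait, edges$prey)), , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}

#' Plot a social Manhattan table
#'
#' Genome position on the x axis, `-log10` tagging-SNP p-value on the y
#' axis, with segments for the protein-interaction edges among plotted
#' genes. Requires ggplot2.
#'
#' @param smt A [social_manhattan_table()] result.
#' @return A ggplot object.
#' @export
plot_social_manhattan <- function(smt) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("plot_social_manhattan requires the 'ggplot2' package")
  }
  nodes <- smt$nodes
  chroms <- unique(nodes$chrom[order(suppressWarnings(as.numeric(nodes$chrom)),
                                     nodes$chrom)])
  offs <- stats::setNames(seq(0, by = 1, length.out = length(chroms)) * 1e8,
                          chroms)
  nodes$x <- nodes$pos + offs[nodes$chrom]
  e <- smt$edges
  if (nrow(e)) {
    e$x0 <- nodes$x[match(e$bait, nodes$gene_id)]
    e$y0 <- nodes$minus_log10_p[match(e$bait, nodes$gene_id)]
    e$x1 <- nodes$x[match(e$prey, nodes$gene_id)]
    e$y1 <- nodes$minus_log10_p[match(e$prey, nodes$gene_id)]
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = x, y = minus_log10_p))
  if (nrow(e)) {
    p <- p + ggplot2::geom_segment(
      data = e, ggplot2::aes(x = x0, y = y0, xend = x1, yend = y1),
      colour = "grey70", linewidth = 0.3, inherit.aes = FALSE)
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = role), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = gene_id),
                       vjust = -0.8, size = 2.5) +
    ggplot2::labs(x = "genomic position", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}
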