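# Orchestration: configuration with full defaulting, per-stage logging,
# seed substreams, and end-to-end commands chaining the pipeline stages over
# synthetic or user-supplied inputs.

#' Pipeline configuration
#'
#' Every fixed constant of the analysis lives here; defaults equal the
#' pipeline's canonical thresholds (log2FC > 0, FDR <= 0.1, replicate
#' correlation > 0.6, imputation width 0.3 / downshift 1.8 SD, LD r^2 > 0.6,
#' +/- 50 kb windows, MHC chr6:28.5-33.4 Mb excluded). No stage uses a
#' threshold that is not sourced from this object.
#'
#' @param lfc_min,fdr_max Interactor-call thresholds.
#' @param corr_min QC replicate-correlation threshold.
#' @param impute_width,impute_shift Imputation parameters (SD units).
#' @param r2_min,window LD threshold and flanking window (bp).
#' @param mhc MHC exclusion interval `list(chrom, start, end)`.
#' @param permutation_b Permutations for the competitive test (0 = analytic).
#' @param seed Top-level seed; stage substreams derive from it.
#' @param sim Simulation settings: lists of arguments for
#'   [ipms_sim_config()] (`ipms`), [panel_sim_config()] (`panel`), plus
#'   `n_datasets_per_celltype`, `n_genes`, `n_sets`, `gwas_effect`,
#'   `n_causal`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lfc_min = 0, fdr_max = 0.1, corr_min = 0.6,
                            impute_width = 0.3, impute_shift = 1.8,
                            r2_min = 0.6, window = 50000,
                            mhc = list(chrom = "6", start = 28500000,
                                       end = 33400000),
                            permutation_b = 0, seed = 1L, sim = list()) {
  assert_prob(fdr_max, "fdr_max")
  assert_prob(corr_min, "corr_min", lo = -1)
  assert_prob(r2_min, "r2_min")
  if (impute_width <= 0 || impute_shift < 0) {
    stopf("impute_width must be > 0 and impute_shift >= 0")
  }
  assert_count(window, "window")
  sim_defaults <- list(
    # desk-scale demo proteome with reproducible non-specific background so
    # the replicate-correlation QC gate operates on realistic data
    ipms = list(n_proteins = 2000, background_logfc_sd = 1),
    # variants every 5 kb across ~7.5 Mb so chromosome-1 genes carry SNPs
    panel = list(n_samples = 300, n_snps = 1500, bp_spacing = 5000),
    n_datasets_per_celltype = 2L, n_genes = 200L,
    n_sets = 10L, gwas_effect = 3, n_causal = 2L)
  sim <- utils::modifyList(sim_defaults, sim)
  structure(list(lfc_min = lfc_min, fdr_max = fdr_max, corr_min = corr_min,
                 impute_width = impute_width, impute_shift = impute_shift,
                 r2_min = r2_min, window = window, mhc = mhc,
                 permutation_b = permutation_b, seed = as.integer(seed),
                 sim = sim),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown fields are rejected with a field-level message; missing fields
#' take their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config field(s): %s",
                         paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

config_checksum <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 31 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[baitnet] ", fmt), ...))
}

#' Run the pipeline
#'
#' Chains the stages over synthetic inputs: `simulate` generates IP-MS
#' datasets for two cell types plus the genetic inputs; `call` analyzes each
#' dataset and applies QC; `network` assembles and partitions the PPI
#' networks; `enrich` runs the hypergeometric gene-set enrichment (global
#' and conditional); `gwas` runs the gene-based scan and competitive
#' genetic-risk tests; `prioritize` clumps index variants and intersects
#' locus genes with the networks; `all` chains everything. Each stage writes
#' its tables under `out_dir` plus a run manifest (config checksum, seed,
#' per-stage row counts).
#'
#' @param command One of `simulate`, `call`, `network`, `enrich`, `gwas`,
#'   `prioritize`, `all`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` for no files.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list of all stage results plus `manifest`.
#' @export
run_pipeline <- function(command = c("all", "simulate", "call", "network",
                                     "enrich", "gwas", "prioritize"),
                         config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  state <- list(config = config)
  counts <- list()
  stages <- if (command == "all") {
    c("simulate", "call", "network", "enrich", "gwas", "prioritize")
  } else command
  if (!identical(stages[1], "simulate") && command != "all") {
    # single-stage commands still need upstream state; rebuild it silently
    pre <- c("simulate", "call", "network", "enrich", "gwas")
    need <- pre[seq_len(match(command, c(pre, "prioritize")) - 1)]
    for (st in need) state <- run_stage(st, state, quiet = TRUE)
  }
  for (st in stages) {
    state <- run_stage(st, state, quiet = quiet)
    counts[[st]] <- state$last_counts
  }
  manifest <- list(command = command,
                   config_checksum = config_checksum(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("baitnet")),
                   counts = counts)
  state$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_outputs(state, out_dir)
  invisible(state)
}

run_stage <- function(stage, state, quiet = FALSE) {
  cfg <- state$config
  switch(stage,
    simulate = {
      sim <- cfg$sim
      n_ct <- sim$n_datasets_per_celltype
      datasets <- list()
      truths <- list()
      for (ct in c("EC", "SMC")) {
        for (i in seq_len(n_ct)) {
          dsid <- sprintf("%s_ds%d", ct, i)
          args <- utils::modifyList(
            list(seed = derive_seed(cfg$seed, paste0("ipms_", dsid))),
            sim$ipms)
          args$seed <- derive_seed(cfg$seed, paste0("ipms_", dsid))
          simc <- do.call(ipms_sim_config, args)
          out <- simulate_ipms_dataset(simc, dataset_id = dsid, cell_type = ct)
          datasets[[dsid]] <- out$table
          truths[[dsid]] <- out$truth
        }
      }
      pargs <- utils::modifyList(
        list(seed = derive_seed(cfg$seed, "panel")), sim$panel)
      panel <- simulate_reference_panel(do.call(panel_sim_config, pargs))
      ann <- simulate_gene_annotation_and_sets(
        n_genes = sim$n_genes, n_sets = sim$n_sets,
        seed = derive_seed(cfg$seed, "annotation"))
      log_stage(quiet, "simulate: %d IP-MS datasets, panel %d x %d, %d genes, %d sets",
                length(datasets), nrow(panel$dosage), ncol(panel$dosage),
                nrow(ann$annotation), length(ann$sets))
      state$datasets <- datasets
      state$truths <- truths
      state$panel <- panel
      state$annotation <- ann$annotation
      state$gene_sets <- ann$sets
      state$last_counts <- list(n_datasets = length(datasets),
                                n_snps = ncol(panel$dosage),
                                n_genes = nrow(ann$annotation))
      state
    },
    call = {
      stats_list <- list()
      qc_rows <- list()
      for (dsid in names(state$datasets)) {
        st <- analyze_ipms_dataset(
          state$datasets[[dsid]],
          impute_width = cfg$impute_width, impute_shift = cfg$impute_shift,
          lfc_min = cfg$lfc_min, fdr_max = cfg$fdr_max,
          seed = derive_seed(cfg$seed, paste0("impute_", dsid)))
        qc <- qc_dataset(st, corr_min = cfg$corr_min)
        qc_rows[[dsid]] <- cbind(qc$metrics, qc_pass = qc$pass)
        if (qc$pass) stats_list[[dsid]] <- st
        log_stage(quiet, "call: %s — %d detected, %d significant, QC %s",
                  dsid, qc$metrics$n_detected, qc$metrics$n_significant,
                  if (qc$pass) "pass" else paste(qc$reasons, collapse = ";"))
      }
      if (!length(stats_list)) stopf("no dataset passed QC")
      state$stats <- stats_list
      state$qc <- do.call(rbind, c(qc_rows, make.row.names = FALSE))
      state$last_counts <- list(n_pass = length(stats_list),
                                n_fail = sum(!state$qc$qc_pass))
      state
    },
    network = {
      by_ct <- split(names(state$stats),
                     vapply(state$stats, function(s) attr(s, "cell_type"), ""))
      nets <- list()
      for (ct in names(by_ct)) {
        nets[[ct]] <- build_network(state$stats[by_ct[[ct]]],
                                    scope = paste0("per-cell-type:", ct))
      }
      combined <- build_network(state$stats, scope = "combined")
      state$networks <- nets
      state$network_combined <- combined
      if (all(c("EC", "SMC") %in% names(nets))) {
        state$partitions <- celltype_partition(nets$EC, nets$SMC)
      }
      freq <- interactor_frequency(combined)
      state$frequency <- freq
      log_stage(quiet, "network: combined %d interactors / %d non-interactors; %.0f%% multi-bait",
                length(combined$interactors), length(combined$noninteractors),
                100 * (freq$fraction_multi %||% NA))
      state$last_counts <- list(
        n_interactors = length(combined$interactors),
        n_noninteractors = length(combined$noninteractors),
        n_edges = nrow(combined$edges))
      state
    },
    enrich = {
      res_g <- geneset_enrichment(state$network_combined, state$gene_sets,
                                  mode = "global")
      res_c <- geneset_enrichment(state$network_combined, state$gene_sets,
                                  mode = "conditional")
      state$enrichment <- list(global = res_g, conditional = res_c)
      log_stage(quiet, "enrich: %d sets tested; min global p = %.3g",
                nrow(res_g), min(res_g$p, na.rm = TRUE))
      state$last_counts <- list(n_sets = nrow(res_g))
      state
    },
    gwas = {
      interactors <- state$network_combined$interactors
      noninteractors <- state$network_combined$noninteractors
      causal <- utils::head(intersect(interactors, state$annotation$gene_id),
                            cfg$sim$n_causal)
      state$gwas_causal <- causal
      gwas <- simulate_gwas_summary(
        state$panel, causal_gene_ids = causal,
        gene_annotation = state$annotation,
        effect_size = cfg$sim$gwas_effect,
        seed = derive_seed(cfg$seed, "gwas"))
      state$gwas <- gwas
      scan <- gene_based_scan(gwas, state$panel, state$annotation,
                              window = cfg$window, mhc = cfg$mhc)
      state$gene_results <- scan
      mode <- if (cfg$permutation_b > 0) "permutation" else "analytic"
      glob <- competitive_geneset_test(
        scan, members = interactors, mode = mode, B = max(cfg$permutation_b, 1),
        seed = derive_seed(cfg$seed, "perm_global"))
      cond <- competitive_geneset_test(
        scan, members = interactors,
        background = union(interactors, noninteractors),
        mode = mode, B = max(cfg$permutation_b, 1),
        seed = derive_seed(cfg$seed, "perm_cond"))
      state$risk_enrichment <- list(global = glob, conditional = cond)
      log_stage(quiet, "gwas: %d genes tested; global risk-enrichment p = %.3g",
                nrow(scan), glob$p)
      state$last_counts <- list(n_genes_tested = nrow(scan))
      state
    },
    prioritize = {
      gwas <- state$gwas
      # index variants: the most significant SNP per causal gene region,
      # plus the overall top SNPs
      top <- gwas[order(gwas$p), ]
      index_variants <- utils::head(top$snp, 3)
      loci <- lapply(index_variants, function(v) {
        ld_clump_locus(v, state$panel, r2_min = cfg$r2_min, pad = cfg$window)
      })
      nets <- state$networks %||% list(combined = state$network_combined)
      pri <- prioritize_locus_genes(loci, state$annotation, nets)
      smt <- social_manhattan_table(pri, gwas, nets)
      state$loci <- loci
      state$prioritized <- pri
      state$social_manhattan <- smt
      log_stage(quiet, "prioritize: %d loci, %d prioritized gene(s)",
                length(loci),
                pri$summary$n_prioritized[pri$summary$network == "combined"])
      state$last_counts <- list(
        n_loci = length(loci),
        n_prioritized = pri$summary$n_prioritized[
          pri$summary$network == "combined"])
      state
    },
    stopf("unknown stage '%s'", stage))
}

write_pipeline_outputs <- function(state, out_dir) {
  tables <- list()
  if (!is.null(state$qc)) tables$qc_metrics <- state$qc
  if (!is.null(state$enrichment)) {
    tables$enrichment_global <- state$enrichment$global
    tables$enrichment_conditional <- state$enrichment$conditional
  }
  if (!is.null(state$gene_results)) tables$gene_results <- state$gene_results
  if (!is.null(state$prioritized)) {
    tables$prioritized_genes <- state$prioritized$table
    tables$prioritized_summary <- state$prioritized$summary
  }
  if (!is.null(state$social_manhattan)) {
    tables$social_manhattan_nodes <- state$social_manhattan$nodes
    tables$social_manhattan_edges <- state$social_manhattan$edges
  }
  if (length(tables)) write_results(tables, out_dir)
  if (!is.null(state$network_combined)) {
    write_network(state$network_combined,
                  file.path(out_dir, "network_combined"))
  }
  jsonlite::write_json(state$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
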