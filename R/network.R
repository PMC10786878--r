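# Assembly of bait-centric PPI networks from per-dataset interactor calls:
# interactor / non-interactor lists, bait-prey edges with provenance,
# known-edge annotation, interactor frequency, and cell-type partitions.

new_ppi_network <- function(baits, edges, interactors, noninteractors, scope) {
  interactors <- sort(unique(setdiff(interactors, baits)))
  noninteractors <- sort(unique(setdiff(noninteractors,
                                        c(interactors, baits))))
  structure(list(baits = sort(unique(baits)),
                 edges = edges,
                 interactors = interactors,
                 noninteractors = noninteractors,
                 scope = scope),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network [%s]: %d index protein(s), %d interactors, %d non-interactors, %d edges\n",
              x$scope, length(x$baits), length(x$interactors),
              length(x$noninteractors), nrow(x$edges)))
  invisible(x)
}

#' Build a PPI network from per-dataset interactor calls
#'
#' Applies the combination rules: proteins significant in at least one
#' contributing dataset are interactors; proteins detected in at least one
#' dataset but significant in none are non-interactors; all index (bait)
#' proteins of the contributing IPs are excluded from both lists. Bait-prey
#' edges record the supporting dataset ids; an edge from one index protein to
#' another is kept as an index-index interaction even though the prey is
#' excluded from the interactor list.
#'
#' @param datasets List of [call_interactors()] results (all QC-passing).
#' @param scope Scope label (`"per-bait"`, `"per-cell-type"`, `"combined"`,
#'   ...).
#' @return A `ppi_network` object.
#' @export
build_network <- function(datasets, scope = "combined") {
  if (!length(datasets)) stopf("empty dataset list")
  baits <- unique(vapply(datasets, function(s) attr(s, "bait_gene"), ""))
  baits <- baits[!is.na(baits)]
  sig_all <- character(0)
  det_all <- character(0)
  edge_rows <- list()
  for (s in datasets) {
    bait <- attr(s, "bait_gene")
    dsid <- attr(s, "dataset_id")
    sig <- unique(s$gene_symbol[s$significant & s$gene_symbol != bait])
    sig_all <- union(sig_all, sig)
    det_all <- union(det_all, unique(s$gene_symbol))
    if (length(sig)) {
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        bait = bait, prey = sig, dataset_id = dsid,
        cell_type = attr(s, "cell_type") %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  edges_long <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(bait = character(), prey = character(),
               dataset_id = character(), cell_type = character())
  edges_long <- edges_long[edges_long$bait != edges_long$prey, , drop = FALSE]
  if (nrow(edges_long)) {
    key <- paste(edges_long$bait, edges_long$prey, sep = "\r")
    agg_ds <- tapply(edges_long$dataset_id, key,
                     function(v) paste(sort(unique(v)), collapse = ","))
    agg_ct <- tapply(edges_long$cell_type, key, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) paste(sort(unique(v)), collapse = ",") else NA_character_
    })
    parts <- strsplit(names(agg_ds), "\r", fixed = TRUE)
    edges <- data.frame(
      bait = vapply(parts, `[`, "", 1),
      prey = vapply(parts, `[`, "", 2),
      datasets = as.character(agg_ds),
      cell_types = as.character(agg_ct),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$bait, edges$prey), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(bait = character(), prey = character(),
                        datasets = character(), cell_types = character())
  }
  new_ppi_network(baits = baits, edges = edges,
                  interactors = sig_all,
                  noninteractors = setdiff(det_all, sig_all),
                  scope = scope)
}

#' Interactor frequency across index proteins
#'
#' Counts, per interactor, the number of distinct index proteins it is linked
#' to, and summarizes the fraction of interactors linked to more than one.
#'
#' @param network A `ppi_network`.
#' @return List with `frequency` (data.frame `gene`, `n_baits`) and
#'   `fraction_multi` (fraction with frequency >= 2).
#' @export
interactor_frequency <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges[network$edges$prey %in% network$interactors, ,
                     drop = FALSE]
  if (nrow(e)) {
    tab <- tapply(e$bait, e$prey, function(b) length(unique(b)))
    freq <- data.frame(gene = names(tab), n_baits = as.integer(tab),
                       stringsAsFactors = FALSE)
    freq <- freq[order(-freq$n_baits, freq$gene), , drop = FALSE]
    rownames(freq) <- NULL
  } else {
    freq <- data.frame(gene = character(), n_baits = integer())
  }
  frac <- if (nrow(freq)) mean(freq$n_baits >= 2) else NA_real_
  list(frequency = freq, fraction_multi = frac)
}

#' Annotate network edges against reference PPI lists
#'
#' An edge is flagged known in a reference list iff its unordered gene pair
#' appears there; `known_any` marks presence in at least one list.
#'
#' @param network A `ppi_network`.
#' @param reference_lists Named list of edge data.frames (two gene columns,
#'   as from [read_edge_list()]).
#' @return The network with per-list `known_<name>` columns, `known_any`,
#'   and a `known_summary` data.frame of per-list known fractions.
#' @export
annotate_known_edges <- function(network, reference_lists) {
  stopifnot(inherits(network, "ppi_network"))
  if (!is.list(reference_lists) || is.data.frame(reference_lists)) {
    reference_lists <- list(reference = reference_lists)
  }
  if (is.null(names(reference_lists))) {
    names(reference_lists) <- sprintf("ref%d", seq_along(reference_lists))
  }
  e <- network$edges
  ekey <- if (nrow(e)) {
    cp <- canonical_pairs(e$bait, e$prey)
    paste(cp$gene_a, cp$gene_b)
  } else character(0)
  known_any <- rep(FALSE, nrow(e))
  summary_rows <- list()
  for (nm in names(reference_lists)) {
    ref <- reference_lists[[nm]]
    rkey <- if (nrow(ref)) {
      cp <- canonical_pairs(as.character(ref[[1]]), as.character(ref[[2]]))
      paste(cp$gene_a, cp$gene_b)
    } else character(0)
    flag <- ekey %in% rkey
    e[[paste0("known_", nm)]] <- flag
    known_any <- known_any | flag
    summary_rows[[nm]] <- data.frame(
      reference = nm, n_edges = nrow(e), n_known = sum(flag),
      fraction_known = if (nrow(e)) mean(flag) else NA_real_,
      stringsAsFactors = FALSE)
  }
  e$known_any <- known_any
  summary_rows$any <- data.frame(
    reference = "any", n_edges = nrow(e), n_known = sum(known_any),
    fraction_known = if (nrow(e)) mean(known_any) else NA_real_,
    stringsAsFactors = FALSE)
  network$edges <- e
  network$known_summary <- do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE))
  network
}

#' Partition two cell-type networks
#'
#' For index proteins assayed in both cell types, splits interactors into
#' those found exclusively in the first network (e.g. EC only), exclusively
#' in the second (SMC only), in both (Intersect), or in either (Union).
#' Non-interactor backgrounds are the union of the contributing cell types'
#' non-interactors minus the union of their interactors, which guarantees
#' that a gene significant in any contributing dataset never appears as a
#' non-interactor.
#'
#' @param network_a,network_b `ppi_network` objects for the two cell types.
#' @param labels Length-2 labels (default `c("EC", "SMC")`).
#' @return List with the four partition networks (`a_only`, `b_only`,
#'   `intersect`, `union`) and `per_bait` summary counts for shared baits.
#' @export
celltype_partition <- function(network_a, network_b, labels = c("EC", "SMC")) {
  stopifnot(inherits(network_a, "ppi_network"),
            inherits(network_b, "ppi_network"))
  ia <- network_a$interactors
  ib <- network_b$interactors
  baits <- union(network_a$baits, network_b$baits)
  parts <- list(
    a_only = setdiff(ia, ib),
    b_only = setdiff(ib, ia),
    intersect = intersect(ia, ib),
    union = union(ia, ib))
  names(parts)[1:2] <- c(paste0(labels[1], "_only"), paste0(labels[2], "_only"))
  contrib <- list(network_a, network_b, list(network_a, network_b),
                  list(network_a, network_b))
  mk <- function(members, contrib_nets, scope) {
    if (inherits(contrib_nets, "ppi_network")) contrib_nets <- list(contrib_nets)
    nonint <- Reduce(union, lapply(contrib_nets, `[[`, "noninteractors"))
    ints <- Reduce(union, lapply(contrib_nets, `[[`, "interactors"))
    edges <- do.call(rbind, lapply(contrib_nets, `[[`, "edges"))
    edges <- edges[edges$prey %in% members, , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$bait, edges$prey)), , drop = FALSE]
    rownames(edges) <- NULL
    new_ppi_network(baits = baits, edges = edges, interactors = members,
                    noninteractors = setdiff(nonint, ints), scope = scope)
  }
  nets <- Map(mk, parts, contrib, names(parts))
  shared <- intersect(network_a$baits, network_b$baits)
  per_bait <- do.call(rbind, lapply(shared, function(b) {
    pa <- unique(network_a$edges$prey[network_a$edges$bait == b])
    pb <- unique(network_b$edges$prey[network_b$edges$bait == b])
    pa <- intersect(pa, ia); pb <- intersect(pb, ib)
    data.frame(bait = b,
               n_a_only = length(setdiff(pa, pb)),
               n_b_only = length(setdiff(pb, pa)),
               n_intersect = length(intersect(pa, pb)),
               n_union = length(union(pa, pb)),
               stringsAsFactors = FALSE)
  }))
  c(nets, list(per_bait = per_bait %||%
                 data.frame(bait = character(), n_a_only = integer(),
                            n_b_only = integer(), n_intersect = integer(),
                            n_union = integer())))
}
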