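# Overlap statistics: one-tailed hypergeometric enrichment with global and
# conditional population constructions, Bonferroni adjustment over the tests
# actually run, and Wilcoxon rank-sum comparisons.

#' One-tailed hypergeometric overlap test
#'
#' Upper-tail probability of drawing at least `x` successes:
#' `p = sum_{i >= x} C(k, i) C(N - k, n - i) / C(N, n)`, including the
#' observed `x` itself. Computed in log space via [stats::phyper()].
#'
#' @param N Population size.
#' @param k Successes in the population.
#' @param n Sample size drawn.
#' @param x Observed successes in the sample.
#' @return The upper-tail p-value.
#' @export
hypergeometric_test <- function(N, k, n, x) {
  for (v in c(N = N, k = k, n = n, x = x)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v)) {
      stopf("N, k, n, x must be single non-negative integers")
    }
  }
  if (k > N || n > N) stopf("k and n must not exceed N")
  if (x > min(k, n)) stopf("x (%d) exceeds min(k, n) = %d", x, min(k, n))
  stats::phyper(x - 1, m = k, n = N - k, k = n, lower.tail = FALSE)
}

#' Gene-set enrichment of network interactors
#'
#' For each set in the collection: the population `N` is the universe (all
#' genes annotated in at least one set, by default); successes in the
#' population `k` are the network's interactors within `N`; the sample `n`
#' is the set within `N`; the observed successes `x` are the overlap. In
#' conditional mode the population is further restricted to the network's
#' interactors and non-interactors — an expression-matched background that
#' accounts for what the assay detects. `compare = "noninteractors"` runs
#' the companion global analysis for the non-interactor list. Bonferroni
#' adjustment uses the number of sets actually tested.
#'
#' @param network A `ppi_network` (or a list with `interactors` and
#'   `noninteractors` character vectors).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param mode `"global"` or `"conditional"`.
#' @param universe Population gene universe; defaults to the union of the
#'   collection.
#' @param compare Which list to test: `"interactors"` (default) or
#'   `"noninteractors"` (global mode only).
#' @param alpha Nominal significance level before adjustment (default 0.05).
#' @return data.frame with one row per set: `set`, `N`, `k`, `n`, `x`, `p`,
#'   `p_bonferroni`, `mode`, `tier` (`"none"`, `"nominal"`, `"bonferroni"`).
#'   Sets whose restricted population is empty are recorded with `NA` p.
#' @export
geneset_enrichment <- function(network, collection,
                               mode = c("global", "conditional"),
                               universe = NULL,
                               compare = c("interactors", "noninteractors"),
                               alpha = 0.05) {
  mode <- match.arg(mode)
  compare <- match.arg(compare)
  if (!length(collection)) stopf("empty gene-set collection")
  if (compare == "noninteractors" && mode == "conditional") {
    stopf("the non-interactor companion analysis is defined for global mode")
  }
  if (is.null(universe)) universe <- unique(unlist(collection))
  interactors <- network$interactors
  noninteractors <- network$noninteractors
  target <- if (compare == "interactors") interactors else noninteractors
  pop <- unique(universe)
  if (mode == "conditional") {
    pop <- intersect(pop, union(interactors, noninteractors))
  }
  m <- length(collection)
  rows <- lapply(names(collection), function(nm) {
    set <- unique(collection[[nm]])
    Nv <- pop
    kg <- intersect(target, Nv)
    ng <- intersect(set, Nv)
    xg <- intersect(kg, ng)
    if (!length(Nv)) {
      return(data.frame(set = nm, N = 0L, k = 0L, n = 0L, x = 0L,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(set = nm, N = length(Nv), k = length(kg), n = length(ng),
               x = length(xg),
               p = hypergeometric_test(length(Nv), length(kg), length(ng),
                                       length(xg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * m)
  out$mode <- mode
  out$compare <- compare
  out$tier <- ifelse(is.na(out$p), "none",
                     ifelse(out$p < alpha / m, "bonferroni",
                            ifelse(out$p < alpha, "nominal", "none")))
  out[order(out$p), , drop = FALSE]
}

#' Wilcoxon rank-sum test
#'
#' Two-sample location comparison. Uses exact enumeration when both samples
#' are small (`min(n_a, n_b) <= 8`) and tie-free, and the normal
#' approximation with tie and continuity corrections otherwise. When every
#' value in both samples is identical the comparison is vacuous: returns
#' p = 1 with a warning.
#'
#' @param sample_a,sample_b Numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `statistic` (W), `p_value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(sample_a) || !length(sample_b)) {
    stopf("both samples must be non-empty")
  }
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1L) {
    warnf("all values identical across both samples; p = 1")
    return(list(statistic = NA_real_, p_value = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- min(length(sample_a), length(sample_b)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "normal_approximation")
}
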