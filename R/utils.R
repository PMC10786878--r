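# Internal helpers: seeding, validation, small numerics.

#' Derive a reproducible sub-seed from a top-level seed
#'
#' A single pipeline seed deterministically spawns independent substreams for
#' each named component, so partial reruns of one stage reproduce exactly.
#'
#' @param seed Integer top-level seed.
#' @param label Character label of the component (e.g. `"impute"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stopf("'%s' must be a single integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE,
                        hi_open = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    x < lo || x > hi || (lo_open && x == lo) || (hi_open && x == hi)
  if (bad) stopf("'%s' must be in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]")
  invisible(x)
}

# Newton inversion of trigamma, as used by the empirical-Bayes moment
# estimator (cf. Smyth 2004).  Solves trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Canonical unordered gene pair: alphabetical within row.
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
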