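# Upper-level over-representation statistics: contingency construction,
# one-sided Fisher exact (hypergeometric) tail, the jackknifed variant,
# the gene-enrichment value, and Benjamini-Hochberg FDR control.

#' Contingency counts for one term
#'
#' The quadruple every enrichment statistic consumes: `list_hits` (k, the
#' list genes annotated to the term), `list_size` (n, the list genes with
#' any annotation in the category), `pop_hits` (K, the background genes
#' annotated to the term), and `pop_size` (N, the annotated background).
#' Invariants enforced: `k <= min(n, K)`, `n <= N`, `K <= N`,
#' `k >= max(0, n + K - N)`.
#'
#' @param list_hits,list_size,pop_hits,pop_size Non-negative integers
#'   (`list_size`, `pop_hits`, `pop_size` must be positive).
#' @return An object of class `contingency_counts`.
#' @export
#' @examples
#' contingency(27, 277, 104, 1534)
contingency <- function(list_hits, list_size, pop_hits, pop_size) {
  v <- c(list_hits, list_size, pop_hits, pop_size)
  if (length(v) != 4L || anyNA(v) || any(v != round(v))) {
    stop("contingency counts must be four integers")
  }
  k <- as.integer(list_hits); n <- as.integer(list_size)
  K <- as.integer(pop_hits);  N <- as.integer(pop_size)
  if (n < 1L || K < 1L || N < 1L) stop("list_size, pop_hits, pop_size must be positive")
  if (k < 0L) stop("list_hits must be non-negative")
  if (n > N) stop("list_size exceeds pop_size")
  if (K > N) stop("pop_hits exceeds pop_size")
  if (k > min(n, K)) stop("list_hits exceeds min(list_size, pop_hits)")
  if (k < n + K - N) stop("list_hits below the hypergeometric support minimum")
  structure(list(list_hits = k, list_size = n, pop_hits = K, pop_size = N),
            class = "contingency_counts")
}

#' @export
print.contingency_counts <- function(x, ...) {
  cat(sprintf("contingency: list %d/%d, population %d/%d\n",
              x$list_hits, x$list_size, x$pop_hits, x$pop_size))
  invisible(x)
}

#' Build contingency counts for a term
#'
#' Intersects the gene list with the category background and the term's
#' gene set. List genes with no annotation in the category are excluded
#' from both the list size and the test.
#'
#' @param genes A [gene_list()] or character vector.
#' @param term Term accession present in `universe`.
#' @param universe An [annotation_universe()].
#' @return A [contingency()] object.
#' @export
build_contingency <- function(genes, term, universe) {
  stopifnot(inherits(universe, "annotation_universe"))
  if (!term %in% names(universe$term_to_genes)) {
    stop(sprintf("unknown term '%s' in category '%s'", term, universe$category))
  }
  g <- .as_genes(genes)
  in_bg <- intersect(g, universe$background)
  if (length(in_bg) == 0L) {
    stop("gene list has no overlap with the annotated background; nothing testable")
  }
  tset <- universe$term_to_genes[[term]]
  contingency(length(intersect(in_bg, tset)), length(in_bg),
              length(tset), length(universe$background))
}

# Vectorised upper tail P(X >= k); underflow clamped to the smallest
# positive double so downstream logs stay finite.
.fisher_tail <- function(k, n, K, N) {
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  under <- p <= 0
  if (any(under)) {
    message("fisher_upper_tail: p-value underflow clamped to smallest positive double")
    p[under] <- .Machine$double.xmin
  }
  pmin(p, 1)
}

#' One-sided Fisher exact p-value (hypergeometric upper tail)
#'
#' Returns `P(X >= list_hits)` for `X` hypergeometric with population
#' `pop_size`, `pop_hits` successes and `list_size` draws -- the exact
#' one-sided Fisher p-value for over-representation. Computed by exact
#' summation (via [stats::phyper()]), never a normal approximation.
#' Underflow is clamped to the smallest positive double with a message,
#' so p-values are never reported as zero.
#'
#' @param counts A [contingency()] object.
#' @return A probability in (0, 1\].
#' @export
#' @examples
#' fisher_upper_tail(contingency(3, 122, 3, 735))  # 4.5e-3 at 2 s.f.
fisher_upper_tail <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  .fisher_tail(counts$list_hits, counts$list_size, counts$pop_hits, counts$pop_size)
}

#' Jackknifed (EASE-score) variant of the Fisher upper tail
#'
#' The conservative variant of the one-sided Fisher test that removes one
#' list hit before computing the tail: `P(X >= max(list_hits - 1, 0))`.
#' Always at least as large as [fisher_upper_tail()] on the same counts.
#'
#' @param counts A [contingency()] object.
#' @return A probability in (0, 1\].
#' @export
ease_score <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  .fisher_tail(max(counts$list_hits - 1L, 0L), counts$list_size,
               counts$pop_hits, counts$pop_size)
}

#' Gene-enrichment value
#'
#' Observed list hits minus the hits expected from background
#' proportions: `list_hits - list_size * pop_hits / pop_size`. Reported
#' to two decimal places in rendered tables.
#'
#' @param counts A [contingency()] object.
#' @return A real number (positive when the term is over-represented).
#' @export
#' @examples
#' gene_enrich(contingency(27, 277, 104, 1534))  # 8.22
gene_enrich <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  counts$list_hits - counts$list_size * counts$pop_hits / counts$pop_size
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotone enforcement (via
#' [stats::p.adjust()]). Output order matches input order; every
#' adjusted value is at least its raw value and at most 1.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Upper-level over-representation analysis
#'
#' Tests every term reaching `min_hits` list hits in every supplied
#' category with the one-sided Fisher exact test (or its jackknifed
#' variant), applies Benjamini-Hochberg correction within each category's
#' family of tested terms (or globally), and flags terms whose corrected
#' p-value is at most `alpha` as over-represented.
#'
#' @param genes A [gene_list()] or character vector.
#' @param universes An [annotation_universe()] or (named) list of them.
#' @param min_hits Minimum list hits for a term to be tested (default 2:
#'   singleton hits are uninformative).
#' @param alpha Corrected-p threshold defining the over-represented set.
#' @param score `"fisher"` (default, the canonical reported p-value) or
#'   `"ease"` for the jackknifed variant; the chosen score feeds the
#'   correction and the `enriched` flag.
#' @param family `"per-category"` (default) corrects within each
#'   category's tested terms; `"global"` pools all categories into one
#'   family.
#' @return A `data.frame` (class `ease_result`) with one row per tested
#'   term: `category`, `term`, `term_name`, `list_hits`, `list_size`,
#'   `pop_hits`, `pop_size`, `fisher_p`, `ease_p`, `corrected_p`,
#'   `gene_enrich`, `enriched`; sorted by `corrected_p` then the raw
#'   score. Attributes record `alpha`, `score` and `family`.
#' @export
run_ease <- function(genes, universes, min_hits = 2, alpha = 0.05,
                     score = c("fisher", "ease"),
                     family = c("per-category", "global")) {
  score <- match.arg(score)
  family <- match.arg(family)
  stopifnot(min_hits >= 1, alpha > 0, alpha <= 1)
  if (inherits(universes, "annotation_universe")) universes <- list(universes)
  if (length(universes) == 0L) stop("at least one annotation universe is required")
  g <- .as_genes(genes)

  per_cat <- lapply(universes, function(u) {
    stopifnot(inherits(u, "annotation_universe"))
    in_bg <- intersect(g, u$background)
    if (length(in_bg) == 0L) {
      warning(sprintf("gene list has no overlap with category '%s'; skipped",
                      u$category))
      return(NULL)
    }
    k <- vapply(u$term_to_genes, function(s) length(intersect(in_bg, s)), 0L)
    keep <- k >= min_hits
    if (!any(keep)) return(NULL)
    K <- lengths(u$term_to_genes)[keep]
    kk <- k[keep]
    n <- length(in_bg)
    N <- length(u$background)
    data.frame(
      category    = u$category,
      term        = names(u$term_to_genes)[keep],
      term_name   = unname(u$term_names[names(u$term_to_genes)[keep]]),
      list_hits   = unname(kk),
      list_size   = n,
      pop_hits    = unname(K),
      pop_size    = N,
      fisher_p    = .fisher_tail(kk, n, K, N),
      ease_p      = .fisher_tail(pmax(kk - 1L, 0L), n, K, N),
      gene_enrich = unname(kk - n * K / N),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  res <- do.call(rbind, per_cat)
  if (is.null(res) || nrow(res) == 0L) {
    warning(sprintf("no term reaches min_hits = %d; empty result", min_hits))
    res <- data.frame(category = character(), term = character(),
                      term_name = character(), list_hits = integer(),
                      list_size = integer(), pop_hits = integer(),
                      pop_size = integer(), fisher_p = numeric(),
                      ease_p = numeric(), corrected_p = numeric(),
                      gene_enrich = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE)
    return(.as_ease_result(res, alpha, score, family))
  }
  raw <- if (score == "fisher") res$fisher_p else res$ease_p
  res$corrected_p <- if (family == "global") {
    bh_adjust(raw)
  } else {
    stats::ave(raw, res$category, FUN = bh_adjust)
  }
  res$enriched <- res$corrected_p <= alpha
  res <- res[order(res$corrected_p, raw), , drop = FALSE]
  res <- res[, c("category", "term", "term_name", "list_hits", "list_size",
                 "pop_hits", "pop_size", "fisher_p", "ease_p", "corrected_p",
                 "gene_enrich", "enriched")]
  rownames(res) <- NULL
  .as_ease_result(res, alpha, score, family)
}

.as_ease_result <- function(res, alpha, score, family) {
  attr(res, "alpha") <- alpha
  attr(res, "score") <- score
  attr(res, "family") <- family
  class(res) <- c("ease_result", "data.frame")
  res
}
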