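# Nested (sub-level) over-representation analysis: each enriched
# upper-level term's annotated genes become the population, the list is
# restricted to its genes, and all other terms are re-tested inside that
# conditional background.

#' Restrict an annotation universe to a parent term's genes
#'
#' The returned universe's background is the parent term's full gene set
#' (its genome-level population hits become the nested population size);
#' every other term's gene set is intersected with it, terms with an
#' empty intersection are dropped, and the parent itself is excluded from
#' the returned term collection. Restricting an already-restricted
#' universe to the same parent is a no-op.
#'
#' @param universe An [annotation_universe()].
#' @param parent Term accession present in `universe`, or -- for
#'   cross-category nesting -- any accession provided `parent_genes` is
#'   given.
#' @param parent_genes Optional character vector of the parent's genes;
#'   defaults to the parent's gene set within `universe`.
#' @return An `annotation_universe` whose background is the parent gene
#'   set, carrying attribute `restricted_to = parent`.
#' @export
restrict_background <- function(universe, parent, parent_genes = NULL) {
  stopifnot(inherits(universe, "annotation_universe"))
  if (identical(attr(universe, "restricted_to"), parent)) {
    return(universe)
  }
  if (is.null(parent_genes)) {
    if (!parent %in% names(universe$term_to_genes)) {
      stop(sprintf("unknown parent term '%s' in category '%s'",
                   parent, universe$category))
    }
    parent_genes <- universe$term_to_genes[[parent]]
  }
  parent_genes <- unique(as.character(parent_genes))
  if (length(parent_genes) == 0L) stop("parent gene set is empty")
  sets <- universe$term_to_genes
  sets <- sets[names(sets) != parent]
  sets <- lapply(sets, intersect, y = parent_genes)
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) {
    stop(sprintf("no term overlaps the genes of parent '%s'", parent))
  }
  out <- annotation_universe(sets,
                             category = universe$category,
                             term_names = universe$term_names,
                             background = parent_genes)
  attr(out, "restricted_to") <- parent
  out
}

#' Percent gene enrichment
#'
#' The gene-enrichment value expressed as a percentage of the term's
#' population hits: `100 * gene_enrich(counts) / pop_hits`. Reported to
#' two decimal places in rendered tables; never exceeds 100.
#'
#' @param counts A [contingency()] object.
#' @return A real number (percent).
#' @export
#' @examples
#' pct_gene_enrich(contingency(3, 49, 4, 227))  # 53.41
pct_gene_enrich <- function(counts) {
  stopifnot(inherits(counts, "contingency_counts"))
  100 * gene_enrich(counts) / counts$pop_hits
}

#' Log10 difference between nested and unrestricted p-values
#'
#' `|log10(parent_level_p) - log10(nested_p)|`, where `parent_level_p` is
#' the same nested term's Fisher p-value computed against the full
#' (unrestricted) category background. This is a candidate interpretation
#' of the published column and is flagged as such wherever it is
#' rendered.
#'
#' @param nested_p,parent_level_p Probabilities in (0, 1\].
#' @return Non-negative real.
#' @export
pvalue_log_diff <- function(nested_p, parent_level_p) {
  stopifnot(all(nested_p > 0 & nested_p <= 1),
            all(parent_level_p > 0 & parent_level_p <= 1))
  abs(log10(parent_level_p) - log10(nested_p))
}

#' Nested over-representation analysis
#'
#' For every over-represented upper-level term (the "parents":
#' `enriched == TRUE` rows of the [run_ease()] result), the parent's gene
#' set becomes the population, the gene list is restricted to genes
#' annotated to the parent, and every other term -- from any category,
#' not only ontology descendants -- overlapping the parent is re-tested
#' with the one-sided Fisher exact test. Candidate terms need at least
#' `min_hits` within-parent list hits. Benjamini-Hochberg correction is
#' applied across the full nested family (all parent/nested pairs in the
#' run) or per parent.
#'
#' Each row carries the within-parent contingency (whose `list_size`
#' equals the parent's genome-level list hits and whose `pop_size` equals
#' the parent's genome-level population hits), the nested Fisher p-value
#' and its BH correction, the gene-enrichment value and its percent form,
#' and two candidate-interpretation statistics: `pvalue_log_diff`
#' (see [pvalue_log_diff()]) and `nease_gene_enrich` (the nested
#' gene-enrichment scaled by the parent's enrichment relative to its
#' expected hits) -- both flagged non-canonical in rendered output.
#'
#' @param ease_results A [run_ease()] result; its `enriched` rows feed
#'   the nested pass.
#' @param genes The same gene list passed to [run_ease()].
#' @param universes The same universe or list of universes.
#' @param min_hits Minimum within-parent list hits (default 2).
#' @param alpha Corrected-p threshold selecting reported rows.
#' @param family `"global"` (default) corrects across all nested tests in
#'   the run; `"per-parent"` corrects within each parent's family.
#' @param descendants_only If `TRUE`, only is-a descendants of the parent
#'   (per `obo`) are candidate nested terms.
#' @param obo Result of [read_obo()]; required when
#'   `descendants_only = TRUE`.
#' @return A `data.frame` (class `nease_result`) sorted by parent then
#'   nested `fisher_p`, with columns `parent_term`, `parent_name`,
#'   `parent_category`, `nested_term`, `nested_name`, `nested_category`,
#'   `list_hits`, `list_size`, `pop_hits`, `pop_size`, `fisher_p`,
#'   `corrected_p`, `gene_enrich`, `pct_gene_enrich`, `pvalue_log_diff`,
#'   `nease_gene_enrich`, `selected` (`corrected_p <= alpha`).
#' @export
run_nease <- function(ease_results, genes, universes, min_hits = 2,
                      alpha = 0.05, family = c("global", "per-parent"),
                      descendants_only = FALSE, obo = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(ease_results, "ease_result"), min_hits >= 1,
            alpha > 0, alpha <= 1)
  if (descendants_only && is.null(obo)) {
    stop("descendants_only = TRUE requires an 'obo' ontology")
  }
  if (inherits(universes, "annotation_universe")) universes <- list(universes)
  names(universes) <- vapply(universes, `[[`, "", "category")
  g <- .as_genes(genes)
  parents <- ease_results[ease_results$enriched, , drop = FALSE]
  if (nrow(parents) == 0L) {
    warning("no enriched upper-level terms; nothing to nest")
    return(.empty_nease(alpha, family))
  }

  # Full-background Fisher p for any (category, term): memoised per category.
  full_env <- new.env(parent = emptyenv())
  full_p <- function(cat, term) {
    key <- paste0(cat, "\r", term)
    if (!is.null(full_env[[key]])) return(full_env[[key]])
    u <- universes[[cat]]
    in_bg <- intersect(g, u$background)
    tset <- u$term_to_genes[[term]]
    p <- .fisher_tail(length(intersect(in_bg, tset)), length(in_bg),
                      length(tset), length(u$background))
    full_env[[key]] <- p
    p
  }

  rows <- list()
  for (i in seq_len(nrow(parents))) {
    pr <- parents[i, ]
    pu <- universes[[pr$category]]
    if (is.null(pu)) {
      stop(sprintf("universe for category '%s' not supplied", pr$category))
    }
    parent_set <- pu$term_to_genes[[pr$term]]
    within_list <- intersect(g, parent_set)
    if (length(within_list) < max(min_hits, 1L)) {
      message(sprintf("parent '%s': within-parent list too small; skipped", pr$term))
      next
    }
    allowed <- NULL
    if (descendants_only) allowed <- obo_descendants(obo, pr$term)
    parent_rows <- list()
    for (cat in names(universes)) {
      u <- universes[[cat]]
      cand <- names(u$term_to_genes)
      cand <- cand[!(cat == pr$category & cand == pr$term)]
      if (!is.null(allowed)) cand <- intersect(cand, allowed)
      if (length(cand) == 0L) next
      k <- vapply(u$term_to_genes[cand],
                  function(s) length(intersect(within_list, s)), 0L)
      keep <- k >= min_hits
      if (!any(keep)) next
      cand <- cand[keep]
      K <- vapply(u$term_to_genes[cand],
                  function(s) length(intersect(parent_set, s)), 0L)
      kk <- k[keep]
      n <- length(within_list)
      N <- length(parent_set)
      ge <- kk - n * K / N
      parent_expected <- pr$list_size * pr$pop_hits / pr$pop_size
      flp <- vapply(cand, function(t) full_p(cat, t), 0)
      fp <- .fisher_tail(kk, n, K, N)
      parent_rows[[cat]] <- data.frame(
        parent_term       = pr$term,
        parent_name       = pr$term_name,
        parent_category   = pr$category,
        nested_term       = cand,
        nested_name       = unname(u$term_names[cand]),
        nested_category   = cat,
        list_hits         = unname(kk),
        list_size         = n,
        pop_hits          = unname(K),
        pop_size          = N,
        fisher_p          = unname(fp),
        gene_enrich       = unname(ge),
        pct_gene_enrich   = unname(100 * ge / K),
        pvalue_log_diff   = unname(pvalue_log_diff(fp, flp)),
        nease_gene_enrich = unname(ge * (pr$gene_enrich / parent_expected)),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
    if (length(parent_rows) == 0L) {
      message(sprintf("parent '%s': no testable nested terms; skipped", pr$term))
      next
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, parent_rows)
  }
  if (length(rows) == 0L) {
    warning("no nested tests performed")
    return(.empty_nease(alpha, family))
  }
  res <- do.call(rbind, rows)
  res$corrected_p <- if (family == "global") {
    bh_adjust(res$fisher_p)
  } else {
    stats::ave(res$fisher_p, res$parent_term, FUN = bh_adjust)
  }
  res$selected <- res$corrected_p <= alpha
  res <- res[order(match(res$parent_term, parents$term), res$fisher_p), ,
             drop = FALSE]
  res <- res[, c("parent_term", "parent_name", "parent_category",
                 "nested_term", "nested_name", "nested_category",
                 "list_hits", "list_size", "pop_hits", "pop_size",
                 "fisher_p", "corrected_p", "gene_enrich",
                 "pct_gene_enrich", "pvalue_log_diff", "nease_gene_enrich",
                 "selected")]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "family") <- family
  class(res) <- c("nease_result", "data.frame")
  res
}

.empty_nease <- function(alpha, family) {
  res <- data.frame(parent_term = character(), parent_name = character(),
                    parent_category = character(), nested_term = character(),
                    nested_name = character(), nested_category = character(),
                    list_hits = integer(), list_size = integer(),
                    pop_hits = integer(), pop_size = integer(),
                    fisher_p = numeric(), corrected_p = numeric(),
                    gene_enrich = numeric(), pct_gene_enrich = numeric(),
                    pvalue_log_diff = numeric(), nease_gene_enrich = numeric(),
                    selected = logical(), stringsAsFactors = FALSE)
  attr(res, "alpha") <- alpha
  attr(res, "family") <- family
  class(res) <- c("nease_result", "data.frame")
  res
}
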