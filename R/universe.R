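# Annotation universe: the gene <-> term incidence structure for one
# annotation category, plus the category background (every gene carrying
# at least one annotation in the category).

#' Construct an annotation universe
#'
#' An annotation universe holds, for a single annotation category (for
#' example "GO Biological Process"), the mapping from each term to its
#' annotated genes, the inverse gene-to-term mapping, and the category
#' background: the set of genes with at least one annotation. The size of
#' the background is the population size ("Pop Size") used by every
#' enrichment test in that category, and the size of a term's gene set is
#' its population hits ("Pop Hits").
#'
#' @param term_to_genes Named list; each element is a character vector of
#'   gene identifiers annotated to that term. Duplicate identifiers within
#'   a term are collapsed; terms left with no genes are dropped.
#' @param category Single string labelling the annotation category.
#' @param term_names Optional named character vector mapping term
#'   accessions to human-readable names. Accessions without an entry fall
#'   back to the accession itself.
#' @param background Optional character vector of background genes. Must
#'   be a superset of the union of all term gene sets; defaults to exactly
#'   that union. A larger background arises when a universe is restricted
#'   to a parent term whose genes are not all covered by the remaining
#'   terms (see [restrict_background()]).
#'
#' @return An object of class `annotation_universe`: a list with elements
#'   `category`, `term_to_genes`, `gene_to_terms`, `background`,
#'   `term_names`.
#' @seealso [read_annotations()], [restrict_background()]
#' @export
#' @examples
#' u <- annotation_universe(list(A = c("g1", "g2", "g3"), B = c("g3", "g4")))
#' u$background
annotation_universe <- function(term_to_genes,
                                category = "gene sets",
                                term_names = NULL,
                                background = NULL) {
  if (!is.list(term_to_genes) || is.null(names(term_to_genes)) ||
      anyNA(names(term_to_genes)) || any(names(term_to_genes) == "")) {
    stop("'term_to_genes' must be a named list of gene identifier vectors")
  }
  if (anyDuplicated(names(term_to_genes))) {
    stop("duplicated term accessions in 'term_to_genes'")
  }
  term_to_genes <- lapply(term_to_genes, function(g) unique(as.character(g)))
  term_to_genes <- term_to_genes[lengths(term_to_genes) > 0L]
  if (length(term_to_genes) == 0L) {
    stop("empty universe: no term has at least one annotated gene")
  }
  union_bg <- sort(unique(unlist(term_to_genes, use.names = FALSE)))
  if (is.null(background)) {
    background <- union_bg
  } else {
    background <- sort(unique(as.character(background)))
    if (!all(union_bg %in% background)) {
      stop("'background' must contain every gene annotated to some term")
    }
  }
  nm <- stats::setNames(names(term_to_genes), names(term_to_genes))
  if (!is.null(term_names)) {
    hit <- intersect(names(term_to_genes), names(term_names))
    nm[hit] <- as.character(term_names[hit])
  }
  structure(
    list(category      = as.character(category)[1],
         term_to_genes = term_to_genes,
         gene_to_terms = .invert_incidence(term_to_genes),
         background    = background,
         term_names    = nm),
    class = "annotation_universe"
  )
}

.invert_incidence <- function(term_to_genes) {
  term <- rep(names(term_to_genes), lengths(term_to_genes))
  gene <- unlist(term_to_genes, use.names = FALSE)
  split(term, gene)
}

#' @export
print.annotation_universe <- function(x, ...) {
  cat(sprintf("annotation_universe: %s\n", x$category))
  cat(sprintf("  %d terms, %d background genes\n",
              length(x$term_to_genes), length(x$background)))
  sz <- lengths(x$term_to_genes)
  cat(sprintf("  term sizes: %d-%d (median %g)\n",
              min(sz), max(sz), stats::median(sz)))
  invisible(x)
}

#' Number of background genes (population size) of a universe
#' @param universe An `annotation_universe`.
#' @return Integer population size.
#' @export
pop_size <- function(universe) {
  stopifnot(inherits(universe, "annotation_universe"))
  length(universe$background)
}

#' Per-term gene counts (population hits) of a universe
#' @param universe An `annotation_universe`.
#' @return Named integer vector of term sizes.
#' @export
pop_hits <- function(universe) {
  stopifnot(inherits(universe, "annotation_universe"))
  lengths(universe$term_to_genes)
}

#' Construct a gene list
#'
#' An ordered, duplicate-free list of gene identifiers, as produced by
#' [read_gene_list()] or [derive_signature()]. Order of first appearance
#' is preserved.
#'
#' @param genes Character vector of gene identifiers.
#' @param source_label Free-text provenance label.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(genes, source_label = "") {
  genes <- as.character(genes)
  genes <- genes[!is.na(genes) & nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L) stop("gene list is empty after cleaning")
  structure(list(genes = genes, source_label = as.character(source_label)[1]),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list (%d identifiers)", length(x$genes)))
  if (nzchar(x$source_label)) cat(sprintf(" from %s", x$source_label))
  cat("\n  ", paste(utils::head(x$genes, 8), collapse = ", "))
  if (length(x$genes) > 8) cat(", ...")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$genes)

# Accept either a gene_list or a bare character vector everywhere.
.as_genes <- function(genes) {
  if (inherits(genes, "gene_list")) return(genes$genes)
  g <- unique(as.character(genes))
  if (length(g) == 0L) stop("empty gene list")
  g
}
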