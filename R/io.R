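# Readers and writers for annotation sources (GAF 2.x, GMT, two-column
# TSV), OBO term metadata, plain gene lists, probeset maps, and
# differential-expression tables.

.gaf_aspects <- c(P = "GO Biological Process",
                  F = "GO Molecular Function",
                  C = "GO Cellular Component")

.read_lines_nometa <- function(path, comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  keep <- !startsWith(ln, comment) & nzchar(trimws(ln))
  stats::setNames(ln[keep], which(keep))  # names = original line numbers
}

#' Read a gene-to-term annotation source
#'
#' Parses one of three annotation dialects into an
#' [annotation_universe()]:
#' \describe{
#'   \item{`gmt`}{Gene-set matrix: `term<TAB>description<TAB>gene...`, one
#'     term per line.}
#'   \item{`tsv2col`}{Two columns `gene<TAB>term`, one association per
#'     line.}
#'   \item{`gaf`}{GO Annotation File 2.x: tab-separated, `!` comment
#'     lines; column 2 is the gene (DB Object ID), column 5 the term
#'     accession, column 9 the aspect (P/F/C). Lines whose qualifier
#'     (column 4) contains `NOT` are skipped.}
#' }
#' Genes with no annotation never enter the background: the background is
#' the union of all term gene sets in the category.
#'
#' @param path Path to the annotation file.
#' @param format One of `"gmt"`, `"gaf"`, `"tsv2col"` (alias `"tsv"`).
#' @param category_filter For GAF input, which aspect to keep: `"P"`,
#'   `"F"` or `"C"` (or the corresponding full category label). `NULL`
#'   returns a named list of universes, one per aspect present. For GMT
#'   and TSV input the value, if given, is used as the category label.
#' @param fold_case If `TRUE`, gene identifiers are normalised to upper
#'   case before comparison (identifier matching is case-sensitive by
#'   default).
#'
#' @return An `annotation_universe`, or for GAF input without a
#'   `category_filter`, a named list of them (one per aspect).
#' @export
read_annotations <- function(path,
                             format = c("gmt", "gaf", "tsv2col", "tsv"),
                             category_filter = NULL,
                             fold_case = FALSE) {
  format <- match.arg(format)
  if (format == "tsv") format <- "tsv2col"
  switch(format,
         gmt     = .read_gmt(path, category_filter, fold_case),
         tsv2col = .read_tsv2col(path, category_filter, fold_case),
         gaf     = .read_gaf(path, category_filter, fold_case))
}

.maybe_fold <- function(genes, fold_case) {
  if (fold_case) toupper(genes) else genes
}

.read_gmt <- function(path, category_filter, fold_case) {
  ln <- .read_lines_nometa(path)
  fields <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %s in %s: expected term<TAB>description<TAB>gene...",
                 names(ln)[bad[1]], path))
  }
  terms <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) .maybe_fold(f[-(1:2)], fold_case))
  names(sets) <- terms
  if (anyDuplicated(terms)) {  # merge repeated stanzas for the same term
    sets <- tapply(sets, terms, function(s) unique(unlist(s)), simplify = FALSE)
    sets <- sets[unique(terms)]
    descs <- descs[!duplicated(terms)]
  }
  annotation_universe(sets,
                      category = if (is.null(category_filter)) "gene sets" else category_filter,
                      term_names = stats::setNames(descs, unique(terms)))
}

.read_tsv2col <- function(path, category_filter, fold_case) {
  ln <- .read_lines_nometa(path)
  fields <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %s in %s: expected gene<TAB>term",
                 names(ln)[bad[1]], path))
  }
  gene <- .maybe_fold(vapply(fields, `[[`, "", 1L), fold_case)
  term <- vapply(fields, `[[`, "", 2L)
  annotation_universe(split(gene, term),
                      category = if (is.null(category_filter)) "gene sets" else category_filter)
}

.read_gaf <- function(path, category_filter, fold_case) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  keep <- !startsWith(ln, "!") & nzchar(trimws(ln))
  lineno <- which(keep)
  fields <- strsplit(ln[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad)) {
    stop(sprintf("malformed GAF line %d in %s: fewer than 9 columns",
                 lineno[bad[1]], path))
  }
  gene   <- .maybe_fold(vapply(fields, `[[`, "", 2L), fold_case)
  qual   <- vapply(fields, `[[`, "", 4L)
  term   <- vapply(fields, `[[`, "", 5L)
  aspect <- vapply(fields, `[[`, "", 9L)
  drop <- grepl("\\bNOT\\b", qual)
  gene <- gene[!drop]; term <- term[!drop]; aspect <- aspect[!drop]
  unknown <- setdiff(unique(aspect), names(.gaf_aspects))
  if (length(unknown)) {
    stop("unknown GAF aspect(s): ", paste(unknown, collapse = ", "))
  }
  one_aspect <- function(a) {
    sel <- aspect == a
    if (!any(sel)) return(NULL)
    annotation_universe(split(gene[sel], term[sel]),
                        category = .gaf_aspects[[a]])
  }
  if (!is.null(category_filter)) {
    a <- category_filter
    if (a %in% .gaf_aspects) a <- names(.gaf_aspects)[match(a, .gaf_aspects)]
    if (!a %in% names(.gaf_aspects)) {
      stop("category_filter must be one of P, F, C (or a full aspect label)")
    }
    u <- one_aspect(a)
    if (is.null(u)) {
      stop(sprintf("no annotations with aspect '%s' in %s", a, path))
    }
    return(u)
  }
  out <- Filter(Negate(is.null), lapply(names(.gaf_aspects), one_aspect))
  if (length(out) == 0L) stop("no usable annotation lines in ", path)
  stats::setNames(out, vapply(out, `[[`, "", "category"))
}

#' Write an annotation universe to a GMT file
#'
#' @param universe An `annotation_universe`.
#' @param path Output path.
#' @param metadata Optional character vector written as leading `#`
#'   comment lines (skipped by [read_annotations()]).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(universe, path, metadata = NULL) {
  stopifnot(inherits(universe, "annotation_universe"))
  body <- vapply(names(universe$term_to_genes), function(t) {
    paste(c(t, universe$term_names[[t]], universe$term_to_genes[[t]]),
          collapse = "\t")
  }, "")
  head <- if (is.null(metadata)) character() else paste0("# ", metadata)
  writeLines(c(head, body), path)
  invisible(path)
}

#' Read a probeset-to-gene mapping
#'
#' Two-column TSV `probeset<TAB>gene`. Later duplicates of a probeset are
#' ignored.
#'
#' @param path Path to the mapping file.
#' @return Named character vector mapping probeset to gene identifier.
#' @export
read_probeset_map <- function(path) {
  ln <- .read_lines_nometa(path)
  fields <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %s in %s: expected probeset<TAB>gene",
                 names(ln)[bad[1]], path))
  }
  probe <- vapply(fields, `[[`, "", 1L)
  gene  <- vapply(fields, `[[`, "", 2L)
  keep <- !duplicated(probe)
  stats::setNames(gene[keep], probe[keep])
}

#' Read a gene list, optionally translating probesets to genes
#'
#' Reads one identifier per line (blank and `#` lines skipped). When a
#' probeset map is supplied, identifiers are translated through it;
#' probesets without a mapping are dropped with a message reporting the
#' count. Duplicates -- including several probesets collapsing onto one
#' gene -- are removed, keeping the order of first appearance.
#'
#' @param path Path to the list file.
#' @param probeset_map Optional named character vector (see
#'   [read_probeset_map()]).
#' @param fold_case If `TRUE`, identifiers are upper-cased.
#' @return A [gene_list()].
#' @export
read_gene_list <- function(path, probeset_map = NULL, fold_case = FALSE) {
  ln <- trimws(.read_lines_nometa(path))
  if (length(ln) == 0L) stop("gene list file is empty: ", path)
  ids <- .maybe_fold(ln, fold_case)
  if (!is.null(probeset_map)) {
    mapped <- probeset_map[ids]
    n_unmapped <- sum(is.na(mapped))
    if (n_unmapped > 0L) {
      message(sprintf("read_gene_list: %d unmapped probeset(s) dropped", n_unmapped))
    }
    ids <- .maybe_fold(unname(mapped[!is.na(mapped)]), fold_case)
    if (length(ids) == 0L) stop("no identifiers survive probeset mapping: ", path)
  }
  gene_list(ids, source_label = path)
}

#' Read a differential-expression result table
#'
#' Tab-separated with a header naming (in any order, case-insensitively)
#' the columns `feature_id` (or `id`/`probeset`/`gene`), `score`,
#' `q_value` (or `qvalue`/`q`), and `fold_change` (or `fc`). Such tables
#' are produced by differential-expression procedures at the summary
#' level (for example SAM output with q-values and signed fold changes);
#' this package consumes them, it does not compute them.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `feature_id`, `score`, `q_value`,
#'   `fold_change`, validated so q-values lie in \[0,1\] and fold changes
#'   are finite and non-zero.
#' @export
read_differential_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pick <- function(aliases) {
    i <- match(aliases, tolower(names(df)))
    i <- i[!is.na(i)]
    if (length(i) == 0L) {
      stop(sprintf("%s: missing column (one of: %s)", path,
                   paste(aliases, collapse = ", ")))
    }
    df[[i[1]]]
  }
  out <- data.frame(
    feature_id  = as.character(pick(c("feature_id", "id", "probeset", "gene"))),
    score       = as.numeric(pick("score")),
    q_value     = as.numeric(pick(c("q_value", "qvalue", "q"))),
    fold_change = as.numeric(pick(c("fold_change", "fc"))),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) stop("differential table is empty: ", path)
  if (anyNA(out$q_value) || any(out$q_value < 0 | out$q_value > 1)) {
    stop("q_value column must lie in [0, 1]")
  }
  if (anyNA(out$fold_change) || any(!is.finite(out$fold_change)) ||
      any(out$fold_change == 0)) {
    stop("fold_change column must be finite and non-zero")
  }
  out
}

#' Signature filter configuration
#'
#' Thresholds used by [derive_signature()] to reduce a differential table
#' to a gene signature: keep features with `q_value <= max_q` and
#' absolute fold change at least (or strictly above, with
#' `strict_inequality = TRUE`) `min_abs_fold_change`. Defaults follow a
#' common microarray-signature convention: q-value 0 and a two-fold
#' change, with the non-strict comparison.
#'
#' @param max_q Maximum q-value, in \[0,1\].
#' @param min_abs_fold_change Minimum absolute fold change, at least 1.
#' @param strict_inequality Use `>` instead of `>=` for the fold-change
#'   comparison.
#' @return An object of class `signature_filter`.
#' @export
signature_filter <- function(max_q = 0, min_abs_fold_change = 2,
                             strict_inequality = FALSE) {
  stopifnot(is.numeric(max_q), length(max_q) == 1L, max_q >= 0, max_q <= 1,
            is.numeric(min_abs_fold_change), length(min_abs_fold_change) == 1L,
            min_abs_fold_change >= 1,
            is.logical(strict_inequality), length(strict_inequality) == 1L)
  structure(list(max_q = max_q,
                 min_abs_fold_change = min_abs_fold_change,
                 strict_inequality = strict_inequality),
            class = "signature_filter")
}

#' Derive a gene signature from a differential table
#'
#' @param table A differential table (see [read_differential_table()]).
#' @param config A [signature_filter()].
#' @param probeset_map Optional probeset-to-gene map applied to the
#'   surviving feature identifiers, as in [read_gene_list()].
#' @param fold_case If `TRUE`, identifiers are upper-cased.
#' @return A [gene_list()] of the features passing both thresholds.
#' @export
derive_signature <- function(table, config = signature_filter(),
                             probeset_map = NULL, fold_case = FALSE) {
  stopifnot(inherits(config, "signature_filter"))
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("differential table is empty")
  }
  afc <- abs(table$fold_change)
  fc_ok <- if (config$strict_inequality) afc > config$min_abs_fold_change
           else afc >= config$min_abs_fold_change
  keep <- table$q_value <= config$max_q & fc_ok
  ids <- .maybe_fold(table$feature_id[keep], fold_case)
  if (length(ids) == 0L) {
    stop("no features pass the signature filter; consider relaxing max_q ",
         "or min_abs_fold_change")
  }
  if (!is.null(probeset_map)) {
    mapped <- probeset_map[ids]
    n_unmapped <- sum(is.na(mapped))
    if (n_unmapped > 0L) {
      message(sprintf("derive_signature: %d unmapped probeset(s) dropped", n_unmapped))
    }
    ids <- .maybe_fold(unname(mapped[!is.na(mapped)]), fold_case)
    if (length(ids) == 0L) stop("no identifiers survive probeset mapping")
  }
  gene_list(ids, source_label = "signature filter")
}

#' Read term names and relationships from an OBO file
#'
#' Minimal OBO 1.2/1.4 parser covering `[Term]` stanzas with `id`,
#' `name`, `namespace`, `is_a` and `is_obsolete` tags -- enough to attach
#' human-readable names to accessions and to walk the is-a hierarchy for
#' descendant-restricted nesting.
#'
#' @param path Path to the OBO file.
#' @return A list with `terms` (data.frame: `id`, `name`, `namespace`)
#'   and `parents` (named list: term id -> character vector of is-a
#'   parents).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  stanza_start <- c(which(grepl("^\\[", ln)), length(ln) + 1L)
  is_term <- ln[stanza_start[-length(stanza_start)]] == "[Term]"
  ids <- character(); nms <- character(); nss <- character()
  parents <- list()
  for (i in which(is_term)) {
    block <- ln[(stanza_start[i] + 1L):(stanza_start[i + 1L] - 1L)]
    tag <- function(t) sub(paste0("^", t, ":\\s*"), "",
                           block[startsWith(block, paste0(t, ":"))])
    if (length(tag("is_obsolete")) && any(tag("is_obsolete") == "true")) next
    id <- tag("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nm <- tag("name"); nms <- c(nms, if (length(nm)) nm[1] else id)
    ns <- tag("namespace"); nss <- c(nss, if (length(ns)) ns[1] else NA_character_)
    isa <- sub("\\s*!.*$", "", tag("is_a"))
    parents[[id]] <- trimws(isa)
  }
  if (length(ids) == 0L) stop("no [Term] stanzas found in ", path)
  list(terms = data.frame(id = ids, name = nms, namespace = nss,
                          stringsAsFactors = FALSE),
       parents = parents)
}

#' Descendants of a term in an OBO is-a hierarchy
#'
#' @param obo Result of [read_obo()].
#' @param term Term identifier.
#' @return Character vector of all is-a descendants (excluding `term`).
#' @export
obo_descendants <- function(obo, term) {
  children <- list()
  for (id in names(obo$parents)) {
    for (p in obo$parents[[id]]) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    kids <- setdiff(unique(unlist(children[frontier])), seen)
    seen <- c(seen, kids)
    frontier <- kids
  }
  setdiff(seen, term)
}

#' Attach OBO term names to a universe
#'
#' @param universe An `annotation_universe`.
#' @param obo Result of [read_obo()].
#' @return The universe with `term_names` updated where accessions match
#'   OBO ids (bare numeric accessions are also matched against
#'   `GO:`-prefixed ids).
#' @export
apply_obo_names <- function(universe, obo) {
  stopifnot(inherits(universe, "annotation_universe"))
  acc <- names(universe$term_to_genes)
  lookup <- stats::setNames(obo$terms$name, obo$terms$id)
  hit <- lookup[acc]
  miss <- is.na(hit)
  hit[miss] <- lookup[paste0("GO:", acc[miss])]
  universe$term_names[!is.na(hit)] <- hit[!is.na(hit)]
  universe
}

#' Write a gene list to a plain text file
#' @param genes A [gene_list()] or character vector.
#' @param path Output path.
#' @param metadata Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path, metadata = NULL) {
  head <- if (is.null(metadata)) character() else paste0("# ", metadata)
  writeLines(c(head, .as_genes(genes)), path)
  invisible(path)
}

#' Write a differential table to TSV
#' @param table Data frame with `feature_id`, `score`, `q_value`,
#'   `fold_change`.
#' @param path Output path.
#' @param metadata Optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(table, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) writeLines(paste0("# ", metadata), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
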