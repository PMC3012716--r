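# Seeded generators for annotation universes, gene lists with planted
# term enrichment, nested driver structure, and differential tables.
# These emulate the summary level the analysis consumes (annotations,
# signatures, q-values, fold changes), not expression matrices.

#' Specification for the synthetic-data generators
#'
#' Defaults emulate a modest microarray-scale study: a few thousand
#' annotated genes, overlapping term sets spanning two orders of
#' magnitude in size (as real GO categories do), and a differential list
#' of a few hundred genes. Terms are drawn independently, so overlap
#' between null terms is unconstrained, mirroring the overlapping
#' structure of real annotations rather than a partition.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_terms Number of terms; accessions are `T001`, `T002`, ...
#' @param term_size_range Integer pair: inclusive bounds on term sizes.
#' @param planted_terms Optional data.frame with columns `term` and
#'   `odds_ratio` (>= 1): gene-list sampling weights are multiplied by
#'   `odds_ratio` for genes in each planted term.
#' @param nested_plants Optional data.frame with columns `parent`,
#'   `child`, `odds_ratio` (>= 1): the child's gene set is guaranteed to
#'   overlap the parent's by at least `min(|child|, |parent|/2)`, and
#'   genes in the child-parent intersection get the extra within-parent
#'   sampling weight.
#' @param list_size Size of the generated gene list.
#' @param seed Single integer governing all sampling.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_terms = 100,
                           term_size_range = c(10, 200),
                           planted_terms = NULL, nested_plants = NULL,
                           list_size = 150, seed = 1L) {
  stopifnot(n_genes >= 1, n_terms >= 1, length(term_size_range) == 2L,
            term_size_range[1] >= 1,
            term_size_range[2] >= term_size_range[1],
            list_size >= 1, list_size <= n_genes,
            is.numeric(seed), length(seed) == 1L)
  if (term_size_range[2] > n_genes) {
    stop("term sizes may not exceed n_genes")
  }
  check_plants <- function(df, cols) {
    if (is.null(df)) return(NULL)
    stopifnot(is.data.frame(df), all(cols %in% names(df)))
    if (any(df$odds_ratio < 1)) stop("odds ratios must be >= 1")
    df
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_terms = as.integer(n_terms),
                 term_size_range = as.integer(term_size_range),
                 planted_terms = check_plants(planted_terms, c("term", "odds_ratio")),
                 nested_plants = check_plants(nested_plants,
                                              c("parent", "child", "odds_ratio")),
                 list_size = as.integer(list_size),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.spec_term_ids <- function(spec) sprintf("T%03d", seq_len(spec$n_terms))
.spec_gene_ids <- function(spec) sprintf("g%05d", seq_len(spec$n_genes))

# Tiny polynomial content hash (mod 2^31-1) for reproducibility metadata.
.spec_hash <- function(spec) {
  bytes <- utf8ToInt(paste(unlist(spec), collapse = "|"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.check_plant_terms <- function(spec) {
  ids <- .spec_term_ids(spec)
  ref <- c(spec$planted_terms$term, spec$nested_plants$parent,
           spec$nested_plants$child)
  bad <- setdiff(ref, ids)
  if (length(bad)) {
    stop("planted term(s) not among generated accessions: ",
         paste(bad, collapse = ", "))
  }
}

#' Generate a synthetic annotation universe
#'
#' Term gene sets are drawn uniformly at random with sizes uniform in
#' `term_size_range`; genes left uncovered are each added to one random
#' term, so every gene carries at least one annotation. For every nested
#' plant `(parent, child)`, the child set is rebuilt to overlap the
#' parent by at least `min(|child|, floor(|parent|/2))` genes.
#' Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An [annotation_universe()] (category `"synthetic"`), with
#'   attributes `seed` and `spec_hash`.
#' @export
make_universe <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .check_plant_terms(spec)
  set.seed(spec$seed)
  genes <- .spec_gene_ids(spec)
  terms <- .spec_term_ids(spec)
  sizes <- sample(seq(spec$term_size_range[1], spec$term_size_range[2]),
                  spec$n_terms, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- terms
  if (!is.null(spec$nested_plants)) {
    for (i in seq_len(nrow(spec$nested_plants))) {
      np <- spec$nested_plants[i, ]
      pset <- sets[[np$parent]]
      csize <- length(sets[[np$child]])
      m <- min(csize, floor(length(pset) / 2))
      inside <- sample(pset, m)
      outside <- sample(setdiff(genes, pset), csize - m)
      sets[[np$child]] <- c(inside, outside)
    }
  }
  # Host uncovered genes only in unplanted terms, so planted sets (and the
  # guaranteed parent-child overlaps) are exactly as constructed.
  plant_ids <- unique(c(spec$planted_terms$term, spec$nested_plants$parent,
                        spec$nested_plants$child))
  hosts_pool <- setdiff(terms, plant_ids)
  if (length(hosts_pool) == 0L) hosts_pool <- terms
  uncovered <- setdiff(genes, unlist(sets, use.names = FALSE))
  if (length(uncovered)) {
    host <- sample(hosts_pool, length(uncovered), replace = TRUE)
    for (j in seq_along(uncovered)) {
      sets[[host[j]]] <- c(sets[[host[j]]], uncovered[j])
    }
  }
  u <- annotation_universe(sets, category = "synthetic")
  attr(u, "seed") <- spec$seed
  attr(u, "spec_hash") <- .spec_hash(spec)
  u
}

# Per-gene sampling weights: product of odds ratios of planted terms
# containing the gene; nested plants weight the child-parent overlap.
.plant_weights <- function(universe, spec) {
  genes <- .spec_gene_ids(spec)
  w <- stats::setNames(rep(1, length(genes)), genes)
  if (!is.null(spec$planted_terms)) {
    for (i in seq_len(nrow(spec$planted_terms))) {
      pt <- spec$planted_terms[i, ]
      members <- universe$term_to_genes[[pt$term]]
      w[members] <- w[members] * pt$odds_ratio
    }
  }
  if (!is.null(spec$nested_plants)) {
    for (i in seq_len(nrow(spec$nested_plants))) {
      np <- spec$nested_plants[i, ]
      overlap <- intersect(universe$term_to_genes[[np$parent]],
                           universe$term_to_genes[[np$child]])
      w[overlap] <- w[overlap] * np$odds_ratio
    }
  }
  w
}

#' Generate a gene list with planted enrichment
#'
#' Samples `list_size` genes without replacement with per-gene weights
#' proportional to the product of the odds ratios of the planted terms
#' containing each gene (within-parent odds ratios act on the
#' child-parent overlap). With no plants the sampling is uniform.
#' Deterministic for a fixed seed (a sub-seed derived from `spec$seed`).
#'
#' @param universe The universe built from the same spec.
#' @param spec A [synthetic_spec()].
#' @return A [gene_list()] with attributes `seed`, `spec_hash`, and
#'   `truth`: a data.frame of per-planted-term ground-truth hit counts.
#' @export
make_gene_list <- function(universe, spec) {
  stopifnot(inherits(universe, "annotation_universe"),
            inherits(spec, "synthetic_spec"))
  if (spec$list_size > spec$n_genes) stop("list_size exceeds n_genes")
  set.seed(spec$seed + 1L)
  w <- .plant_weights(universe, spec)
  picked <- sample(names(w), spec$list_size, prob = w)
  gl <- gene_list(picked, source_label = sprintf("synthetic seed=%d", spec$seed))
  planted <- unique(c(spec$planted_terms$term, spec$nested_plants$child,
                      spec$nested_plants$parent))
  truth <- data.frame(term = character(), hits = integer(),
                      stringsAsFactors = FALSE)
  if (length(planted)) {
    truth <- data.frame(
      term = planted,
      hits = vapply(planted, function(t) {
        length(intersect(picked, universe$term_to_genes[[t]]))
      }, 0L),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  attr(gl, "seed") <- spec$seed
  attr(gl, "spec_hash") <- .spec_hash(spec)
  attr(gl, "truth") <- truth
  gl
}

#' Generate a differential-expression summary table
#'
#' Emulates the summary output of a differential-expression procedure:
#' one row per gene with a score, a q-value and a signed fold change.
#' The genes that [make_gene_list()] would select (same seed) are the
#' planted positives: they receive `q_value = 0` and an absolute fold
#' change drawn in `[boundary, boundary + 4]` with random sign. All
#' other genes receive a q-value in (0, 1\] and an absolute fold change
#' in `[1, boundary)`, so the default signature filter recovers exactly
#' the planted rows. Deterministic for a fixed seed.
#'
#' @param universe The universe built from the same spec.
#' @param spec A [synthetic_spec()].
#' @param boundary Fold-change boundary separating planted from null
#'   rows (default 2, straddling the conventional two-fold threshold).
#' @param planted If `FALSE`, generate an all-null table (no row passes
#'   the default filter).
#' @return A data.frame (`feature_id`, `score`, `q_value`,
#'   `fold_change`) with attributes `pass_count` (ground-truth number of
#'   rows passing the default filter), `seed` and `spec_hash`.
#' @export
make_differential_table <- function(universe, spec, boundary = 2,
                                    planted = TRUE) {
  stopifnot(inherits(universe, "annotation_universe"),
            inherits(spec, "synthetic_spec"), boundary > 1)
  positives <- if (planted) make_gene_list(universe, spec)$genes else character()
  set.seed(spec$seed + 2L)
  genes <- .spec_gene_ids(spec)
  is_pos <- genes %in% positives
  n_pos <- sum(is_pos)
  n_nul <- length(genes) - n_pos
  fc <- numeric(length(genes))
  qv <- numeric(length(genes))
  fc[is_pos] <- stats::runif(n_pos, boundary, boundary + 4) *
    sample(c(-1, 1), n_pos, replace = TRUE)
  qv[is_pos] <- 0
  eps <- 1e-6
  fc[!is_pos] <- stats::runif(n_nul, 1, boundary - eps) *
    sample(c(-1, 1), n_nul, replace = TRUE)
  qv[!is_pos] <- stats::runif(n_nul, eps, 1)
  out <- data.frame(feature_id = genes,
                    score = abs(fc) * (1 - qv),
                    q_value = qv,
                    fold_change = fc,
                    stringsAsFactors = FALSE)
  attr(out, "pass_count") <- n_pos
  attr(out, "seed") <- spec$seed
  attr(out, "spec_hash") <- .spec_hash(spec)
  out
}

#' Write a complete synthetic fixture set to a directory
#'
#' Writes `universe.gmt`, `genes.txt`, `de_table.tsv` and `truth.json`
#' (planted structure and ground-truth counts). All files carry `#`
#' metadata lines embedding the seed and spec hash; the readers skip
#' them.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("seed=%d spec_hash=%s", spec$seed, .spec_hash(spec))
  u <- make_universe(spec)
  gl <- make_gene_list(u, spec)
  dt <- make_differential_table(u, spec)
  paths <- c(universe = file.path(dir, "universe.gmt"),
             genes    = file.path(dir, "genes.txt"),
             de_table = file.path(dir, "de_table.tsv"),
             truth    = file.path(dir, "truth.json"))
  write_gmt(u, paths[["universe"]], metadata = meta)
  write_gene_list(gl, paths[["genes"]], metadata = meta)
  write_differential_table(dt, paths[["de_table"]], metadata = meta)
  truth <- list(seed = spec$seed,
                spec_hash = .spec_hash(spec),
                planted_terms = spec$planted_terms,
                nested_plants = spec$nested_plants,
                list_truth = attr(gl, "truth"),
                de_pass_count = attr(dt, "pass_count"))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
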