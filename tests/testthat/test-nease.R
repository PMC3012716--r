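# Background restriction and the nested analysis pass.

test_that("restriction intersects terms with the parent set", {
  u <- annotation_universe(list(P = paste0("g", 1:5),
                                T = paste0("g", 4:8),
                                U = paste0("g", 20:25)),
                           category = "toy")
  r <- restrict_background(u, "P")
  expect_setequal(r$background, paste0("g", 1:5))
  expect_equal(pop_size(r), 5L)
  expect_setequal(r$term_to_genes[["T"]], c("g4", "g5"))
  expect_false("P" %in% names(r$term_to_genes))   # parent excluded
  expect_false("U" %in% names(r$term_to_genes))   # empty intersection dropped
  expect_error(restrict_background(u, "missing"), "unknown parent")
})

test_that("restriction is idempotent and never grows term sets", {
  u <- random_universe(21)
  parent <- names(which.max(pop_hits(u)))
  r <- restrict_background(u, parent)
  expect_identical(restrict_background(r, parent), r)
  for (s in 1:5) {
    u <- random_universe(s)
    parent <- sample(names(u$term_to_genes), 1)
    r <- tryCatch(restrict_background(u, parent), error = function(e) NULL)
    if (is.null(r)) next
    expect_lte(sum(lengths(r$term_to_genes)), sum(lengths(u$term_to_genes)))
    for (t in names(r$term_to_genes)) {
      expect_true(all(r$term_to_genes[[t]] %in% u$term_to_genes[[t]]))
      expect_true(all(r$term_to_genes[[t]] %in% u$term_to_genes[[parent]]))
    }
  }
})

test_that("percent gene enrichment scales the enrichment by pop hits", {
  expect_equal(round(pct_gene_enrich(contingency(3, 49, 4, 227)), 2), 53.41)
  expect_equal(round(pct_gene_enrich(contingency(4, 655, 10, 4596)), 2), 25.75)
  expect_equal(pct_gene_enrich(contingency(5, 10, 50, 100)), 0)
  # by construction, never above 100
  for (s in 1:20) {
    set.seed(s)
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample_one(max(0, n + K - N):min(n, K))
    expect_lte(pct_gene_enrich(contingency(k, n, K, N)), 100)
  }
})

test_that("p-value log difference is the absolute log10 gap", {
  expect_equal(pvalue_log_diff(0.01, 0.01), 0)
  expect_equal(pvalue_log_diff(1e-3, 1e-5), 2)
  set.seed(5)
  a <- runif(20); b <- runif(20)
  expect_equal(pvalue_log_diff(a, b), abs(log10(b) - log10(a)))
})

test_that("nested rows inherit the parent's hits and pop hits as their frame", {
  spec <- synthetic_spec(n_genes = 800, n_terms = 30,
                         term_size_range = c(30, 80),
                         planted_terms = data.frame(term = c("T001", "T005"),
                                                    odds_ratio = c(6, 5)),
                         list_size = 150, seed = 7)
  u <- make_universe(spec)
  gl <- make_gene_list(u, spec)
  e <- run_ease(gl, u)
  n <- run_nease(e, gl, u, alpha = 1)
  expect_gt(nrow(n), 0)
  for (i in seq_len(nrow(n))) {
    pr <- e[e$term == n$parent_term[i], ]
    expect_equal(n$list_size[i], pr$list_hits)
    expect_equal(n$pop_size[i], pr$pop_hits)
  }
  # nested fisher_p equals the single shared code path on the same quadruple
  i <- which.min(n$fisher_p)
  expect_equal(n$fisher_p[i],
               fisher_upper_tail(contingency(n$list_hits[i], n$list_size[i],
                                             n$pop_hits[i], n$pop_size[i])))
  # within-parent list is the intersection of the list with the parent set
  expect_equal(n$list_size[i],
               length(intersect(gl$genes, u$term_to_genes[[n$parent_term[i]]])))
  # log-diff column recomputes from the two stored p-value routes
  full_cc <- build_contingency(gl, n$nested_term[i], u)
  expect_equal(n$pvalue_log_diff[i],
               pvalue_log_diff(n$fisher_p[i], fisher_upper_tail(full_cc)))
})

test_that("a planted within-parent driver is the top nested term", {
  spec <- synthetic_spec(n_genes = 1000, n_terms = 40,
                         term_size_range = c(40, 80),
                         planted_terms = data.frame(term = "T001", odds_ratio = 6),
                         nested_plants = data.frame(parent = "T001", child = "T002",
                                                    odds_ratio = 8),
                         list_size = 150, seed = 13)
  u <- make_universe(spec)
  gl <- make_gene_list(u, spec)
  e <- run_ease(gl, u)
  n <- run_nease(e, gl, u, alpha = 1)
  under_parent <- n[n$parent_term == "T001", ]
  expect_equal(under_parent$nested_term[1], "T002")
})

test_that("parents without testable nested terms are skipped with a note", {
  u <- annotation_universe(list(P = paste0("g", 1:6),
                                Q = paste0("g", 20:40)),
                           category = "toy")
  gl <- paste0("g", c(1:4, 20:29))
  e <- run_ease(gl, u, min_hits = 2, alpha = 1)
  expect_true(all(c("P", "Q") %in% e$term[e$enriched]))
  # P and Q are disjoint: no candidate overlaps either parent
  expect_warning(expect_message(n <- run_nease(e, gl, u, alpha = 1), "skipped"),
                 "no nested tests")
  expect_equal(nrow(n), 0L)
})

test_that("no enriched parents yields an empty nested result with a warning", {
  u <- toy_universe()
  e <- run_ease(paste0("g", c(1, 4, 9)), u, min_hits = 1, alpha = 1e-6)
  expect_warning(n <- run_nease(e, paste0("g", c(1, 4, 9)), u), "nothing to nest")
  expect_equal(nrow(n), 0L)
})

test_that("descendant-restricted nesting honours the ontology", {
  obo_file <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: P", "name: parent", "",
               "[Term]", "id: D", "name: child", "is_a: P", "",
               "[Term]", "id: X", "name: unrelated"), obo_file)
  obo <- read_obo(obo_file)
  u <- annotation_universe(list(P = paste0("g", 1:10),
                                D = paste0("g", 1:5),
                                X = paste0("g", 2:6)),
                           category = "toy")
  gl <- paste0("g", 1:6)
  e <- run_ease(gl, u, min_hits = 1, alpha = 1)
  all_terms <- run_nease(e[e$term == "P", ], gl, u, alpha = 1)
  expect_setequal(unique(all_terms$nested_term), c("D", "X"))
  desc_only <- run_nease(e[e$term == "P", ], gl, u, alpha = 1,
                         descendants_only = TRUE, obo = obo)
  expect_equal(unique(desc_only$nested_term), "D")
})

test_that("nested raw p-values are conservative under a null universe", {
  pv <- c()
  for (s in 1:8) {
    spec <- synthetic_spec(n_genes = 1500, n_terms = 40,
                           term_size_range = c(100, 250),
                           list_size = 250, seed = 500 + s)
    u <- make_universe(spec)
    gl <- make_gene_list(u, spec)
    e <- run_ease(gl, u, alpha = 1)
    e$enriched <- rank(-e$pop_hits, ties.method = "first") <= 3
    n <- run_nease(e, gl, u, alpha = 1)
    pv <- c(pv, n$fisher_p)
  }
  m <- length(pv)
  expect_gt(m, 300)
  frac <- mean(pv < 0.05)
  se <- sqrt(0.05 * 0.95 / m)
  # discrete Fisher tests are conservative: at or below the nominal level
  expect_lte(frac, 0.05 + 3 * se)
  # and stochastically no smaller than uniform (one-sided KS bound)
  ps <- sort(pv)
  dplus <- max(seq_len(m) / m - ps)
  expect_lte(dplus, 1.22 / sqrt(m))
})
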