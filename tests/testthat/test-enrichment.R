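# Contingency construction, Fisher upper tail, jackknifed variant,
# gene enrichment, BH adjustment, and the upper-level driver.

test_that("contingency construction enforces the hypergeometric invariants", {
  cc <- contingency(3, 122, 3, 735)
  expect_equal(cc$list_hits, 3L)
  expect_error(contingency(4, 3, 5, 10), "exceeds min")
  expect_error(contingency(0, 11, 5, 10), "exceeds pop_size")
  expect_error(contingency(0, 5, 11, 10), "exceeds pop_size")
  expect_error(contingency(0, 8, 8, 10), "support minimum")
  expect_error(contingency(1.5, 3, 5, 10), "integers")
})

test_that("contingency counts come from set intersections with the background", {
  u <- toy_universe()
  cc <- build_contingency(c("g1", "g2", "g3"), "A", u)
  expect_equal(unlist(cc, use.names = FALSE), c(3L, 3L, 5L, 10L))
  # unannotated identifiers are excluded from list size and hits
  cc2 <- build_contingency(c("g1", "g2", "g3", "zz1", "zz2"), "A", u)
  expect_equal(unlist(cc2, use.names = FALSE), c(3L, 3L, 5L, 10L))
  expect_error(build_contingency(c("g1"), "Z", u), "unknown term")
  expect_error(build_contingency(c("zz1"), "A", u), "no overlap")
})

test_that("contingency counts match a naive set oracle on random draws", {
  for (s in 1:25) {
    u <- random_universe(s)
    set.seed(1000 + s)
    gl <- sample(u$background, 12)
    term <- sample(names(u$term_to_genes), 1)
    cc <- build_contingency(gl, term, u)
    tset <- u$term_to_genes[[term]]
    expect_equal(cc$list_hits, sum(gl %in% tset))
    expect_equal(cc$list_size, sum(gl %in% u$background))
    expect_equal(cc$pop_hits, length(tset))
    expect_equal(cc$pop_size, length(u$background))
  }
})

test_that("the Fisher upper tail reproduces closed-form published counts", {
  # (3,122,3,735): P = (122*121*120)/(735*734*733)
  expect_equal(fisher_upper_tail(contingency(3, 122, 3, 735)),
               (122 * 121 * 120) / (735 * 734 * 733), tolerance = 1e-12)
  expect_equal(signif(fisher_upper_tail(contingency(3, 122, 3, 735)), 2), 4.5e-3)
  # (2,150,2,818): P = (150*149)/(818*817)
  expect_equal(fisher_upper_tail(contingency(2, 150, 2, 818)),
               (150 * 149) / (818 * 817), tolerance = 1e-12)
  expect_equal(signif(fisher_upper_tail(contingency(2, 150, 2, 818)), 2), 3.3e-2)
  # genome-scale rows
  expect_equal(signif(fisher_upper_tail(contingency(150, 1573, 818, 12439)), 2), 9.0e-7)
  expect_equal(signif(fisher_upper_tail(contingency(25, 1573, 82, 12439)), 2), 1.6e-5)
})

test_that("zero hits give p = 1 and the tail is monotone in list hits", {
  expect_equal(fisher_upper_tail(contingency(0, 10, 5, 100)), 1)
  ps <- vapply(0:5, function(k) fisher_upper_tail(contingency(k, 10, 5, 100)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("upper and lower tails are complementary", {
  cases <- list(c(3, 10, 5, 30), c(7, 20, 12, 45), c(1, 5, 2, 12))
  for (cs in cases) {
    up <- fisher_upper_tail(contingency(cs[1], cs[2], cs[3], cs[4]))
    lo <- phyper(cs[1] - 1, cs[3], cs[4] - cs[3], cs[2])
    expect_equal(up + lo, 1, tolerance = 1e-12)
  }
})

test_that("the jackknifed score removes one hit and never undercuts Fisher", {
  cc <- contingency(3, 122, 3, 735)
  # oracle: P(X >= 2) as a two-term pmf sum
  expect_equal(ease_score(cc), hyper_tail_oracle(2, 122, 3, 735),
               tolerance = 1e-12)
  expect_gt(ease_score(cc), fisher_upper_tail(cc))
  expect_equal(ease_score(contingency(0, 10, 5, 100)), 1)
  expect_equal(ease_score(contingency(1, 12, 4, 50)), 1)
  for (s in 1:20) {
    set.seed(s)
    N <- sample(20:200, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample_one(max(0, n + K - N):min(n, K))
    cc <- contingency(k, n, K, N)
    expect_gte(ease_score(cc), fisher_upper_tail(cc))
  }
})

test_that("gene enrichment is observed minus expected hits", {
  expect_equal(round(gene_enrich(contingency(27, 277, 104, 1534)), 2), 8.22)
  expect_equal(round(gene_enrich(contingency(24, 1451, 96, 10985)), 2), 11.32)
  # exact expectation -> 0
  expect_equal(gene_enrich(contingency(5, 10, 50, 100)), 0)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.034), 0.034)
  expect_equal(bh_adjust(rep(0.02, 7)), rep(0.02, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(3)
  p <- runif(40)^2
  adj <- bh_adjust(p)
  expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
  expect_true(all(adj >= p & adj <= 1))
  # permutation equivariance
  perm <- sample(length(p))
  expect_equal(bh_adjust(p[perm]), adj[perm])
})

test_that("the upper-level driver matches direct binomial-coefficient evaluation", {
  u <- annotation_universe(list(A = paste0("g", 1:5)), category = "toy",
                           background = paste0("g", 1:10))
  res <- run_ease(c("g1", "g2", "g3"), u, min_hits = 1, alpha = 1)
  expect_equal(nrow(res), 1L)
  expect_equal(res$fisher_p, choose(5, 3) * choose(5, 0) / choose(10, 3),
               tolerance = 1e-12)
  expect_equal(res$corrected_p, res$fisher_p)
})

test_that("alpha = 1 with min_hits = 1 reports every term touching the list", {
  u <- toy_universe()
  gl <- c("g1", "g5", "g9")
  res <- run_ease(gl, u, min_hits = 1, alpha = 1)
  touching <- sum(vapply(u$term_to_genes,
                         function(s) length(intersect(gl, s)) > 0, TRUE))
  expect_equal(nrow(res), touching)
  expect_true(all(res$enriched))
})

test_that("a planted high-odds term ranks first", {
  spec <- synthetic_spec(n_genes = 1000, n_terms = 50,
                         term_size_range = c(20, 60),
                         planted_terms = data.frame(term = "T001", odds_ratio = 10),
                         list_size = 100, seed = 99)
  u <- make_universe(spec)
  gl <- make_gene_list(u, spec)
  res <- run_ease(gl, u, alpha = 1)
  expect_equal(res$term[1], "T001")
})

test_that("no-term-reaches-min-hits yields an empty result with a warning", {
  u <- toy_universe()
  expect_warning(res <- run_ease("g9", u, min_hits = 2), "min_hits")
  expect_equal(nrow(res), 0L)
})

test_that("BH families are per-category by default and poolable globally", {
  u1 <- annotation_universe(list(A = paste0("g", 1:6), B = paste0("g", 4:9)),
                            category = "cat1")
  u2 <- annotation_universe(list(X = paste0("g", 1:3), Y = paste0("g", 2:9)),
                            category = "cat2")
  gl <- paste0("g", 1:4)
  per <- run_ease(gl, list(u1, u2), min_hits = 1, alpha = 1)
  glob <- run_ease(gl, list(u1, u2), min_hits = 1, alpha = 1, family = "global")
  for (cat in c("cat1", "cat2")) {
    sel <- per$category == cat
    expect_equal(per$corrected_p[sel], bh_oracle(per$fisher_p[sel]),
                 tolerance = 1e-12)
  }
  expect_equal(glob$corrected_p[order(glob$term)],
               bh_oracle(glob$fisher_p[order(glob$term)]),
               tolerance = 1e-12)
})
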