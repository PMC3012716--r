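# Independent oracles and tiny fixtures shared across the suite.

# Hypergeometric upper tail by direct summation of the pmf written in
# binomial coefficients -- independent of the phyper-based implementation.
hyper_tail_oracle <- function(k, n, K, N) {
  i <- max(k, 0, n + K - N):min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up worked from the definition:
# adjusted p_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Ten-gene toy universe: term A = g1..g5, term B = g4..g8, term C = g9..g10.
toy_universe <- function() {
  annotation_universe(
    list(A = paste0("g", 1:5),
         B = paste0("g", 4:8),
         C = paste0("g", 9:10)),
    category = "toy"
  )
}

# A 6-line GAF 2.2 fixture spanning aspects P and F, with one NOT line.
write_gaf_fixture <- function(path) {
  pad <- function(db, id, qual, go, aspect) {
    f <- rep("", 17)
    f[1] <- db; f[2] <- id; f[3] <- id; f[4] <- qual; f[5] <- go
    f[7] <- "IDA"; f[9] <- aspect; f[12] <- "protein"; f[13] <- "taxon:9606"
    paste(f, collapse = "\t")
  }
  writeLines(c(
    "!gaf-version: 2.2",
    pad("DB", "g1", "involved_in", "GO:0007049", "P"),
    pad("DB", "g2", "involved_in", "GO:0007049", "P"),
    pad("DB", "g3", "involved_in", "GO:0006915", "P"),
    pad("DB", "g1", "enables", "GO:0005515", "F"),
    pad("DB", "g4", "enables", "GO:0005515", "F"),
    pad("DB", "g5", "NOT|involved_in", "GO:0007049", "P")
  ), path)
  path
}

# Deterministic random universe for property checks.
random_universe <- function(seed, n_genes = 40, n_terms = 8, smin = 3, smax = 12) {
  set.seed(seed)
  genes <- sprintf("r%03d", seq_len(n_genes))
  sets <- lapply(seq_len(n_terms), function(i) {
    sample(genes, sample(smin:smax, 1))
  })
  names(sets) <- sprintf("RT%02d", seq_len(n_terms))
  annotation_universe(sets, category = "random")
}

# sample() treats a length-1 vector as 1:n; this picks uniformly from the
# elements of v regardless of its length.
sample_one <- function(v) v[sample.int(length(v), 1L)]
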