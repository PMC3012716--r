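# nease

Two-level gene ontology over-representation analysis for differential
gene lists, in R.

## The problem

Over-representation analysis (ORA) asks whether a list of interesting
genes — say, the genes differentially expressed after a gene knock-down —
contains more members of an annotated functional class than expected if
the list were drawn at random from the annotated background. A broad
upper-level hit such as *cell proliferation*, however, rarely explains
*why* the class lights up. The nested second pass implemented here
answers that: for each enriched term, its annotated genes become both the
population and the list restriction, and every other term is re-tested
inside that conditional background. Terms that remain significant within
the parent are the sub-classes that drive the parent's enrichment.

## The statistics

For a term with `k` list hits, an annotated list of size `n`, `K` term
genes in the background and an annotated background of size `N`, the
upper-level test is the one-sided Fisher exact p-value, i.e. the
hypergeometric upper tail

    p = P(X >= k),  X ~ Hypergeometric(N, K, n)

computed by exact summation. The conservative jackknifed variant
(`P(X >= k - 1)`, the "EASE score") is available behind a flag. Derived
statistics reported alongside:

* **gene enrichment** — observed minus expected hits, `k − nK/N`;
* **percent gene enrichment** — `100 · (k − nK/N) / K`;
* **p-value log difference** — `|log10 p_full − log10 p_nested|`, the
  gap between a term's nested and unrestricted p-values (a documented
  candidate interpretation, flagged in output headers).

P-values are corrected by the Benjamini–Hochberg step-up within each
category's family of tested terms (other family choices by flag). In the
nested pass the within-parent contingency of a candidate term `t` under
parent `P` is

    k = |list ∩ P ∩ t|,  n = |list ∩ P|,  K = |P ∩ t|,  N = |P|

so a nested row's list size equals the parent's list hits and its
population size equals the parent's population hits. Candidates come
from any category, not only ontology descendants of the parent
(a `descendants_only` mode restricts to is-a descendants).

## Worked example

Seeded synthetic data with a planted enriched term (`T001`, odds ratio
6) and a planted within-parent driver (`T002`, within-parent odds ratio
8):

```r
library(nease)

spec <- synthetic_spec(
  n_genes = 1000, n_terms = 40, term_size_range = c(40, 80),
  planted_terms = data.frame(term = "T001", odds_ratio = 6),
  nested_plants = data.frame(parent = "T001", child = "T002", odds_ratio = 8),
  list_size = 150, seed = 42)

u    <- make_universe(spec)
gl   <- make_gene_list(u, spec)
ease <- run_ease(gl, u)
head(as.data.frame(ease)[, c("term", "list_hits", "list_size", "pop_hits",
                             "pop_size", "fisher_p", "corrected_p", "enriched")], 3)
#>   term list_hits list_size pop_hits pop_size     fisher_p  corrected_p enriched
#> 1 T001        58       150       76     1000 4.963982e-37 1.985593e-35     TRUE
#> 2 T002        37       150       40     1000 3.449145e-29 6.898291e-28     TRUE
#> 3 T019        18       150       76     1000 2.518549e-02 2.905677e-01    FALSE
```

Of 150 sampled genes, 58 fall in `T001` against an expectation of
`150·76/1000 ≈ 11.4`; the planted term dominates. The nested pass then
asks what drives `T001`:

```r
nested <- run_nease(ease, gl, u)
head(as.data.frame(nested)[, c("parent_term", "nested_term", "list_hits",
     "list_size", "pop_hits", "pop_size", "fisher_p", "corrected_p", "selected")], 3)
#>   parent_term nested_term list_hits list_size pop_hits pop_size     fisher_p
#> 1        T001        T002        37        58       38       76 8.997295e-06
#> 2        T001        T014         4        58        4       76 3.306923e-01
#> 3        T001        T012         3        58        3       76 4.389189e-01
#>    corrected_p selected
#> 1 0.0004948512     TRUE
#> 2 0.9943319838    FALSE
#> 3 0.9943319838    FALSE
```

Inside `T001`'s 76 genes (now the population), 37 of the 58 in-parent
list genes fall in `T002` — the planted driver is the only nested term
surviving correction. Note the frame: the nested list size (58) is the
parent's list hits, and the nested population (76) is the parent's
population hits.

Single-row statistics work on bare contingency counts too:

```r
cc <- contingency(27, 277, 104, 1534)
format_pvalue(fisher_upper_tail(cc), glyph = TRUE)  # "2.4×10^−2"
round(gene_enrich(cc), 2)                           # 8.22
round(pct_gene_enrich(cc), 2)                       # 7.90
```

## Command line

A thin shim over the same functions, installed under
`inst/scripts/nease-cli.R`:

```sh
Rscript nease-cli.R synth --out fixtures --seed 7 --planted T001:8
Rscript nease-cli.R ease  --annotations fixtures/universe.gmt --format gmt \
    --genes fixtures/genes.txt --out results
Rscript nease-cli.R nease --annotations anno.gaf --format gaf --category P \
    --de-table sam_output.tsv --max-q 0 --min-fc 2 --out results
```

Every run writes a JSON manifest (inputs, thresholds, seed, version)
next to its result tables.

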