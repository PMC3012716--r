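---
title: "Nested over-representation analysis: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested over-representation analysis: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nease)
```

## The model

Over-representation analysis treats a differential gene list as a draw
without replacement from an annotated background. For a term with $K$
annotated genes in a background of $N$ annotated genes, and a list of
$n$ annotated genes of which $k$ carry the term, the number of hits
under the null is hypergeometric, and the one-sided Fisher exact
p-value for over-representation is the upper tail

$$p = P(X \ge k) = \sum_{i=k}^{\min(n,K)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

`fisher_upper_tail()` evaluates this by exact summation through
`stats::phyper()`; no normal approximation is used anywhere, and the
test suite cross-checks the implementation against an independent
binomial-coefficient summation oracle over the full valid lattice for
small populations.

Two details matter more than they look:

* **The background is per category.** Only genes with at least one
  annotation in a category count toward that category's population
  ($N$) or list size ($n$). A gene list is therefore trimmed
  differently in, say, a biological-process universe than in a
  molecular-function universe, and the same term can carry different
  list sizes across categories. This is why `annotation_universe`
  objects carry their own background and why universes are never merged.
* **Analysis is at the gene level.** Probeset-to-gene collapse happens
  at read time (`read_gene_list()`, `derive_signature()`); duplicates
  and many-probesets-one-gene collisions are removed before any
  counting, so hits are counted over distinct genes.

### The nested pass

An enriched broad term rarely explains itself. The nested pass
conditions on it: for each enriched parent $P$ the population becomes
$P$'s gene set, the list becomes the list genes inside $P$, and every
other term $t$ is re-tested with counts

$$k = |L \cap P \cap t|,\quad n = |L \cap P|,\quad
K = |P \cap t|,\quad N = |P|.$$

Structurally, every nested row's list size equals its parent's
upper-level list hits and its population size equals the parent's
upper-level population hits; the test suite asserts this invariant on
every generated analysis. The p-value is the same single code path as
the upper level applied to the restricted quadruple.

Candidate nested terms are *all* terms overlapping the parent, from any
category — not only ontology descendants. Conditional enrichment is a
statement about gene overlap, not about the is-a graph: a cell-adhesion
module can drive a cell-proliferation signal without either term being
an ancestor of the other. Users who want DAG-restricted nesting can set
`descendants_only = TRUE` with an OBO file. Exactly two levels are
computed; the conditioning argument iterates poorly (backgrounds shrink
quickly and the tests lose resolution), so no third level is offered.

### Derived statistics

* `gene_enrich` $= k - nK/N$: observed hits above expectation, in
  genes. Displayed to two decimals.
* `pct_gene_enrich` $= 100\,(k - nK/N)/K$: the same excess as a
  percentage of the term's population hits; bounded above by 100.
* `pvalue_log_diff` $= |\log_{10} p_{\text{full}} -
  \log_{10} p_{\text{nested}}|$, where $p_{\text{full}}$ is the nested
  term's p-value against the full category background. A large value
  means conditioning on the parent changed the term's standing
  dramatically.
* `nease_gene_enrich` $= (k - nK/N)\cdot
  \frac{\text{parent gene enrich}}{\text{parent expected hits}}$: the
  nested excess scaled by the parent's relative enrichment.

The last two are **candidate interpretations**: the verbal definitions
in circulation for these columns under-determine a formula, and no
printed value we are aware of pins one down. They are therefore flagged
with a `*` marker and a footnote in every rendered table, and no
correctness claim beyond the formulas above is attached to them. The
first two, by contrast, reproduce published reference values exactly at
printed precision (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `min_hits` | 2 | A single-gene hit cannot distinguish signal from annotation noise; requiring two follows long-standing ORA practice. Applies at both levels (within-parent hits for nesting). |
| `alpha` | 0.05 | Corrected-p threshold defining the over-represented set and the parents fed to the nested pass. |
| `score` | `"fisher"` | The plain upper tail is the canonical reported p-value; closed-form checks of published nested rows (e.g. counts (3, 122, 3, 735) giving $\frac{122\cdot121\cdot120}{735\cdot734\cdot733} \approx 4.5\times10^{-3}$) match it and exclude the jackknifed variant, which remains available as `score = "ease"`. |
| `family` | per-category (upper), global (nested) | Correction families follow the unit of interpretation: each category is read as its own table at the upper level; the nested pass is usually read as one joint table. Both poolable/splittable by flag. |
| Signature filter | `max_q = 0`, `min_abs_fold_change = 2`, non-strict | The conventional "q-value 0, two-fold" signature rule. Strict (`>`) and non-strict (`>=`) fold-change comparisons are both supported because published wording is frequently inconsistent between the two; non-strict is the default. |
| `fold_case` | off | Identifier comparison is case-sensitive by default; symbol-case conventions differ across sources, so folding is explicit, not silent. |
| True-path propagation | none | Annotations are counted as given. Whether an input should be propagated up the ontology before counting is a property of the annotation source, not of the test; propagate upstream if desired, or restrict nesting with `descendants_only`. |

Numerical choices: p-values are clamped to the smallest positive double
on underflow (with a message) so logs stay finite and no p-value is
ever reported as 0; rendered tables use two-significant-figure
scientific notation (ASCII `2.1e-09` by default, the typeset
`2.1×10^−9` dialect by flag) and two decimals for the derived
statistics; ties in sorting break by raw p-value. Degenerate inputs
(empty lists after background trimming, parents with no overlapping
candidates, filters that nothing survives) raise errors or logged skips
rather than returning silent empties, except where an empty result is a
legitimate outcome (no term reaching `min_hits`).

## The synthetic generators

`make_universe()`, `make_gene_list()` and `make_differential_table()`
provide the test substrate: seeded, deterministic, and carrying their
ground truth as attributes. The generator emulates:

* overlapping term sets (terms drawn independently, as real annotation
  categories overlap), sizes uniform within a configurable range, every
  gene annotated at least once;
* planted upper-level enrichment — list sampling weights multiplied by
  an odds ratio for genes in a planted term;
* planted nested drivers — a child term rebuilt to overlap its parent
  by at least `min(|child|, |parent|/2)`, with extra weight on the
  child–parent intersection, producing enrichment that is concentrated
  inside the parent;
* differential summary tables with q-values and signed fold changes
  straddling the two-fold boundary, with an exact recorded count of
  rows passing the default signature filter.

Default scale (2000 genes, 100 terms, sizes 10–200, list 150) is a
deliberately modest microarray-like setting; recovery and calibration
tests in the suite use 800–2000 genes, 30–50 terms and 100 seeded
replicates, sizes chosen so the full suite runs in about a minute.

What the generator does **not** emulate: correlated expression between
genes (annotation-driven co-regulation), the ontology's hierarchical
true-path structure, annotation bias toward well-studied genes, or the
probeset-level noise of a real array. Passing recovery tests therefore
show that the statistics find planted set-level structure under honest
nulls — not that the pipeline is robust to the dependence structure of
real transcriptomes.

## Calibration

Under a null generator (no plants), upper-level raw p-values are
stochastically no smaller than uniform: discrete exact tests are
conservative, and the suite checks this with a one-sided
Kolmogorov–Smirnov bound on the excess of the empirical CDF above the
diagonal. The same holds for nested p-values; the observed fraction of
nested tests below 0.05 sits slightly *under* the nominal level
(≈ 0.04 at the suite's problem sizes), which is why calibration is
asserted as conservative-vs-uniform rather than as a symmetric band
around 0.05 — a symmetric band is unattainable for discrete
hypergeometric support at these counts.

## Known limitations

* Gene-level independence is assumed by the Fisher test; co-expressed
  gene modules inflate significance in real data, as in all ORA tools.
* The nested family can be large (every enriched parent × every
  overlapping term); with many parents the global BH family is strict,
  and per-parent correction is offered but raises the multiplicity
  burden of interpretation instead.
* `pvalue_log_diff` and `nease_gene_enrich` are candidate
  interpretations (above) and should not be compared against published
  values of similarly named columns.
* OBO support covers `id`/`name`/`namespace`/`is_a` only — enough for
  names and descendant restriction, not for relationship types such as
  `part_of`.
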