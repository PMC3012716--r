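Package: nease
Title: Nested Gene Ontology Over-Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level gene ontology over-representation analysis of
    differential gene lists. The upper level tests each annotation term
    with the one-sided Fisher exact (hypergeometric) test against a
    per-category annotated background, with Benjamini-Hochberg false
    discovery rate control; the nested second level re-tests all terms
    against a background restricted to each enriched term's genes, to
    identify the sub-terms that drive upper-level enrichment. Includes
    readers for GAF, GMT, two-column TSV annotations and OBO term
    metadata, signature derivation from differential-expression tables,
    seeded synthetic-data generators with planted enrichment for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
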