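# Table rendering: two-significant-figure scientific notation for
# p-values (ASCII "2.1e-09" by default, the typeset "2.1x10^-9" glyph
# dialect on request), fixed two-decimal derived statistics, and the
# published table layouts.

#' Format p-values at two significant figures in scientific notation
#'
#' @param p Numeric vector of probabilities in (0, 1\].
#' @param glyph If `TRUE`, render the typeset dialect
#'   `"a.b×10^−c"` (multiplication sign, superscript-style
#'   exponent with a true minus); otherwise ASCII `"a.be-0c"`.
#' @return Character vector.
#' @export
#' @examples
#' format_pvalue(2.1e-9)                # "2.1e-09"
#' format_pvalue(2.1e-9, glyph = TRUE)  # "2.1×10^−9"
format_pvalue <- function(p, glyph = FALSE) {
  stopifnot(all(p > 0 & p <= 1))
  ex <- floor(log10(p))
  man <- p / 10^ex
  ms <- sprintf("%.1f", man)
  bump <- ms == "10.0"  # mantissa rounded up to the next decade
  ms[bump] <- "1.0"
  ex[bump] <- ex[bump] + 1L
  if (glyph) {
    es <- ifelse(ex < 0, paste0("−", -ex), as.character(ex))
    paste0(ms, "×", "10^", es)
  } else {
    sprintf("%se%+03d", ms, ex)
  }
}

#' Parse p-values rendered by [format_pvalue()]
#'
#' Accepts both the ASCII and the glyph dialect (including the published
#' markdown-style `"2.1×10^−9^"` with trailing caret).
#'
#' @param s Character vector.
#' @return Numeric vector.
#' @export
parse_pvalue <- function(s) {
  s <- gsub("−", "-", s)
  s <- gsub("×10\\^", "e", s)
  s <- gsub("\\^", "", s)
  as.numeric(s)
}

.fmt2 <- function(x) sprintf("%.2f", x)

.ease_header <- c("Accession Type", "Accession Number", "Accession Term",
                  "List Hits", "List Size", "Pop. Hits", "Pop. Size",
                  "Fisher's Exact", "Corrected P Value")

#' Write an upper-level result table
#'
#' Renders the canonical upper-level layout: Accession Type, Accession
#' Number, Accession Term, List Hits, List Size, Pop. Hits, Pop. Size,
#' Fisher's Exact, Corrected P Value. P-values are formatted at two
#' significant figures.
#'
#' @param results A [run_ease()] result (or subset of its rows).
#' @param path Output path.
#' @param glyph Use the typeset p-value dialect (see [format_pvalue()]).
#' @return `path`, invisibly.
#' @export
write_ease_table <- function(results, path, glyph = FALSE) {
  score <- attr(results, "score")
  raw <- if (identical(score, "ease")) results$ease_p else results$fisher_p
  body <- if (nrow(results) == 0L) character() else {
    paste(results$category, results$term, results$term_name,
          results$list_hits, results$list_size,
          results$pop_hits, results$pop_size,
          format_pvalue(raw, glyph), format_pvalue(results$corrected_p, glyph),
          sep = "\t")
  }
  writeLines(c(paste(.ease_header, collapse = "\t"), body), path)
  invisible(path)
}

.nease_header <- c("nEASE Term", "List Hits", "List Size", "Pop. Hits",
                   "Pop. Size", "Fisher's Exact", "Gene Enrich",
                   "nEASE pvalue Diff*", "nEASE Gene Enrich*",
                   "% Gene Enrich", "EASE Term")
.nease_footnote <- paste("# * candidate interpretation: the published",
                         "definitions of these two columns are",
                         "under-specified; values are computed from the",
                         "documented formulas in ?run_nease.")

#' Write a nested result table
#'
#' Renders the canonical nested layout: nEASE Term, List Hits, List
#' Size, Pop. Hits, Pop. Size, Fisher's Exact, Gene Enrich, nEASE pvalue
#' Diff, nEASE Gene Enrich, % Gene Enrich, EASE Term. The two
#' candidate-interpretation columns carry a `*` header marker explained
#' in a trailing `#` footnote line.
#'
#' @param results A [run_nease()] result (or subset of its rows).
#' @param path Output path.
#' @param glyph Use the typeset p-value dialect.
#' @return `path`, invisibly.
#' @export
write_nease_table <- function(results, path, glyph = FALSE) {
  body <- if (nrow(results) == 0L) character() else {
    paste(results$nested_name, results$list_hits, results$list_size,
          results$pop_hits, results$pop_size,
          format_pvalue(results$fisher_p, glyph),
          .fmt2(results$gene_enrich),
          .fmt2(results$pvalue_log_diff),
          .fmt2(results$nease_gene_enrich),
          .fmt2(results$pct_gene_enrich),
          results$parent_name,
          sep = "\t")
  }
  writeLines(c(paste(.nease_header, collapse = "\t"), body, .nease_footnote),
             path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, thresholds, package version and seed -- enough to
#' reproduce the run.
#'
#' @param path Output path (JSON).
#' @param config Named list of run parameters.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config) {
  manifest <- c(list(package = "nease",
                     version = as.character(utils::packageVersion("nease")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
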