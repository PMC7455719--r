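#' Audit configuration
#'
#' Collects every numeric knob of the audit pipeline in one list so that all
#' stages share a single, inspectable configuration. Defaults follow the
#' published audit protocol where one is stated (primer mismatch rate 0.2,
#' minimum primer overlap 10 nt, barcode length 4-30 nt, 1,000 sampled reads
#' per FASTQ file, automatic inclusion of accession ranges up to 40,
#' popular-optional metadata fields present in more than 25% of studies);
#' the remaining knobs are this package's own declared defaults.
#'
#' @param max_digits Maximum number of digits after an accession prefix.
#'   INSDC archives long ago outgrew six digits, so the extraction default is
#'   9; `strict_grammar = TRUE` restores the six-digit limit.
#' @param strict_grammar Logical; restrict accession digits to at most six
#'   and count read `N` bases as primer mismatches.
#' @param range_auto_threshold Accession ranges larger than this are expanded
#'   but flagged `needs_manual_check`.
#' @param range_cap Hard ceiling on range expansion size (memory guard).
#' @param n_reads Reads sampled per FASTQ file.
#' @param max_error_rate Primer mismatch rate; the mismatch budget for an
#'   alignment of overlap `w` is `floor(max_error_rate * w)`.
#' @param min_overlap Minimum primer/read overlap in bases.
#' @param barcode_len Length-2 integer vector, inclusive bounds on inferred
#'   barcode length.
#' @param primer_prevalence_threshold Fraction of sampled reads that must
#'   carry a primer for the study-level "primers present" flag.
#' @param optional_field_threshold Presence fraction above which a metadata
#'   field is classed "popular optional".
#' @param primers Tibble with columns `name`, `sequence` giving the
#'   degenerate primer pair searched for. Defaults to the 515F/806R pair in
#'   IUPAC-degenerate form.
#' @param lenient_strategy Logical; accept case variants of the library
#'   strategy token "AMPLICON" (off by default, the archive vocabulary is
#'   case-sensitive).
#' @return A list of class `audit_config`.
#' @export
#' @examples
#' cfg <- audit_config()
#' cfg$max_error_rate
#' audit_config(strict_grammar = TRUE)$max_digits
audit_config <- function(max_digits = 9L,
                         strict_grammar = FALSE,
                         range_auto_threshold = 40L,
                         range_cap = 10000L,
                         n_reads = 1000L,
                         max_error_rate = 0.2,
                         min_overlap = 10L,
                         barcode_len = c(4L, 30L),
                         primer_prevalence_threshold = 0.5,
                         optional_field_threshold = 0.25,
                         primers = default_primers(),
                         lenient_strategy = FALSE) {
  if (isTRUE(strict_grammar)) max_digits <- min(max_digits, 6L)
  stopifnot(
    max_digits >= 1L,
    range_auto_threshold >= 2L,
    range_cap >= range_auto_threshold,
    n_reads >= 1L,
    max_error_rate >= 0, max_error_rate < 1,
    min_overlap >= 1L,
    length(barcode_len) == 2L, barcode_len[1] >= 1L,
    barcode_len[2] >= barcode_len[1],
    primer_prevalence_threshold >= 0, primer_prevalence_threshold <= 1,
    optional_field_threshold > 0, optional_field_threshold < 1,
    is.data.frame(primers), all(c("name", "sequence") %in% names(primers))
  )
  structure(
    list(
      max_digits = as.integer(max_digits),
      strict_grammar = isTRUE(strict_grammar),
      range_auto_threshold = as.integer(range_auto_threshold),
      range_cap = as.integer(range_cap),
      n_reads = as.integer(n_reads),
      max_error_rate = max_error_rate,
      min_overlap = as.integer(min_overlap),
      barcode_len = as.integer(barcode_len),
      primer_prevalence_threshold = primer_prevalence_threshold,
      optional_field_threshold = optional_field_threshold,
      primers = tibble::as_tibble(primers),
      lenient_strategy = isTRUE(lenient_strategy)
    ),
    class = "audit_config"
  )
}

#' Default degenerate primer pair
#'
#' The 515F (Parada) / 806R (Apprill) primer pair targeting the V4 region of
#' the 16S rRNA gene, in IUPAC-degenerate form. Primer sequences are
#' configuration data, not constants: pass your own tibble to
#' [audit_config()] to audit a different amplicon.
#'
#' @return Tibble with columns `name`, `sequence`.
#' @export
#' @examples
#' default_primers()
default_primers <- function() {
  tibble::tibble(
    name = c("515F", "806R"),
    sequence = c("GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT")
  )
}

#' @export
print.audit_config <- function(x, ...) {
  cat("<audit_config>\n")
  for (nm in setdiff(names(x), "primers")) {
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  cat(sprintf(
    "  primers: %s\n",
    paste(sprintf("%s=%s", x$primers$name, x$primers$sequence), collapse = " ")
  ))
  invisible(x)
}
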