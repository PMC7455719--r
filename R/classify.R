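# Per-study fault ledger, fate classification, corpus summaries, and the
# chi-squared test for trend in proportions.

#' Fault flag names
#'
#' The per-study boolean fault flags, grouped into the four loss
#' categories: data location (`loc_*`), data deposition (`dep_*`), data
#' formatting (`fmt_*`) and data labeling (`lab_*`).
#'
#' @format Character vector of the eleven flag names.
#' @export
FAULT_FLAGS <- c(
  "loc_not_deposited", "loc_alternative_db",
  "dep_accession_not_found", "dep_data_private", "dep_metadata_private",
  "dep_placeholder_accession",
  "fmt_not_demultiplexed", "fmt_no_quality_scores", "fmt_primers_present",
  "lab_strategy_mislabeled", "lab_paired_mislabeled"
)

# Flags that make a study's data not available (availability faults
# dominate), versus flags that leave it partially usable.
AVAILABILITY_FLAGS <- c(
  "loc_not_deposited", "loc_alternative_db",
  "dep_accession_not_found", "dep_data_private", "dep_metadata_private",
  "dep_placeholder_accession",
  "fmt_not_demultiplexed", "fmt_no_quality_scores"
)
PARTIAL_FLAGS <- c(
  "fmt_primers_present", "lab_strategy_mislabeled", "lab_paired_mislabeled"
)

FATE_LEVELS <- c("reusable", "partially_usable", "not_available")

#' Assemble the per-study fault ledger
#'
#' Mechanically joins the three audit stages into one boolean fault flag
#' table per study; no judgment calls are made here. Inputs are keyed by
#' `study_id` and every study in `text` appears exactly once in the output;
#' `metadata` and `fastq` rows for unknown study ids raise an error.
#'
#' Flag derivation: a study with no well-formed accession and no
#' alternative-database mention is `loc_not_deposited`; with an
#' alternative-database mention only, `loc_alternative_db`; a
#' placeholder-only accession sets `dep_placeholder_accession`; an accession
#' absent from the repository sets `dep_accession_not_found`; resolvable but
#' non-public metadata sets `dep_metadata_private`; public metadata with
#' private sequence data sets `dep_data_private`. Formatting and labeling
#' flags are copied from the FASTQ and metadata audits for studies whose
#' data is public. Location and deposition faults force all downstream
#' flags to `FALSE` (there is nothing left to audit), preserving the ledger
#' invariant.
#'
#' @param text Per-study text-mining tibble: `study_id`, `has_insdc`,
#'   `has_placeholder`, `alt_db`, and optionally `year`.
#' @param metadata Per-study tibble from [audit_study_metadata()] plus a
#'   `study_id` column.
#' @param fastq Per-study tibble from [audit_fastq_manifest()]'s
#'   `per_study`, with a `study_id` column.
#' @return A `FaultLedger` tibble: `study_id`, `year`, and the eleven
#'   logical fault flags of [FAULT_FLAGS].
#' @export
assemble_fault_ledger <- function(text, metadata = NULL, fastq = NULL) {
  stopifnot(is.data.frame(text),
            all(c("study_id", "has_insdc", "has_placeholder", "alt_db")
                %in% names(text)))
  if (anyDuplicated(text$study_id)) {
    audit_abort("duplicate study_id in text input",
                class = "ampliaudit_duplicate_id")
  }
  check_ids <- function(tbl, nm) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      unknown <- setdiff(tbl$study_id, text$study_id)
      if (length(unknown) > 0) {
        audit_abort(
          sprintf("%s audit has study id(s) absent from text mining: %s",
                  nm, paste(unknown, collapse = ", ")),
          class = "ampliaudit_id_mismatch"
        )
      }
    }
  }
  check_ids(metadata, "metadata")
  check_ids(fastq, "fastq")

  ledger <- tibble::tibble(
    study_id = text$study_id,
    year = if ("year" %in% names(text)) text$year else NA_integer_
  )
  if (is.null(metadata)) metadata <- tibble::tibble(study_id = character())
  if (is.null(fastq)) fastq <- tibble::tibble(study_id = character())
  meta_cols <- c("accession_found", "data_public", "metadata_public",
                 "strategy_is_amplicon")
  for (col in setdiff(meta_cols, names(metadata))) metadata[[col]] <- NA
  fq_cols <- c("has_quality_fault", "primers_present",
               "paired_label_inconsistent", "single_file_multisample")
  for (col in setdiff(fq_cols, names(fastq))) fastq[[col]] <- NA

  ledger <- ledger |>
    dplyr::left_join(
      dplyr::select(text, "study_id", "has_insdc", "has_placeholder", "alt_db"),
      by = "study_id"
    ) |>
    dplyr::left_join(
      dplyr::select(metadata, "study_id", dplyr::all_of(meta_cols)),
      by = "study_id"
    ) |>
    dplyr::left_join(
      dplyr::select(fastq, "study_id", dplyr::all_of(fq_cols)),
      by = "study_id"
    )

  found <- dplyr::coalesce(ledger$accession_found, FALSE)
  meta_pub <- dplyr::coalesce(ledger$metadata_public, FALSE)
  data_pub <- dplyr::coalesce(ledger$data_public, FALSE)

  out <- tibble::tibble(
    study_id = ledger$study_id,
    year = ledger$year,
    loc_not_deposited = !ledger$has_insdc & !ledger$has_placeholder &
      !ledger$alt_db,
    loc_alternative_db = !ledger$has_insdc & !ledger$has_placeholder &
      ledger$alt_db,
    dep_placeholder_accession = !ledger$has_insdc & ledger$has_placeholder,
    dep_accession_not_found = ledger$has_insdc & !found,
    dep_metadata_private = ledger$has_insdc & found & !meta_pub,
    dep_data_private = ledger$has_insdc & found & meta_pub & !data_pub,
    fmt_not_demultiplexed = dplyr::coalesce(ledger$single_file_multisample, FALSE),
    fmt_no_quality_scores = dplyr::coalesce(ledger$has_quality_fault, FALSE),
    fmt_primers_present = dplyr::coalesce(ledger$primers_present, FALSE),
    lab_strategy_mislabeled = meta_pub &
      !dplyr::coalesce(ledger$strategy_is_amplicon, TRUE),
    lab_paired_mislabeled = dplyr::coalesce(ledger$paired_label_inconsistent,
                                            FALSE)
  )
  # availability faults upstream of the read audit leave nothing to audit
  upstream <- out$loc_not_deposited | out$loc_alternative_db |
    out$dep_placeholder_accession | out$dep_accession_not_found |
    out$dep_metadata_private | out$dep_data_private
  for (flag in c("fmt_not_demultiplexed", "fmt_no_quality_scores",
                 "fmt_primers_present", "lab_strategy_mislabeled",
                 "lab_paired_mislabeled")) {
    out[[flag]] <- out[[flag]] & !upstream
  }
  dplyr::relocate(out, "study_id", "year", dplyr::all_of(FAULT_FLAGS))
}

#' Classify the fate of each study
#'
#' Applies the exclusive classification policy: a study is `not_available`
#' when any availability fault is set (data not deposited, deposited only to
#' an alternative database, placeholder/unfindable accession, private data
#' or metadata, not demultiplexed, or lacking quality scores — faults that
#' preclude reuse); otherwise `partially_usable` when any obstacle-creating
#' fault is set (retained primers, library-strategy mislabeling,
#' paired-label mislabeling); otherwise `reusable`. Availability faults
#' dominate, and multiple faults within the partial tier count once, so the
#' three fates are exhaustive and exclusive.
#'
#' @param ledger A `FaultLedger` tibble from [assemble_fault_ledger()] (any
#'   tibble with the [FAULT_FLAGS] columns).
#' @return The ledger with a `fate` column appended (ordered factor
#'   `reusable < partially_usable < not_available`).
#' @export
#' @examples
#' ledger <- ledger_from_counts(10, c(fmt_primers_present = 3,
#'                                    loc_not_deposited = 2))
#' dplyr::count(classify_fate(ledger), fate)
classify_fate <- function(ledger) {
  stopifnot(is.data.frame(ledger), all(FAULT_FLAGS %in% names(ledger)))
  avail_fault <- Reduce(`|`, lapply(AVAILABILITY_FLAGS, function(f) ledger[[f]]))
  partial_fault <- Reduce(`|`, lapply(PARTIAL_FLAGS, function(f) ledger[[f]]))
  fate <- dplyr::case_when(
    avail_fault ~ "not_available",
    partial_fault ~ "partially_usable",
    TRUE ~ "reusable"
  )
  ledger$fate <- factor(fate, levels = FATE_LEVELS, ordered = TRUE)
  ledger
}

#' Summarize a classified corpus
#'
#' Counts and percentages per fault flag and per fate category. Percentages
#' are `100 * count / denominator`, half-up rounded to `digits` decimals;
#' the denominator defaults to the corpus size but can be supplied
#' explicitly (reported subsets are often quoted against a denominator
#' printed elsewhere). Rows with a zero denominator are omitted with a
#' warning.
#'
#' @param ledger A classified ledger (from [classify_fate()]; if the `fate`
#'   column is missing it is computed).
#' @param digits Reporting precision for percentages (default 1 decimal;
#'   use 0 to match whole-percent prints).
#' @param denominator Denominator for percentages (default `nrow(ledger)`).
#' @param by_year Logical; additionally stratify counts by `year`.
#' @return Tibble with columns `metric`, `count`, `denominator`, `percent`
#'   (plus `year` when `by_year`), class `audit_summary`.
#' @export
summarize_corpus <- function(ledger, digits = 1, denominator = nrow(ledger),
                             by_year = FALSE) {
  stopifnot(is.data.frame(ledger), nrow(ledger) > 0)
  if (!"fate" %in% names(ledger)) ledger <- classify_fate(ledger)
  if (denominator <= 0) {
    warning("zero denominator: summary rows omitted", call. = FALSE)
    return(structure(
      tibble::tibble(metric = character(), count = integer(),
                     denominator = integer(), percent = numeric()),
      class = c("audit_summary", "tbl_df", "tbl", "data.frame")
    ))
  }
  one_stratum <- function(df) {
    counts <- c(
      vapply(FAULT_FLAGS, function(f) sum(df[[f]]), integer(1)),
      table(factor(df$fate, levels = FATE_LEVELS))
    )
    tibble::tibble(
      metric = c(FAULT_FLAGS, paste0("fate_", FATE_LEVELS)),
      count = as.integer(counts)
    )
  }
  if (by_year) {
    out <- ledger |>
      dplyr::filter(!is.na(.data$year)) |>
      dplyr::group_by(.data$year) |>
      dplyr::group_modify(~ one_stratum(.x)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        denominator = as.integer(denominator),
        percent = percent_of(.data$count, denominator, digits)
      )
  } else {
    out <- one_stratum(ledger) |>
      dplyr::mutate(
        denominator = as.integer(denominator),
        percent = percent_of(.data$count, denominator, digits)
      )
  }
  structure(out, class = c("audit_summary", class(tibble::tibble())))
}

#' Chi-squared test for trend in proportions
#'
#' Score test for a monotone trend of binomial proportions across ordered
#' groups (df = 1). With pooled proportion `p = sum(x)/sum(n)` and group
#' scores `s`, the statistic is `T^2 / V` where
#' `T = sum(s*x) - p*sum(s*n)` and
#' `V = p*(1-p) * (sum(s^2*n) - sum(s*n)^2/sum(n))`; the p-value is the
#' upper tail of the chi-squared distribution with one degree of freedom.
#' No continuity correction is applied; for two groups the statistic equals
#' the Pearson chi-squared of the 2x2 table, and it is invariant under
#' affine transformation of the scores.
#'
#' @param x Successes per group.
#' @param n Totals per group (all `> 0`).
#' @param scores Group scores, default `1..k` (e.g. calendar years).
#' @return Object of class `audit_trend`: `chi2`, `df` (1), `p_value`,
#'   `scores`, `x`, `n`.
#' @export
#' @examples
#' chi2_trend(c(33, 172), c(56, 214))
#' chi2_trend(c(5, 10, 20), c(50, 50, 50), scores = c(2015, 2016, 2017))
chi2_trend <- function(x, n, scores = seq_along(x)) {
  stopifnot(length(x) >= 2, length(n) == length(x),
            length(scores) == length(x))
  stopifnot(all(x >= 0), all(n > 0), all(x <= n))
  p <- sum(x) / sum(n)
  if (p == 0 || p == 1) {
    audit_abort("degenerate proportions: pooled proportion is 0 or 1",
                class = "ampliaudit_degenerate")
  }
  s <- as.numeric(scores)
  T_stat <- sum(s * x) - p * sum(s * n)
  V <- p * (1 - p) * (sum(s^2 * n) - sum(s * n)^2 / sum(n))
  if (V <= 0) {
    audit_abort("zero score variance: scores must not be constant",
                class = "ampliaudit_degenerate"
    )
  }
  chi2 <- T_stat^2 / V
  structure(
    list(
      chi2 = chi2, df = 1L,
      p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
      scores = s, x = x, n = n,
      method = "Chi-squared test for trend in proportions"
    ),
    class = "audit_trend"
  )
}

#' @export
print.audit_trend <- function(x, ...) {
  cat(sprintf("%s\n  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$method, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Tidy a trend test
#'
#' @param x An `audit_trend` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `method`.
#' @exportS3Method generics::tidy
tidy.audit_trend <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p_value,
                 method = x$method)
}

#' Glance at a trend test
#'
#' @param x An `audit_trend` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `n_groups`,
#'   `n_total`.
#' @exportS3Method generics::glance
glance.audit_trend <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p_value,
                 n_groups = length(x$x), n_total = sum(x$n))
}

#' Per-year success/total counts for a fault flag or predicate
#'
#' Convenience aggregation feeding [chi2_trend()]: counts, per publication
#' year, the studies for which `flag` is `TRUE` and the year totals.
#' Studies without a year are excluded.
#'
#' @param ledger Ledger tibble with a `year` column.
#' @param flag Name of a logical column of `ledger`.
#' @return Tibble with columns `year`, `x`, `n` ordered by year.
#' @export
count_by_year <- function(ledger, flag) {
  stopifnot(is.data.frame(ledger), flag %in% names(ledger),
            "year" %in% names(ledger))
  ledger |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(x = sum(.data[[flag]]), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$year)
}
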