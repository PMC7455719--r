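# ggplot2 views of classified corpora and summaries.

#' Plot the fate distribution of a classified corpus
#'
#' Stacked single-bar view of the share of studies whose data is reusable,
#' partially usable, or not available.
#'
#' @param ledger A classified ledger (with a `fate` column, or one is
#'   computed).
#' @return A ggplot object.
#' @export
plot_fate_summary <- function(ledger) {
  if (!"fate" %in% names(ledger)) ledger <- classify_fate(ledger)
  counts <- dplyr::count(ledger, .data$fate, .drop = FALSE)
  counts$share <- counts$n / sum(counts$n)
  ggplot2::ggplot(
    counts,
    ggplot2::aes(x = "corpus", y = .data$share, fill = .data$fate)
  ) +
    ggplot2::geom_col(width = 0.5) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::scale_fill_manual(values = c(
      reusable = "#1b9e77", partially_usable = "#d8b365",
      not_available = "#b2182b"
    )) +
    ggplot2::labs(x = NULL, y = "share of studies", fill = "data fate",
                  title = "Fate of the audited sequencing data") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot fault-flag prevalences
#'
#' Horizontal bars of the percentage of studies carrying each fault flag,
#' grouped by loss category (location, deposition, formatting, labeling).
#'
#' @param summary An `audit_summary` from [summarize_corpus()].
#' @return A ggplot object.
#' @export
plot_flag_prevalence <- function(summary) {
  stopifnot(is.data.frame(summary))
  flags <- summary[summary$metric %in% FAULT_FLAGS, , drop = FALSE]
  flags$category <- factor(
    sub("_.*", "", flags$metric),
    levels = c("loc", "dep", "fmt", "lab"),
    labels = c("location", "deposition", "formatting", "labeling")
  )
  ggplot2::ggplot(
    flags,
    ggplot2::aes(x = stats::reorder(.data$metric, .data$percent),
                 y = .data$percent, fill = .data$category)
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of studies", fill = "loss category",
                  title = "Fault prevalence across the corpus") +
    ggplot2::theme_minimal()
}

#' Autoplot an audit summary
#'
#' @param object An `audit_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object (see [plot_flag_prevalence()]).
#' @exportS3Method ggplot2::autoplot
autoplot.audit_summary <- function(object, ...) plot_flag_prevalence(object)
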