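# Structured report output: flat CSV tables plus one JSON document with
# config echo and input digests for provenance.

#' Write audit reports
#'
#' Writes `summary.csv`, `trends.csv` (when any trend was computed) and
#' `report.json` under `out_dir`. The JSON document carries the summary and
#' trend tables, the fate counts, an echo of the configuration, the
#' classification policy (availability faults dominate; faults within the
#' partial tier count once), MD5 digests of the input files and the package
#' version. No timestamps are embedded, so reruns on identical inputs
#' produce byte-identical files.
#'
#' @param summary An `audit_summary` tibble from [summarize_corpus()].
#' @param trends Optional tibble of trend-test rows (e.g. columns `metric`,
#'   `statistic`, `df`, `p.value`).
#' @param out_dir Output directory (created if needed).
#' @param config The [audit_config()] used.
#' @param input_files Character vector of input file paths to digest.
#' @return Invisibly, the paths written.
#' @export
write_audit_report <- function(summary, trends = NULL, out_dir,
                               config = audit_config(),
                               input_files = character()) {
  stopifnot(is.data.frame(summary))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, "summary.csv")
  readr::write_csv(summary, paths[1])
  has_trends <- !is.null(trends) && nrow(trends) > 0
  if (has_trends) {
    trends_path <- file.path(out_dir, "trends.csv")
    readr::write_csv(trends, trends_path)
    paths <- c(paths, trends_path)
  }
  digests <- if (length(input_files) > 0) {
    files <- sort(input_files[file.exists(input_files)])
    as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  } else {
    NULL
  }
  cfg <- unclass(config)
  cfg$primers <- as.list(stats::setNames(config$primers$sequence,
                                         config$primers$name))
  doc <- list(
    tool = list(
      package = "ampliaudit",
      version = as.character(utils::packageVersion("ampliaudit"))
    ),
    classification_policy = paste(
      "availability faults dominate; multiple faults within the",
      "partially-usable tier count once"
    ),
    config = cfg,
    input_digests = digests,
    summary = summary
  )
  if (has_trends) doc$trends <- trends
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, json_path))
}
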