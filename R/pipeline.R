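# The end-to-end offline pipeline: mine -> resolve -> metadata -> fastq ->
# classify -> report, over a world directory of articles and repository
# fixtures.

#' Run the full audit pipeline over a world directory
#'
#' Expects the directory layout written by [generate_corpus()] (or any
#' real-world export matching it): `articles/` with `*.txt`/`*.xml` full
#' texts, `runs.tsv` (run-level metadata), `biosamples.tsv` (biosample
#' attributes), `manifest.tsv` (study/run/file manifest) and optionally
#' `articles.tsv` (`article_id`, `doi`, `year`). Executes, entirely
#' offline: article mining, accession validation and range resolution,
#' the repository metadata audit, the sampled-read FASTQ audit, fault
#' ledger assembly, fate classification, corpus summarization, per-year
#' trend tests for each fault flag, and (optionally) report writing.
#'
#' @param world_dir Input directory.
#' @param config An [audit_config()].
#' @param out_dir Optional report directory passed to
#'   [write_audit_report()].
#' @return List: `corpus` (mined rows), `resolved`, `text` (per-study
#'   mining summary), `metadata`, `fastq` (per-study read audit), `ledger`
#'   (classified fault ledger with `fate`), `summary`, `trends`,
#'   `informativeness` (per study/field metadata potential).
#' @export
run_audit_pipeline <- function(world_dir, config = audit_config(),
                               out_dir = NULL) {
  stopifnot(dir.exists(world_dir))
  articles_dir <- file.path(world_dir, "articles")
  runs_path <- file.path(world_dir, "runs.tsv")
  biosamples_path <- file.path(world_dir, "biosamples.tsv")
  manifest_path <- file.path(world_dir, "manifest.tsv")
  meta_path <- file.path(world_dir, "articles.tsv")

  corpus <- mine_articles(
    articles_dir, config,
    doi_map = if (file.exists(meta_path)) meta_path else NULL
  )
  resolved <- resolve_corpus(corpus, config)

  text <- resolved |>
    dplyr::group_by(study_id = .data$article_id) |>
    dplyr::summarise(
      has_insdc = any(.data$status %in% "well_formed"),
      has_placeholder = any(.data$status %in% "placeholder"),
      alt_db = any(.data$alt_mgrast | .data$alt_figshare | .data$alt_qiita),
      mentions_16s = any(.data$mentions_16s),
      primer_pair_515_806 = any(.data$primer_pair_515_806),
      year = if ("year" %in% names(resolved)) .data$year[1] else NA_integer_,
      .groups = "drop"
    )

  runs_tbl <- if (file.exists(runs_path)) read_run_table(runs_path) else
    tibble::tibble(
      run_accession = character(), study_accession = character(),
      biosample_accession = character(), library_strategy = character(),
      library_layout = character(), platform = character(),
      n_files = integer(), is_public_data = logical(),
      is_public_metadata = logical(), spots = integer()
    )
  accs <- study_accessions(resolved, config)
  study_runs <- accs |>
    dplyr::group_by(study_id = .data$article_id) |>
    dplyr::group_map(function(g, key) {
      hits <- purrr::map_dfr(g$accession, fetch_run_metadata,
                             runs = runs_tbl, config = config)
      hits <- dplyr::distinct(hits, .data$run_accession, .keep_all = TRUE)
      list(study_id = key$study_id, runs = hits)
    })
  metadata <- purrr::map_dfr(study_runs, function(s) {
    dplyr::mutate(audit_study_metadata(s$runs, config),
                  study_id = s$study_id, .before = 1)
  })
  if (nrow(metadata) == 0) metadata <- NULL
  repo_map <- purrr::map_dfr(study_runs, function(s) {
    if (nrow(s$runs) == 0) return(NULL)
    tibble::tibble(study_id = s$study_id,
                   study_accession = unique(s$runs$study_accession))
  })

  fastq_raw <- if (file.exists(manifest_path)) {
    audit_fastq_manifest(manifest_path, config, root = world_dir)$per_study
  } else {
    tibble::tibble()
  }
  fastq <- if (nrow(fastq_raw) > 0 && nrow(repo_map) > 0) {
    repo_map |>
      dplyr::inner_join(fastq_raw, by = "study_accession") |>
      dplyr::group_by(.data$study_id) |>
      dplyr::summarise(
        has_quality_fault = any(.data$has_quality_fault),
        primers_present = any(.data$primers_present),
        paired_label_inconsistent = any(.data$paired_label_inconsistent),
        single_file_multisample = any(.data$single_file_multisample),
        distinct_barcodes = max(c(.data$distinct_barcodes, 0L), na.rm = TRUE),
        .groups = "drop"
      )
  } else {
    NULL
  }

  ledger <- assemble_fault_ledger(text, metadata, fastq) |>
    classify_fate()
  summary <- summarize_corpus(ledger)

  trends <- purrr::map_dfr(FAULT_FLAGS, function(flag) {
    yr <- count_by_year(ledger, flag)
    if (nrow(yr) < 2 || sum(yr$x) == 0 || sum(yr$x) == sum(yr$n)) return(NULL)
    tt <- chi2_trend(yr$x, yr$n, scores = yr$year)
    dplyr::mutate(tidy(tt), metric = flag, .before = 1)
  })

  informativeness <- if (file.exists(biosamples_path) && nrow(repo_map) > 0) {
    bios <- read_biosample_table(biosamples_path)
    per_study <- bios |>
      dplyr::group_by(study_id = .data$study_accession) |>
      dplyr::group_modify(function(g, key) {
        fields <- audit_biosample_metadata(g)
        fields$n_samples <- dplyr::n_distinct(g$biosample_accession)
        fields
      }) |>
      dplyr::ungroup() |>
      dplyr::rename(n_levels = "n_levels")
    metadata_informativeness(
      dplyr::select(per_study, "study_id", "field", "n_samples", "n_levels"),
      config
    )
  } else {
    NULL
  }

  if (!is.null(out_dir)) {
    write_audit_report(
      summary, trends, out_dir, config,
      input_files = c(runs_path, biosamples_path, manifest_path, meta_path,
                      list.files(articles_dir, full.names = TRUE))
    )
  }

  list(
    corpus = corpus, resolved = resolved, text = text, metadata = metadata,
    fastq = fastq, ledger = ledger, summary = summary, trends = trends,
    informativeness = informativeness
  )
}
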