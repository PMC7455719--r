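# Auditing of run-level and biosample-level repository metadata from an
# offline, table-backed provider (runinfo-style TSV tables).

RUN_TABLE_COLS <- c(
  "run_accession", "study_accession", "biosample_accession",
  "library_strategy", "library_layout", "platform", "n_files",
  "is_public_data", "is_public_metadata", "spots"
)

#' Read a runinfo-style run metadata table
#'
#' The offline metadata provider is a TSV with one row per sequencing run
#' and columns `run_accession`, `study_accession`, `biosample_accession`,
#' `library_strategy`, `library_layout` (SINGLE/PAIRED), `platform`,
#' `n_files`, `is_public_data`, `is_public_metadata`, `spots`.
#'
#' @param path TSV file path.
#' @return Tibble of run metadata.
#' @export
read_run_table <- function(path) {
  runs <- readr::read_tsv(
    path,
    col_types = readr::cols(
      run_accession = readr::col_character(),
      study_accession = readr::col_character(),
      biosample_accession = readr::col_character(),
      library_strategy = readr::col_character(),
      library_layout = readr::col_character(),
      platform = readr::col_character(),
      n_files = readr::col_integer(),
      is_public_data = readr::col_logical(),
      is_public_metadata = readr::col_logical(),
      spots = readr::col_integer()
    )
  )
  missing <- setdiff(RUN_TABLE_COLS, names(runs))
  if (length(missing) > 0) {
    audit_abort(sprintf("run table lacks column(s): %s",
                        paste(missing, collapse = ", ")),
                class = "ampliaudit_bad_table")
  }
  bad <- runs$is_public_data & runs$n_files < 1L
  if (any(bad)) {
    audit_abort(
      sprintf("public runs with no files: %s",
              paste(runs$run_accession[bad], collapse = ", ")),
      class = "ampliaudit_bad_table"
    )
  }
  runs
}

#' Read a biosample attribute table
#'
#' TSV with one row per (biosample, attribute): columns
#' `biosample_accession`, `attribute_name`, `attribute_value`.
#'
#' @param path TSV file path.
#' @return Tibble of biosample attributes.
#' @export
read_biosample_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Fetch run metadata for one accession from the offline provider
#'
#' Resolves project/study, experiment, biosample or run-level accessions to
#' the set of runs beneath them by matching against the corresponding
#' columns of the run table. An accession absent from the table is
#' `not_found` (zero rows), which is distinct from found-but-private rows
#' (present with `is_public_data`/`is_public_metadata` `FALSE`): the two
#' feed different fault flags downstream.
#'
#' @param accession A single well-formed accession string.
#' @param runs Run metadata tibble from [read_run_table()].
#' @param config An [audit_config()].
#' @return Tibble of matching `RunMetadata` rows; zero rows means not found.
#'   Placeholder or malformed accessions raise a precondition error.
#' @export
fetch_run_metadata <- function(accession, runs, config = audit_config()) {
  stopifnot(length(accession) == 1L)
  v <- validate_accession(accession, config)
  if (v$status != "well_formed") {
    audit_abort(
      sprintf("'%s' is not a well-formed accession (%s)", accession, v$status),
      class = "ampliaudit_bad_accession"
    )
  }
  dplyr::filter(
    runs,
    .data$run_accession == accession |
      .data$study_accession == accession |
      .data$biosample_accession == accession
  )
}

#' Audit the run-level metadata of one study
#'
#' @param runs Tibble of `RunMetadata` rows for one study (possibly zero
#'   rows, meaning the accession was not found).
#' @param config An [audit_config()]; `lenient_strategy = TRUE` accepts case
#'   variants of the vocabulary token "AMPLICON".
#' @return One-row tibble: `accession_found`, `data_public`,
#'   `metadata_public`, `strategy_is_amplicon` (`TRUE` iff every run's
#'   `library_strategy` equals the canonical token "AMPLICON"; `NA` when the
#'   metadata is not public), `layout_declared`, `platform`, `n_runs`,
#'   `n_files_total`, `strategy_labels` (distinct labels seen, `;`-joined).
#' @export
#' @examples
#' runs <- tibble::tibble(
#'   run_accession = c("SRR000001", "SRR000002"),
#'   study_accession = "SRP000001", biosample_accession = c("SAMN01", "SAMN02"),
#'   library_strategy = "AMPLICON", library_layout = "SINGLE",
#'   platform = "ILLUMINA", n_files = 1L,
#'   is_public_data = TRUE, is_public_metadata = TRUE, spots = 1000L)
#' audit_study_metadata(runs)
audit_study_metadata <- function(runs, config = audit_config()) {
  stopifnot(is.data.frame(runs))
  if (nrow(runs) == 0) {
    return(tibble::tibble(
      accession_found = FALSE, data_public = FALSE, metadata_public = FALSE,
      strategy_is_amplicon = NA, layout_declared = NA_character_,
      platform = NA_character_, n_runs = 0L, n_files_total = 0L,
      strategy_labels = NA_character_
    ))
  }
  metadata_public <- all(runs$is_public_metadata)
  token_ok <- if (config$lenient_strategy) {
    toupper(runs$library_strategy) == "AMPLICON"
  } else {
    runs$library_strategy == "AMPLICON"
  }
  tibble::tibble(
    accession_found = TRUE,
    data_public = all(runs$is_public_data),
    metadata_public = metadata_public,
    strategy_is_amplicon = if (metadata_public) all(token_ok) else NA,
    layout_declared = paste(sort(unique(runs$library_layout)), collapse = ";"),
    platform = paste(sort(unique(runs$platform)), collapse = ";"),
    n_runs = nrow(runs),
    n_files_total = sum(runs$n_files),
    strategy_labels = paste(sort(unique(runs$library_strategy)), collapse = ";")
  )
}

#' Collate biosample attributes per study
#'
#' Counts, for every attribute field of a study's samples, how many samples
#' carry the field and how many distinct factor levels it realizes. Values
#' are whitespace-trimmed before distinct-level counting, which is
#' case-sensitive.
#'
#' @param attributes Tibble with columns `biosample_accession`,
#'   `attribute_name`, `attribute_value` for the samples of one study.
#' @return Tibble with one row per field: `field`, `n_samples_with_field`,
#'   `n_levels`.
#' @export
#' @examples
#' attrs <- tibble::tibble(
#'   biosample_accession = rep(c("SAMN01", "SAMN02"), each = 2),
#'   attribute_name = rep(c("env", "host"), 2),
#'   attribute_value = c("soil", "maize", "soil ", "wheat"))
#' audit_biosample_metadata(attrs)
audit_biosample_metadata <- function(attributes) {
  stopifnot(is.data.frame(attributes))
  if (nrow(attributes) == 0) {
    return(tibble::tibble(
      field = character(), n_samples_with_field = integer(),
      n_levels = integer()
    ))
  }
  stopifnot(all(c("biosample_accession", "attribute_name", "attribute_value")
                %in% names(attributes)))
  attributes |>
    dplyr::mutate(value = trimws(.data$attribute_value)) |>
    dplyr::group_by(field = .data$attribute_name) |>
    dplyr::summarise(
      n_samples_with_field = dplyr::n_distinct(.data$biosample_accession),
      n_levels = dplyr::n_distinct(.data$value),
      .groups = "drop"
    )
}

#' Field informativeness across a corpus of studies
#'
#' Classifies metadata fields by their presence across studies: `mandatory`
#' when present in every study, `popular_optional` when present in more than
#' `config$optional_field_threshold` (default 25%) of studies, `rare`
#' otherwise; and computes each field's informative potential per study as
#' the number of samples divided by the number of distinct factor levels
#' (a field with as many levels as samples, e.g. free-text, has potential 1;
#' a grouping factor with few levels has high potential). Fields realizing
#' zero levels in a study are skipped with a warning.
#'
#' @param study_fields Tibble with one row per (study, field): columns
#'   `study_id`, `field`, `n_samples`, `n_levels` — e.g. built by running
#'   [audit_biosample_metadata()] per study.
#' @param config An [audit_config()].
#' @return Tibble with one row per (study, field): the inputs plus
#'   `informative_potential`, `presence_fraction` (fraction of studies in
#'   which the field occurs) and `field_class`.
#' @export
metadata_informativeness <- function(study_fields, config = audit_config()) {
  stopifnot(
    is.data.frame(study_fields),
    all(c("study_id", "field", "n_samples", "n_levels") %in% names(study_fields))
  )
  stopifnot(all(study_fields$n_samples >= 1))
  zero <- study_fields$n_levels == 0
  if (any(zero)) {
    warning(sprintf(
      "skipping %d field record(s) with zero levels: %s",
      sum(zero),
      paste(unique(study_fields$field[zero]), collapse = ", ")
    ), call. = FALSE)
    study_fields <- study_fields[!zero, , drop = FALSE]
  }
  n_studies <- dplyr::n_distinct(study_fields$study_id)
  study_fields |>
    dplyr::mutate(informative_potential = .data$n_samples / .data$n_levels) |>
    dplyr::group_by(.data$field) |>
    dplyr::mutate(
      presence_fraction = dplyr::n_distinct(.data$study_id) / n_studies
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      field_class = dplyr::case_when(
        presence_fraction == 1 ~ "mandatory",
        presence_fraction > config$optional_field_threshold ~ "popular_optional",
        TRUE ~ "rare"
      )
    )
}
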