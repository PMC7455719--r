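# Accession validation, range resolution, and the non-deposition
# extrapolation.

#' Validate accession strings
#'
#' Classifies each string as `well_formed` (matches the accession grammar:
#' known INSDC prefix + digits), `placeholder` (grammar-shaped but with
#' filler characters such as `X`, `#` or `?` in digit positions), or
#' `malformed` (anything else, including SRA submission IDs like `SUB123`,
#' which are not accessions).
#'
#' @param s Character vector of candidate accession strings.
#' @param config An [audit_config()].
#' @return Tibble with columns `accession`, `status`
#'   (`well_formed`/`placeholder`/`malformed`), `reason`.
#' @export
#' @examples
#' validate_accession(c("SRP123456", "SRPXXXXXX", "SUB123"))
validate_accession <- function(s, config = audit_config()) {
  stopifnot(is.character(s))
  well <- sprintf(
    "^(%s)[0-9]{1,%d}$", .prefix_alternation(), config$max_digits
  )
  placeholder <- sprintf(
    "^(%s)(?=[0-9Xx#?]*[Xx#?])[0-9Xx#?]{1,%d}$",
    .prefix_alternation(), config$max_digits
  )
  status <- dplyr::case_when(
    stringr::str_detect(s, well) ~ "well_formed",
    stringr::str_detect(s, stringr::regex(placeholder)) ~ "placeholder",
    TRUE ~ "malformed"
  )
  reason <- dplyr::case_when(
    status == "well_formed" ~ "matches accession grammar",
    status == "placeholder" ~ "filler characters in digit positions",
    TRUE ~ "does not match the accession grammar"
  )
  tibble::tibble(accession = s, status = status, reason = reason)
}

#' Detect candidate accession ranges within one article
#'
#' Multiple well-formed mentions sharing an accession prefix within the same
#' article are interpreted as a candidate range spanning their numeric
#' extremes (pairwise candidate intervals over the sorted values chain
#' through shared endpoints, so each prefix group merges into a single
#' range). Singleton mentions never form ranges. Mentions written at
#' different digit widths are normalized by left-padding to the widest
#' width. Ranges larger than `config$range_auto_threshold` accessions are
#' flagged `needs_manual_check` (they are still expandable; the flag is
#' carried into downstream reports for human verification).
#'
#' @param mentions Mention tibble from [extract_accession_mentions()], all
#'   rows from one article. Placeholder mentions are ignored.
#' @param config An [audit_config()].
#' @return Tibble with columns `article_id`, `prefix`, `start_digits`,
#'   `end_digits`, `size`, `needs_manual_check`, `range_id`.
#' @export
#' @examples
#' a <- parse_article("Runs SRR000001 to SRR000005 were deposited.",
#'                    article_id = "a1")
#' detect_ranges(extract_accession_mentions(a))
detect_ranges <- function(mentions, config = audit_config()) {
  stopifnot(is.data.frame(mentions))
  need <- c("article_id", "raw", "prefix", "digits", "is_placeholder")
  if (nrow(mentions) == 0) {
    return(tibble::tibble(
      article_id = character(), prefix = character(),
      start_digits = character(), end_digits = character(),
      size = integer(), needs_manual_check = logical(), range_id = character()
    ))
  }
  stopifnot(all(need %in% names(mentions)))
  if (dplyr::n_distinct(mentions$article_id) > 1L) {
    audit_abort("detect_ranges expects mentions from a single article",
                class = "ampliaudit_mixed_articles")
  }
  real <- mentions |>
    dplyr::filter(!.data$is_placeholder) |>
    dplyr::distinct(.data$article_id, .data$prefix, .data$digits)
  if (nrow(real) == 0) {
    return(tibble::tibble(
      article_id = character(), prefix = character(),
      start_digits = character(), end_digits = character(),
      size = integer(), needs_manual_check = logical(), range_id = character()
    ))
  }
  real |>
    dplyr::group_by(.data$article_id, .data$prefix) |>
    dplyr::summarise(
      width = max(nchar(.data$digits)),
      lo = min(as.numeric(.data$digits)),
      hi = max(as.numeric(.data$digits)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$hi > .data$lo) |>
    dplyr::mutate(
      start_digits = formatC(.data$lo, width = .data$width, flag = "0", format = "d"),
      end_digits = formatC(.data$hi, width = .data$width, flag = "0", format = "d"),
      size = as.integer(.data$hi - .data$lo + 1),
      needs_manual_check = .data$size > config$range_auto_threshold,
      range_id = paste0(.data$prefix, .data$start_digits, "-",
                        .data$prefix, .data$end_digits)
    ) |>
    dplyr::select("article_id", "prefix", "start_digits", "end_digits",
                  "size", "needs_manual_check", "range_id")
}

#' Expand an accession range to single accessions
#'
#' @param r One range: a one-row data frame or named list with fields
#'   `prefix`, `start_digits`, `end_digits` (equal width, zero-padded).
#' @param config An [audit_config()]; `config$range_cap` bounds the
#'   expansion size (memory guard).
#' @return Character vector of `size` accessions, zero-padding preserved;
#'   the first equals `prefix + start_digits`, the last
#'   `prefix + end_digits`.
#' @export
#' @examples
#' expand_range(list(prefix = "SRR", start_digits = "000001",
#'                   end_digits = "000003"))
expand_range <- function(r, config = audit_config()) {
  if (is.data.frame(r)) {
    stopifnot(nrow(r) == 1L)
    r <- as.list(r)
  }
  stopifnot(all(c("prefix", "start_digits", "end_digits") %in% names(r)))
  if (nchar(r$start_digits) != nchar(r$end_digits)) {
    audit_abort(
      sprintf("digit-width mismatch in range %s%s-%s%s",
              r$prefix, r$start_digits, r$prefix, r$end_digits),
      class = "ampliaudit_bad_range"
    )
  }
  lo <- as.numeric(r$start_digits)
  hi <- as.numeric(r$end_digits)
  size <- hi - lo + 1
  if (size < 2) {
    audit_abort("degenerate range: size must be >= 2",
                class = "ampliaudit_bad_range")
  }
  if (size > config$range_cap) {
    audit_abort(
      sprintf("range of %d exceeds expansion cap %d", size, config$range_cap),
      class = "ampliaudit_range_cap"
    )
  }
  paste0(
    r$prefix,
    formatC(seq(lo, hi), width = nchar(r$start_digits), flag = "0", format = "d")
  )
}

#' Extrapolate the number of non-depositing studies
#'
#' Scales the hit rate observed in a manually inspected subsample up to the
#' full pool: `round(k_hits / n_inspected * pool_size)`, half-up. Used to
#' estimate how many studies in a corpus performed amplicon sequencing but
#' provided no access to the data, from a manual check of a random sample of
#' accession-less articles.
#'
#' @param k_hits Number of inspected articles that sequenced but did not
#'   deposit.
#' @param n_inspected Size of the inspected subsample (> 0).
#' @param pool_size Size of the pool the rate is applied to.
#' @return Integer estimate.
#' @export
#' @examples
#' extrapolate_nondeposit(19, 150, 3702)  # 469
extrapolate_nondeposit <- function(k_hits, n_inspected, pool_size) {
  stopifnot(
    length(k_hits) == 1L, length(n_inspected) == 1L, length(pool_size) == 1L,
    k_hits >= 0, n_inspected >= k_hits, pool_size >= n_inspected
  )
  if (n_inspected == 0) {
    audit_abort("n_inspected must be > 0", class = "ampliaudit_bad_input")
  }
  as.integer(round_half_up(k_hits / n_inspected * pool_size))
}

#' Resolve a corpus table: validation status and range annotation
#'
#' Adds per-row accession `status` (via [validate_accession()]) and, per
#' article, the detected range membership: rows whose accession falls inside
#' a detected same-prefix range get that range's `range_id` and
#' `needs_manual_check` flag.
#'
#' @param corpus Corpus tibble from [corpus_to_table()] / [mine_articles()].
#' @param config An [audit_config()].
#' @return The corpus tibble with columns `status`, `range_id`,
#'   `needs_manual_check` appended.
#' @export
resolve_corpus <- function(corpus, config = audit_config()) {
  stopifnot(is.data.frame(corpus), "accession" %in% names(corpus))
  corpus$status <- ifelse(
    is.na(corpus$accession), NA_character_,
    validate_accession(corpus$accession, config)$status
  )
  mention_like <- corpus |>
    dplyr::filter(!is.na(.data$accession)) |>
    dplyr::transmute(
      article_id = .data$article_id, raw = .data$accession,
      prefix = .data$prefix, digits = .data$digits,
      is_placeholder = .data$status != "well_formed"
    )
  ranges <- mention_like |>
    dplyr::group_split(.data$article_id) |>
    purrr::map_dfr(detect_ranges, config = config)
  if (nrow(ranges) == 0) {
    corpus$range_id <- NA_character_
    corpus$needs_manual_check <- FALSE
    return(corpus)
  }
  annotated <- corpus |>
    dplyr::left_join(
      ranges, by = c("article_id", "prefix"), relationship = "many-to-one"
    ) |>
    dplyr::mutate(
      num = suppressWarnings(as.numeric(.data$digits)),
      in_range = !is.na(.data$range_id) & .data$status == "well_formed" &
        !is.na(.data$num) &
        .data$num >= as.numeric(.data$start_digits) &
        .data$num <= as.numeric(.data$end_digits),
      range_id = ifelse(.data$in_range, .data$range_id, NA_character_),
      needs_manual_check = .data$in_range &
        dplyr::coalesce(.data$needs_manual_check, FALSE)
    ) |>
    dplyr::select(-"start_digits", -"end_digits", -"size", -"in_range", -"num")
  annotated
}

#' All accessions to query per article
#'
#' The union of an article's well-formed accession mentions and the single
#' accessions obtained by expanding its detected ranges (ranges beyond
#' `config$range_cap` are left unexpanded with a warning; their endpoint
#' mentions are still included).
#'
#' @param corpus Corpus tibble (resolved or not).
#' @param config An [audit_config()].
#' @return Tibble with columns `article_id`, `accession` (distinct rows).
#' @export
study_accessions <- function(corpus, config = audit_config()) {
  stopifnot(is.data.frame(corpus), "accession" %in% names(corpus))
  base <- corpus |>
    dplyr::filter(!is.na(.data$accession)) |>
    dplyr::mutate(status = validate_accession(.data$accession, config)$status) |>
    dplyr::filter(.data$status == "well_formed")
  mention_like <- dplyr::transmute(
    base,
    article_id = .data$article_id, raw = .data$accession,
    prefix = .data$prefix, digits = .data$digits, is_placeholder = FALSE
  )
  ranges <- mention_like |>
    dplyr::group_split(.data$article_id) |>
    purrr::map_dfr(detect_ranges, config = config)
  expanded <- purrr::map_dfr(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    acc <- tryCatch(
      expand_range(r, config),
      ampliaudit_range_cap = function(e) {
        warning(sprintf("range %s not expanded: %s", r$range_id,
                        conditionMessage(e)), call. = FALSE)
        character()
      }
    )
    tibble::tibble(article_id = r$article_id, accession = acc)
  })
  dplyr::distinct(dplyr::bind_rows(
    dplyr::select(base, "article_id", "accession"),
    expanded
  ))
}
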