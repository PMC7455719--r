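# Text mining of article full texts: accession mentions, sequencing
# keywords, primer-pair mentions, alternative-database mentions.

ACCESSION_PREFIXES <- c(
  "PRJ", "ERP", "DRP", "SRP", "SAME", "SAMND", "SAMN",
  "ERS", "ERX", "DRX", "SRX", "DRR", "SRR", "ERZ", "DRZ", "SRZ"
)

# Alternation with longest prefixes first so e.g. SAMND wins over SAMN.
# PRJ may carry a two-letter project qualifier (PRJNA, PRJEB, PRJDB).
.prefix_alternation <- function() {
  paste(
    c(
      "PRJ[A-Z]{2}", "SAMND", "SAMN", "SAME",
      "ERP", "DRP", "SRP", "ERS", "ERX", "DRX", "SRX",
      "DRR", "SRR", "ERZ", "DRZ", "SRZ", "PRJ"
    ),
    collapse = "|"
  )
}

.accession_regex <- function(max_digits, placeholder = FALSE) {
  digits <- if (placeholder) {
    # grammar-shaped token whose digit positions contain at least one filler
    sprintf("(?=[0-9Xx#?]*[Xx#?])[0-9Xx#?]{1,%d}", max_digits)
  } else {
    sprintf("[0-9]{1,%d}", max_digits)
  }
  sprintf("(?<![A-Za-z0-9])(%s)(%s)(?![A-Za-z0-9#?])", .prefix_alternation(), digits)
}

.prefix_class <- function(prefix) {
  ifelse(startsWith(prefix, "PRJ"), "PRJ", prefix)
}

#' Parse an article document into searchable fields
#'
#' Accepts either plain text or a TEI-flavoured XML document and returns the
#' title, abstract and body with bibliography and supplementary content
#' stripped. For TEI input, `listBibl` and `back` elements are removed before
#' the body text is read. For plain text, everything from the last line whose
#' normalized content matches a reference-section heading (References,
#' Bibliography, Literature Cited, Supplementary ...) onwards is dropped; if
#' no such heading exists the whole text is the body.
#'
#' @param document Character scalar: the document content.
#' @param format One of `"auto"`, `"plain"`, `"tei"`. `"auto"` treats content
#'   starting with an XML declaration or a TEI root element as TEI.
#' @param article_id Identifier (DOI or filename stem) carried through the
#'   corpus table; must be non-empty.
#' @return An object of class `article_text`: a list with fields
#'   `article_id`, `title`, `abstract`, `body`, `source_format`.
#' @export
#' @examples
#' a <- parse_article("We deposited reads under SRP123456.\nReferences\nFoo 2001.",
#'                    article_id = "a1")
#' a$body
parse_article <- function(document,
                          format = c("auto", "plain", "tei"),
                          article_id = "article") {
  format <- match.arg(format)
  stopifnot(is.character(article_id), length(article_id) == 1L, nzchar(article_id))
  if (!is.character(document) || length(document) != 1L || is.na(document) ||
      !nzchar(trimws(document))) {
    audit_abort(
      sprintf("unparseable document for article '%s': empty or not text", article_id),
      class = "ampliaudit_unparseable"
    )
  }
  if (format == "auto") {
    format <- if (grepl("^\\s*(<\\?xml|<TEI)", document)) "tei" else "plain"
  }
  if (format == "tei") {
    doc <- tryCatch(
      xml2::read_xml(document),
      error = function(e) {
        audit_abort(
          sprintf("unparseable XML for article '%s': %s", article_id, conditionMessage(e)),
          class = "ampliaudit_unparseable"
        )
      }
    )
    drop <- xml2::xml_find_all(
      doc, ".//*[local-name()='listBibl' or local-name()='back']"
    )
    xml2::xml_remove(drop)
    grab <- function(xpath) {
      nodes <- xml2::xml_find_all(doc, xpath)
      paste(trimws(xml2::xml_text(nodes)), collapse = " ")
    }
    title <- grab(".//*[local-name()='titleStmt']/*[local-name()='title']")
    abstract <- grab(".//*[local-name()='abstract']")
    body <- grab(".//*[local-name()='body']")
  } else {
    lines <- strsplit(document, "\n", fixed = TRUE)[[1]]
    heading <- paste0(
      "^\\s*[#*]*\\s*(references|bibliography|literature\\s+cited|",
      "supplementary(\\s+(materials?|information|data))?)\\s*[:.]?\\s*$"
    )
    hits <- grep(heading, lines, ignore.case = TRUE, perl = TRUE)
    if (length(hits) > 0) lines <- lines[seq_len(max(hits) - 1L)]
    title <- ""
    abstract <- ""
    body <- paste(lines, collapse = "\n")
  }
  structure(
    list(
      article_id = article_id, title = title, abstract = abstract,
      body = body, source_format = format
    ),
    class = "article_text"
  )
}

#' @export
print.article_text <- function(x, ...) {
  cat(sprintf(
    "<article_text '%s' (%s): title %d chars, abstract %d chars, body %d chars>\n",
    x$article_id, x$source_format, nchar(x$title), nchar(x$abstract), nchar(x$body)
  ))
  invisible(x)
}

#' Extract INSDC accession mentions from an article
#'
#' Scans the title, abstract and body for accession numbers of the INSDC
#' prefixes PRJ (optionally with a two-letter project qualifier, e.g. PRJNA),
#' ERP/DRP/SRP, SAME/SAMND/SAMN, ERS, ERX/DRX/SRX, DRR/SRR, ERZ/DRZ/SRZ,
#' each followed by 1 to `config$max_digits` digits. Prefixes are matched
#' case-sensitively (uppercase, the archive convention) and a mention must
#' not be flanked by alphanumeric characters, so partial matches inside
#' longer tokens are rejected. Grammar-shaped tokens whose digit positions
#' contain filler characters (`X`, `x`, `#`, `?`) are also captured and
#' flagged as placeholders (e.g. `SRPXXXXXX` left in a manuscript).
#'
#' @param article An `article_text` from [parse_article()].
#' @param config An [audit_config()].
#' @return Tibble with one row per mention: `article_id`, `raw`, `prefix`
#'   (as matched, e.g. `PRJNA`), `prefix_class` (one of the 16 listed
#'   prefixes), `digits`, `field` (`title`/`abstract`/`body`), `start`, `end`
#'   (0-based half-open character offsets into that field), `is_placeholder`.
#' @export
#' @examples
#' a <- parse_article("Reads are in the SRA under SRP123456 and PRJNA398234.",
#'                    article_id = "a1")
#' extract_accession_mentions(a)
extract_accession_mentions <- function(article, config = audit_config()) {
  stopifnot(inherits(article, "article_text"))
  scan_field <- function(field, placeholder) {
    text <- article[[field]]
    pat <- .accession_regex(config$max_digits, placeholder = placeholder)
    loc <- stringr::str_locate_all(text, stringr::regex(pat))[[1]]
    if (nrow(loc) == 0) return(NULL)
    raw <- stringr::str_sub(text, loc[, "start"], loc[, "end"])
    prefix <- stringr::str_extract(raw, paste0("^(", .prefix_alternation(), ")"))
    tibble::tibble(
      article_id = article$article_id,
      raw = raw,
      prefix = prefix,
      prefix_class = .prefix_class(prefix),
      digits = substr(raw, nchar(prefix) + 1L, nchar(raw)),
      field = field,
      start = as.integer(loc[, "start"] - 1L),
      end = as.integer(loc[, "end"]),
      is_placeholder = placeholder
    )
  }
  out <- purrr::map_dfr(
    c("title", "abstract", "body"),
    function(f) dplyr::bind_rows(scan_field(f, FALSE), scan_field(f, TRUE))
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(
      article_id = character(), raw = character(), prefix = character(),
      prefix_class = character(), digits = character(), field = character(),
      start = integer(), end = integer(), is_placeholder = logical()
    ))
  }
  dplyr::arrange(out, factor(.data$field, c("title", "abstract", "body")), .data$start)
}

#' Detect primer-pair mentions for the 515F/806R amplicon
#'
#' Implements a tolerant grammar over textual primer mentions: the number
#' may precede or follow the F/R designator (`515F`, `515 F`, `F515`,
#' `Fwd 515`, `Forward 515`), separators may be blanks, hyphens or
#' underscores, matching is case-insensitive, and non-minimal forms with
#' trailing letters (`806Rb`, `515F-barcoded` via its `515F` core) are
#' accepted. A pair is declared only when both a 515-forward variant and an
#' 806-reverse variant occur.
#'
#' @param text Character scalar to search.
#' @return List with `matched` (logical: both sides present) and `variants`
#'   (character vector of the matched substrings).
#' @export
#' @examples
#' detect_primer_pair_mentions("amplified with primers 515F/806R")
#' detect_primer_pair_mentions("primers F515 and R806")
#' detect_primer_pair_mentions("515F only")
detect_primer_pair_mentions <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  side <- function(number, letter, word) {
    pat <- sprintf(
      paste0(
        "(?<![A-Za-z0-9])%s\\s*[-_]?\\s*%s[A-Za-z]*",
        "|(?<![A-Za-z0-9])%s(?:%s)?\\s*[-_]?\\s*%s(?![0-9])"
      ),
      number, letter, letter, word, number
    )
    unlist(stringr::str_extract_all(
      text, stringr::regex(pat, ignore_case = TRUE)
    ))
  }
  fwd <- side("515", "F", "wd|orward")
  rev <- side("806", "R", "ev|everse")
  list(
    matched = length(fwd) > 0 && length(rev) > 0,
    variants = unique(c(fwd, rev))
  )
}

#' Detect sequencing keywords and alternative-database mentions
#'
#' Case-insensitive search of title + abstract + body for: mentions of the
#' 16S rRNA gene; high-throughput sequencing platforms (Illumina, 454,
#' Ion Torrent, PacBio); the 515F/806R primer pair (via
#' [detect_primer_pair_mentions()]); and the alternative databases MG-RAST,
#' figshare, Qiita and dbGaP (the latter "in any combination of capitalized
#' letters"). Alternative-database mentions are always recorded; whether an
#' INSDC accession is also present is a separate flag computed at the corpus
#' level, so replication-style filtering remains possible downstream.
#'
#' @param article An `article_text`.
#' @return One-row tibble: `article_id`, `mentions_16s`,
#'   `primer_pair_515_806`, `platforms` (collapsed `;` string, `""` if none),
#'   `primer_variants` (list column), `alt_mgrast`, `alt_figshare`,
#'   `alt_qiita`, `alt_dbgap`.
#' @export
#' @examples
#' a <- parse_article("We sequenced 16S rRNA amplicons (515F/806R) on Illumina MiSeq.",
#'                    article_id = "a1")
#' detect_keywords(a)
detect_keywords <- function(article) {
  stopifnot(inherits(article, "article_text"))
  text <- paste(article$title, article$abstract, article$body, sep = "\n")
  has <- function(pat) {
    stringr::str_detect(text, stringr::regex(pat, ignore_case = TRUE))
  }
  platform_pats <- c(
    "Illumina" = "illumina|miseq|hiseq|novaseq|nextseq",
    "454" = "(?<![0-9])454(?![0-9])|pyrosequencing",
    "Ion Torrent" = "ion\\s+torrent|ion\\s+pgm",
    "PacBio" = "pac\\s*bio|pacific\\s+biosciences"
  )
  platforms <- names(platform_pats)[vapply(platform_pats, has, logical(1))]
  primer <- detect_primer_pair_mentions(text)
  tibble::tibble(
    article_id = article$article_id,
    mentions_16s = has("16\\s*S\\s*(rRNA|ribosomal)"),
    primer_pair_515_806 = primer$matched,
    platforms = paste(platforms, collapse = ";"),
    primer_variants = list(primer$variants),
    alt_mgrast = has("MG[-\\s]?RAST"),
    alt_figshare = has("figshare"),
    alt_qiita = has("qiita"),
    alt_dbgap = has("dbgap")
  )
}

#' Summarize a corpus of parsed articles as one table
#'
#' Emits one row per accession mention; articles without any mention still
#' contribute a single row with empty accession fields so that no article is
#' silently dropped. Keyword flags are repeated on each of an article's rows.
#' The `insdc_absent` flag is `TRUE` when the article contains no well-formed
#' (non-placeholder) accession mention, contextualizing alternative-database
#' mentions.
#'
#' @param articles List of `article_text` objects with unique `article_id`s.
#' @param config An [audit_config()].
#' @param doi_map Optional tibble/data.frame with columns `article_id`,
#'   `doi`; and optionally `year` (publication year, carried through for
#'   trend tests).
#' @return Tibble, one row per mention (or per mention-less article).
#' @export
#' @examples
#' arts <- list(parse_article("Data: SRP123456.", article_id = "a1"),
#'              parse_article("No data here.", article_id = "a2"))
#' corpus_to_table(arts)
corpus_to_table <- function(articles, config = audit_config(), doi_map = NULL) {
  stopifnot(is.list(articles), length(articles) > 0)
  ids <- vapply(articles, function(a) a$article_id, character(1))
  if (anyDuplicated(ids)) {
    audit_abort(
      sprintf(
        "duplicate article_id(s): %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", ")
      ),
      class = "ampliaudit_duplicate_id"
    )
  }
  empty_mention <- tibble::tibble(
    raw = NA_character_, prefix = NA_character_, prefix_class = NA_character_,
    digits = NA_character_, field = NA_character_,
    start = NA_integer_, end = NA_integer_, is_placeholder = NA
  )
  rows <- purrr::map_dfr(articles, function(a) {
    mentions <- extract_accession_mentions(a, config)
    kw <- detect_keywords(a)
    kw$primer_variants <- NULL
    if (nrow(mentions) == 0) {
      m <- dplyr::mutate(empty_mention, article_id = a$article_id, .before = 1)
    } else {
      m <- mentions
    }
    m <- dplyr::rename(m, accession = "raw")
    m$insdc_absent <- nrow(mentions) == 0 || !any(!mentions$is_placeholder)
    dplyr::left_join(m, kw, by = "article_id")
  })
  if (!is.null(doi_map)) {
    doi_map <- tibble::as_tibble(doi_map)
    stopifnot("article_id" %in% names(doi_map))
    rows <- dplyr::left_join(rows, doi_map, by = "article_id")
  }
  if (!"doi" %in% names(rows)) rows$doi <- NA_character_
  dplyr::relocate(rows, "article_id", "doi", "accession")
}

#' Mine a directory of article files into a corpus table
#'
#' Reads every `*.txt` (plain text) and `*.xml` (TEI) file in `dir`, parses
#' each with [parse_article()] (file stem = `article_id`) and assembles the
#' corpus table with [corpus_to_table()]. Unparseable documents are excluded
#' with a warning naming them, mirroring a screening pipeline that drops
#' conversion failures rather than aborting the corpus.
#'
#' @param dir Directory of article files.
#' @param config An [audit_config()].
#' @param doi_map Optional `article_id`/`doi`/`year` mapping table (or a path
#'   to a TSV with those columns).
#' @return Corpus tibble as from [corpus_to_table()].
#' @export
mine_articles <- function(dir, config = audit_config(), doi_map = NULL) {
  stopifnot(dir.exists(dir))
  files <- list.files(dir, pattern = "\\.(txt|xml)$", full.names = TRUE)
  if (length(files) == 0) {
    audit_abort(sprintf("no .txt or .xml articles in '%s'", dir),
                class = "ampliaudit_empty_corpus")
  }
  if (is.character(doi_map) && length(doi_map) == 1L) {
    doi_map <- readr::read_tsv(doi_map, show_col_types = FALSE)
  }
  failed <- character()
  articles <- purrr::compact(purrr::map(files, function(f) {
    id <- sub("\\.(txt|xml)$", "", basename(f))
    fmt <- if (grepl("\\.xml$", f)) "tei" else "plain"
    txt <- paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
    tryCatch(
      parse_article(txt, format = fmt, article_id = id),
      ampliaudit_unparseable = function(e) {
        failed <<- c(failed, id)
        NULL
      }
    )
  }))
  if (length(failed) > 0) {
    warning(sprintf(
      "excluded %d unparseable article(s): %s",
      length(failed), paste(failed, collapse = ", ")
    ), call. = FALSE)
  }
  if (length(articles) == 0) {
    audit_abort("all articles unparseable", class = "ampliaudit_empty_corpus")
  }
  corpus_to_table(articles, config, doi_map)
}
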