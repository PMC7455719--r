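test_that("TEI parsing keeps body text and strips bibliography and back matter", {
  a <- parse_article(tei_fixture(), format = "tei", article_id = "t1")
  expect_s3_class(a, "article_text")
  expect_match(a$title, "Soil communities")
  expect_match(a$abstract, "16S rRNA")
  expect_match(a$body, "SRP123456")
  expect_no_match(a$body, "ERP000999")
  mentions <- extract_accession_mentions(a)
  expect_equal(mentions$raw, "SRP123456")
  expect_equal(mentions$field, "body")
})

test_that("plain-text parsing strips from the last reference heading, or keeps all", {
  txt <- "Intro SRR000010.\nReferences\nMid text SRR000011.\nREFERENCES\nDecoy SRR000012."
  a <- parse_article(txt, article_id = "p1")
  expect_match(a$body, "SRR000011")
  expect_no_match(a$body, "SRR000012")
  b <- parse_article("No headings here, SRR000013.", article_id = "p2")
  expect_match(b$body, "SRR000013")
})

test_that("empty or broken documents raise a structured unparseable error", {
  expect_error(parse_article("", article_id = "x"),
               class = "ampliaudit_unparseable")
  expect_error(parse_article("   \n  ", article_id = "x"),
               class = "ampliaudit_unparseable")
  expect_error(parse_article("<TEI><unclosed>", format = "tei", article_id = "x"),
               class = "ampliaudit_unparseable")
  expect_error(parse_article("<?xml version='1.0'?><broken", article_id = "x"),
               class = "ampliaudit_unparseable")
})

test_that("accession grammar handles prefixes, qualifiers and word boundaries", {
  a <- parse_article(
    paste(
      "deposited under SRP123456 in the SRA;",
      "project PRJNA398234 and sample SAMND00123;",
      "partial SRP1234567890X should not match;",
      "lowercase srp123456 should not match."
    ),
    article_id = "g1"
  )
  m <- extract_accession_mentions(a)
  expect_setequal(m$raw, c("SRP123456", "PRJNA398234", "SAMND00123"))
  expect_equal(m$prefix_class[m$raw == "PRJNA398234"], "PRJ")
  expect_equal(m$prefix[m$raw == "PRJNA398234"], "PRJNA")
  expect_equal(m$prefix[m$raw == "SAMND00123"], "SAMND")
  # empty input
  expect_equal(
    nrow(extract_accession_mentions(
      parse_article("no ids here", article_id = "g2")
    )),
    0L
  )
})

test_that("strict grammar mode limits accessions to six digits", {
  a <- parse_article("runs SRR123456 and SRR1234567", article_id = "s1")
  strict <- extract_accession_mentions(a, audit_config(strict_grammar = TRUE))
  expect_equal(strict$raw, "SRR123456")
  default <- extract_accession_mentions(a)
  expect_setequal(default$raw, c("SRR123456", "SRR1234567"))
})

test_that("placeholder-shaped tokens are captured and flagged", {
  a <- parse_article("under accession SRPXXXXXX and DRP12#456", article_id = "ph")
  m <- extract_accession_mentions(a)
  expect_setequal(m$raw[m$is_placeholder], c("SRPXXXXXX", "DRP12#456"))
})

test_that("mention extraction agrees with the brute-force positional scanner", {
  set.seed(41)
  planted <- c("SRP000123", "PRJEB12345", "SAMN0009", "ERR999",  # ERR not in grammar
               "DRZ88", "SRX4", "SAME123456")
  fillers <- c("soil microbial community", "was amplified", "then sequenced",
               "with standard protocols", "(Supplementary)", "e.g.,")
  for (rep in 1:25) {
    words <- sample(c(
      sample(planted, sample(0:4, 1), replace = TRUE),
      sample(fillers, sample(3:8, 1), replace = TRUE)
    ))
    text <- paste(words, collapse = " ")
    a <- parse_article(paste0("T\n", text), article_id = "r")
    got <- extract_accession_mentions(a)
    got <- got[!got$is_placeholder & got$field == "body", ]
    want <- oracle_scan_mentions(a$body)
    expect_equal(got$raw, want$raw, info = text)
    expect_equal(got$start, want$start, info = text)
    expect_equal(got$end, want$end, info = text)
  }
})

test_that("mention offsets index the searched field and appending text never drops mentions", {
  set.seed(7)
  for (rep in 1:20) {
    body <- paste(
      "Data under", sprintf("SRP%06d", sample(1e5, 1)), "and",
      sprintf("SRR%07d", sample(1e6, 1)), random_dna_string(10)
    )
    a <- parse_article(body, article_id = "o")
    m <- extract_accession_mentions(a)
    expect_gt(nrow(m), 0)
    for (i in seq_len(nrow(m))) {
      expect_identical(
        substr(a$body, m$start[i] + 1L, m$end[i]), m$raw[i]
      )
    }
    longer <- parse_article(paste(body, "and later ERX123."), article_id = "o")
    m2 <- extract_accession_mentions(longer)
    expect_true(all(m$raw %in% m2$raw))
    expect_gt(nrow(m2), nrow(m))
  }
})

test_that("primer-pair grammar accepts stated variants and requires both sides", {
  yes <- c(
    "515F/806R", "primers F515 and R806", "515 F with 806 R",
    "Fwd515 and Rev806", "515Fwd paired with 806Rev",
    "barcoded 515F and 806Rb primers", "forward 515 and reverse 806"
  )
  for (t in yes) {
    expect_true(detect_primer_pair_mentions(t)$matched, info = t)
  }
  no <- c("515F only, no reverse primer named", "806R alone",
          "primers 341F and 805R", "")
  for (t in no) {
    expect_false(detect_primer_pair_mentions(t)$matched, info = t)
  }
  v <- detect_primer_pair_mentions("515F/806R")
  expect_setequal(v$variants, c("515F", "806R"))
})

test_that("keyword detection finds 16S, platforms and alternative databases", {
  a <- parse_article(
    paste(
      "We sequenced the 16S rRNA gene V4 region (515F and 806R) on an",
      "Illumina MiSeq; older data used 454 pyrosequencing.",
      "Additional data in MG-RAST; protected data under DBGAP accession phs001."
    ),
    article_id = "k1"
  )
  k <- detect_keywords(a)
  expect_true(k$mentions_16s)
  expect_true(k$primer_pair_515_806)
  expect_setequal(strsplit(k$platforms, ";")[[1]], c("Illumina", "454"))
  expect_true(k$alt_mgrast)
  expect_true(k$alt_dbgap)
  expect_false(k$alt_qiita)
})

test_that("corpus table has one row per mention and one row for mention-less articles", {
  arts <- list(
    parse_article("Runs SRR000001, SRR000002, SRR000003.", article_id = "a1"),
    parse_article("Data in figshare only.", article_id = "a2")
  )
  tbl <- corpus_to_table(arts)
  expect_equal(sum(tbl$article_id == "a1"), 3L)
  expect_equal(sum(tbl$article_id == "a2"), 1L)
  expect_true(is.na(tbl$accession[tbl$article_id == "a2"]))
  expect_true(tbl$insdc_absent[tbl$article_id == "a2"])
  expect_false(any(tbl$insdc_absent[tbl$article_id == "a1"]))

  dup <- list(arts[[1]], parse_article("x SRP1", article_id = "a1"))
  expect_error(corpus_to_table(dup), class = "ampliaudit_duplicate_id")
})

test_that("mine_articles reads a directory, applies the DOI map and skips bad files", {
  dir <- withr::local_tempdir()
  writeLines("Reads under SRP000111. 16S rRNA.", file.path(dir, "one.txt"))
  writeLines(tei_fixture(), file.path(dir, "two.xml"))
  writeLines("<TEI><broken", file.path(dir, "bad.xml"))
  readr::write_tsv(
    tibble::tibble(article_id = c("one", "two"), doi = c("10.1/a", "10.1/b"),
                   year = c(2016L, 2018L)),
    file.path(dir, "map.tsv")
  )
  expect_warning(
    tbl <- mine_articles(dir, doi_map = file.path(dir, "map.tsv")),
    "unparseable"
  )
  expect_setequal(unique(tbl$article_id), c("one", "two"))
  expect_equal(tbl$doi[tbl$article_id == "one"][1], "10.1/a")
  expect_equal(tbl$year[tbl$article_id == "two"][1], 2018L)
})
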