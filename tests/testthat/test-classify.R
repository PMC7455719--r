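test_that("the fault ledger is assembled mechanically from the three audits", {
  text <- tibble::tibble(
    study_id = c("a", "b", "c", "d", "e", "f"),
    has_insdc = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    has_placeholder = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    alt_db = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    year = 2016L
  )
  metadata <- tibble::tibble(
    study_id = c("a", "d", "e"),
    accession_found = c(TRUE, TRUE, FALSE),
    data_public = c(TRUE, FALSE, FALSE),
    metadata_public = c(TRUE, TRUE, FALSE),
    strategy_is_amplicon = c(TRUE, TRUE, NA)
  )
  fastq <- tibble::tibble(
    study_id = "a",
    has_quality_fault = FALSE, primers_present = TRUE,
    paired_label_inconsistent = FALSE, single_file_multisample = FALSE
  )
  ledger <- assemble_fault_ledger(text, metadata, fastq)
  get <- function(id) ledger[ledger$study_id == id, ]

  # clean study with primers retained
  avail <- c(
    "loc_not_deposited", "loc_alternative_db", "dep_accession_not_found",
    "dep_data_private", "dep_metadata_private", "dep_placeholder_accession",
    "fmt_not_demultiplexed", "fmt_no_quality_scores"
  )
  expect_true(get("a")$fmt_primers_present)
  expect_false(any(unlist(get("a")[avail])))
  expect_true(get("b")$loc_alternative_db)
  expect_false(get("b")$loc_not_deposited)
  expect_true(get("c")$loc_not_deposited)
  expect_true(get("d")$dep_data_private)
  expect_true(get("e")$dep_accession_not_found)
  expect_true(get("f")$dep_placeholder_accession)
  # upstream faults suppress downstream flags
  expect_false(any(get("c")$fmt_primers_present, get("d")$fmt_primers_present))

  expect_error(
    assemble_fault_ledger(
      text, dplyr::mutate(metadata, study_id = c("a", "zz", "e")), fastq
    ),
    class = "ampliaudit_id_mismatch"
  )
})

test_that("fate classification is exclusive with availability faults dominating", {
  base <- ledger_from_counts(1, c())
  expect_equal(as.character(classify_fate(base)$fate), "reusable")

  one <- function(flag) {
    l <- ledger_from_counts(1, c())
    l[[flag]] <- TRUE
    as.character(classify_fate(l)$fate)
  }
  expect_equal(one("fmt_primers_present"), "partially_usable")
  expect_equal(one("lab_strategy_mislabeled"), "partially_usable")
  expect_equal(one("lab_paired_mislabeled"), "partially_usable")
  expect_equal(one("fmt_not_demultiplexed"), "not_available")
  expect_equal(one("fmt_no_quality_scores"), "not_available")
  expect_equal(one("loc_not_deposited"), "not_available")
  expect_equal(one("dep_metadata_private"), "not_available")

  both <- ledger_from_counts(1, c())
  both$fmt_primers_present <- TRUE
  both$dep_data_private <- TRUE
  expect_equal(as.character(classify_fate(both)$fate), "not_available")
})

test_that("adding any single fault never improves a study's fate", {
  set.seed(19)
  rank <- function(f) match(as.character(f), c("reusable", "partially_usable",
                                               "not_available"))
  for (rep in 1:40) {
    l <- ledger_from_counts(1, c())
    flags_on <- sample(FAULT_FLAGS, sample(0:3, 1))
    for (f in flags_on) l[[f]] <- TRUE
    before <- rank(classify_fate(l)$fate)
    for (f in FAULT_FLAGS[!unlist(l[1, FAULT_FLAGS])]) {
      l2 <- l
      l2[[f]] <- TRUE
      expect_gte(rank(classify_fate(l2)$fate), before)
    }
  }
})

test_that("fates conserve the corpus and summaries are permutation-invariant", {
  set.seed(29)
  counts <- c(loc_not_deposited = 30, dep_data_private = 10,
              fmt_primers_present = 25, lab_paired_mislabeled = 15)
  ledger <- classify_fate(ledger_from_counts(120, counts))
  fate_counts <- table(ledger$fate)
  expect_equal(sum(fate_counts), 120L)
  expect_equal(unname(fate_counts["not_available"]), 40L)
  expect_equal(unname(fate_counts["partially_usable"]), 40L)
  expect_equal(unname(fate_counts["reusable"]), 40L)

  s1 <- summarize_corpus(ledger)
  s2 <- summarize_corpus(ledger[sample(nrow(ledger)), ])
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("summaries reproduce half-up rounded reported percentages", {
  lg <- classify_fate(ledger_from_counts(2015, c(dep_data_private = 146)))
  s <- summarize_corpus(lg)
  expect_equal(s$percent[s$metric == "dep_data_private"], 7.2)
  expect_equal(s$percent[s$metric == "loc_not_deposited"], 0)

  expect_equal(percent_of(216, 635), 34.0)
  expect_equal(percent_of(162, 635), 25.5)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(25.55, 1), 25.6)
  expect_equal(round_half_up(-2.5), -3)

  expect_warning(s0 <- summarize_corpus(lg, denominator = 0), "denominator")
  expect_equal(nrow(s0), 0L)
})

test_that("the trend test matches its closed form and known edge cases", {
  flat <- chi2_trend(c(10, 10), c(20, 20))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)

  # equals the two-sample Pearson statistic without continuity correction
  pearson <- function(x, n) {
    a <- x[1]; b <- n[1] - x[1]; c <- x[2]; d <- n[2] - x[2]
    N <- sum(n)
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  tt <- chi2_trend(c(33, 172), c(56, 214))
  expect_equal(tt$chi2, pearson(c(33, 172), c(56, 214)), tolerance = 1e-12)

  # cross-check against the reference implementation in stats
  ref <- suppressWarnings(stats::prop.trend.test(c(5, 12, 20), c(50, 50, 50)))
  mine <- chi2_trend(c(5, 12, 20), c(50, 50, 50))
  expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  # affine score transforms leave the statistic unchanged
  set.seed(43)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    n <- sample(20:80, k, replace = TRUE)
    x <- vapply(n, function(ni) sample(1:(ni - 1), 1), integer(1))
    s <- seq_len(k)
    t1 <- chi2_trend(x, n, s)
    t2 <- chi2_trend(x, n, 3.7 * s - 11)
    expect_equal(t1$chi2, t2$chi2, tolerance = 1e-10)
  }

  expect_error(chi2_trend(c(0, 0), c(10, 10)), class = "ampliaudit_degenerate")
  expect_error(chi2_trend(c(10, 10), c(10, 10)), class = "ampliaudit_degenerate")
  expect_error(chi2_trend(c(1, 2), c(10, 10), scores = c(2, 2)),
               class = "ampliaudit_degenerate")
})

test_that("tidy and glance return broom-style one-row summaries", {
  tt <- chi2_trend(c(13, 38), c(56, 214), scores = c(2015, 2018))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "df", "p.value", "method"))
  gl <- glance(tt)
  expect_equal(gl$n_groups, 2L)
  expect_equal(gl$n_total, 270L)
})

test_that("count_by_year aggregates flags for trend input", {
  lg <- ledger_from_counts(40, c(dep_data_private = 10),
                           years = rep(c(2015L, 2016L), each = 20))
  yr <- count_by_year(lg, "dep_data_private")
  expect_equal(yr$year, c(2015L, 2016L))
  expect_equal(sum(yr$x), 10)
  expect_equal(yr$n, c(20L, 20L))
})

test_that("reports are written deterministically with provenance", {
  dir <- withr::local_tempdir()
  lg <- classify_fate(ledger_from_counts(50, c(loc_not_deposited = 5)))
  s <- summarize_corpus(lg)
  trends <- tidy(chi2_trend(c(5, 10), c(40, 40)))
  p1 <- write_audit_report(s, trends, file.path(dir, "r1"))
  p2 <- write_audit_report(s, trends, file.path(dir, "r2"))
  for (f in c("summary.csv", "trends.csv", "report.json")) {
    expect_identical(
      readLines(file.path(dir, "r1", f)),
      readLines(file.path(dir, "r2", f))
    )
  }
  rep <- jsonlite::read_json(file.path(dir, "r1", "report.json"))
  expect_equal(rep$tool$package, "ampliaudit")
  expect_true(!is.null(rep$config$max_error_rate))
  # empty trend set omits the trend section
  p3 <- write_audit_report(s, NULL, file.path(dir, "r3"))
  expect_false(file.exists(file.path(dir, "r3", "trends.csv")))
  rep3 <- jsonlite::read_json(file.path(dir, "r3", "report.json"))
  expect_null(rep3$trends)
})

test_that("plot functions return ggplot objects", {
  lg <- classify_fate(ledger_from_counts(60, c(
    loc_not_deposited = 10, fmt_primers_present = 12
  )))
  expect_s3_class(plot_fate_summary(lg), "ggplot")
  s <- summarize_corpus(lg)
  expect_s3_class(plot_flag_prevalence(s), "ggplot")
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
})
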