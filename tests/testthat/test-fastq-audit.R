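cfg <- audit_config()

test_that("read sampling takes the first n records and handles short or gzipped files", {
  set.seed(21)
  seqs <- replicate(1500, random_dna_string(60))
  path <- write_fastq_fixture(seqs)
  s <- sample_reads(path, n = 1000)
  expect_equal(nrow(s), 1000L)
  expect_equal(s$sequence[1], seqs[1])

  short <- write_fastq_fixture(seqs[1:10])
  expect_equal(nrow(sample_reads(short, n = 1000)), 10L)

  gz <- write_fastq_fixture(seqs[1:50], gz = TRUE)
  expect_equal(sample_reads(gz, n = 1000)$sequence, toupper(seqs[1:50]))
})

test_that("malformed FASTQ records raise errors naming the record index", {
  dir <- withr::local_tempdir()
  # sequence/quality length mismatch in record 2
  p1 <- file.path(dir, "mismatch.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", strrep("A", 90), "+", strrep("I", 89)), p1)
  expect_error(sample_reads(p1), "record 2", class = "ampliaudit_bad_fastq")

  p2 <- file.path(dir, "truncated.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), p2)
  expect_error(sample_reads(p2), "record 2", class = "ampliaudit_bad_fastq")

  # wrapped (multi-line) FASTQ is rejected by the 4-line dialect
  p3 <- file.path(dir, "wrapped.fastq")
  writeLines(c("@r1", "ACGT", "ACGT", "+", "IIIIIIII"), p3)
  expect_error(sample_reads(p3), class = "ampliaudit_bad_fastq")

  expect_error(sample_reads(file.path(dir, "nope.fastq")),
               class = "ampliaudit_missing_file")
})

test_that("quality check fails on constant or out-of-range characters, order-invariantly", {
  set.seed(5)
  seqs <- replicate(30, random_dna_string(40))
  varied <- vapply(seqs, function(s) {
    intToUtf8(sample(53:73, nchar(s), replace = TRUE))
  }, character(1))
  ok <- sample_reads(write_fastq_fixture(seqs, varied))
  expect_true(check_quality_scores(ok)$has_standard_qualities)

  const <- sample_reads(write_fastq_fixture(seqs, strrep("#", nchar(seqs))))
  qc <- check_quality_scores(const)
  expect_false(qc$has_standard_qualities)
  expect_equal(qc$distinct_quality_chars, 1L)

  weird <- varied
  substr(weird[3], 5, 5) <- intToUtf8(7)  # a control byte is not Phred+33
  bad <- sample_reads(write_fastq_fixture(seqs, weird))
  expect_false(check_quality_scores(bad)$has_standard_qualities)
  expect_true(check_quality_scores(bad)$out_of_range)

  shuffled <- ok[sample(nrow(ok)), ]
  expect_equal(check_quality_scores(shuffled), check_quality_scores(ok))

  expect_error(check_quality_scores(ok[0, ]), class = "ampliaudit_empty_sample")
})

test_that("primer matching honors IUPAC codes, the mismatch budget and minimum overlap", {
  fwd <- "GTGYCAGCMGCCGCGGTAA"
  # identity at offset 0
  read <- paste0("GTGCCAGCAGCCGCGGTAA", random_dna_string(30))
  m <- find_primer(read, fwd, config = cfg)
  expect_equal(m$read_offset, 0L)
  expect_equal(m$mismatches, 0L)

  # M matches A or C
  loose <- audit_config(min_overlap = 6)
  expect_equal(find_primer("ACGTAAGGGCCC", "ACGTMA", config = loose)$mismatches, 0L)
  expect_equal(find_primer("ACGTCAGGGCCC", "ACGTMA", config = loose)$mismatches, 0L)

  # 3 mismatches in a 10-base terminal overlap exceed floor(0.2*10)=2
  primer10 <- "ACGTACGTAC"
  tail3 <- "TCGTTCGTTC"  # 3 mismatches against primer10
  read3 <- paste0(strrep("G", 40), tail3)
  expect_equal(nrow(find_primer(read3, primer10, config = cfg)), 0L)
  # 2 mismatches in the same overlap are accepted
  tail2 <- "TCGTTCGTAC"
  hit2 <- find_primer(paste0(strrep("G", 40), tail2), primer10, config = cfg)
  expect_equal(hit2$overlap_len, 10L)
  expect_equal(hit2$mismatches, 2L)

  # a perfect 9-base terminal overlap is below the minimum and rejected
  read9 <- paste0(strrep("T", 41), substr(primer10, 1, 9))
  expect_equal(nrow(find_primer(read9, primer10, config = cfg)), 0L)

  # N in the read matches by default, counts as mismatch in strict mode
  readN <- paste0("GTGNCAGCNGCCGCGGTAA", strrep("C", 30))
  expect_equal(find_primer(readN, fwd, config = cfg)$mismatches, 0L)
  expect_equal(
    find_primer(readN, fwd, config = audit_config(strict_grammar = TRUE))$mismatches,
    2L
  )
})

test_that("matching is symmetric under reverse complementation", {
  set.seed(31)
  revcomp_chr <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  primers <- default_primers()$sequence
  for (rep in 1:20) {
    p <- sample(primers, 1)
    read <- paste0(gsub("[^ACGT]", "A", p), random_dna_string(40))
    if (rep %% 2 == 0) {
      substr(read, 3, 3) <- "T"  # perturb one base
    }
    fwdhit <- find_primer(read, p, "forward", cfg)
    rchit <- find_primer(revcomp_chr(read), p, "reverse_complement", cfg)
    expect_equal(nrow(fwdhit), nrow(rchit))
    if (nrow(fwdhit) == 1) {
      expect_equal(fwdhit$mismatches, rchit$mismatches)
      expect_equal(
        rchit$read_offset,
        nchar(read) - fwdhit$read_offset - fwdhit$overlap_len
      )
    }
  }
})

test_that("the matcher agrees with the exhaustive oracle on seeded random reads", {
  set.seed(77)
  primers <- default_primers()
  for (rep in 1:60) {
    len <- sample(20:100, 1)
    read <- random_dna_string(len)
    if (rep %% 3 == 0) {
      # plant a primer realization at a random offset to exercise matches
      p <- sample(primers$sequence, 1)
      real <- vapply(
        strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(p, "")[[1]]], ""),
        function(s) sample(s, 1), character(1)
      )
      off <- sample(0:max(0, len - nchar(p)), 1)
      substr(read, off + 1, off + nchar(p)) <- paste(real, collapse = "")
    }
    for (pi in seq_len(nrow(primers))) {
      for (ori in c("forward", "reverse_complement")) {
        got <- find_primer(read, primers$sequence[pi], ori, cfg)
        want <- oracle_find_primer(read, primers$sequence[pi], ori)
        if (is.null(want)) {
          expect_equal(nrow(got), 0L, info = read)
        } else {
          expect_equal(got$read_offset, want$offset, info = read)
          expect_equal(got$mismatches, want$mismatches, info = read)
          expect_equal(got$overlap_len, want$overlap, info = read)
        }
      }
    }
  }
})

test_that("primer prevalence counts planted reads and thresholds the study flag", {
  set.seed(13)
  fwd <- default_primers()$sequence[1]
  concrete <- gsub("Y", "C", gsub("M", "A", fwd))
  planted <- replicate(50, paste0(concrete, random_dna_string(80)))
  clean <- replicate(50, strrep("T", 100))  # no primer window fits the budget
  s <- sample_reads(write_fastq_fixture(c(planted, clean)))
  prev <- audit_primers(s, config = cfg)
  expect_equal(sum(prev$per_read$matched[1:50]), 50L)
  expect_equal(prev$frac_reads_with_any_primer, 0.5)
  expect_true(prev$study_flag_primers_present)  # >= at the default 0.5

  all_clean <- audit_primers(sample_reads(write_fastq_fixture(clean)), config = cfg)
  expect_equal(all_clean$frac_reads_with_any_primer, 0)
  expect_false(all_clean$study_flag_primers_present)
})

test_that("barcode inference reads prefixes before the primer match", {
  set.seed(17)
  fwd <- default_primers()$sequence[1]
  concrete <- gsub("Y", "T", gsub("M", "C", fwd))

  at_zero <- replicate(20, paste0(concrete, random_dna_string(60)))
  r0 <- infer_barcodes(sample_reads(write_fastq_fixture(at_zero)), config = cfg)
  expect_equal(r0$n_reads_with_barcode, 0L)

  one_bc <- replicate(20, paste0("ACGTACGT", concrete, random_dna_string(50)))
  r1 <- infer_barcodes(sample_reads(write_fastq_fixture(one_bc)), config = cfg)
  expect_equal(r1$n_reads_with_barcode, 20L)
  expect_equal(r1$distinct_barcodes, 1L)

  bcs <- vapply(1:12, function(i) random_dna_string(8), character(1))
  many <- vapply(rep(bcs, 2), function(b) {
    paste0(b, concrete, random_dna_string(50))
  }, character(1))
  r12 <- infer_barcodes(sample_reads(write_fastq_fixture(many)), config = cfg)
  expect_equal(r12$distinct_barcodes, 12L)
  expect_lte(r12$distinct_barcodes, r12$n_reads_with_barcode)
})

test_that("layout and demultiplexing checks follow the file-count rules", {
  expect_equal(
    check_layout_consistency(c("PAIRED", "PAIRED", "SINGLE"), c(2L, 1L, 1L)),
    c(TRUE, FALSE, TRUE)
  )
  expect_error(check_layout_consistency("MATE_PAIR", 2L),
               class = "ampliaudit_bad_layout")

  expect_true(check_demultiplexing(1, 24)$single_file_multisample)
  expect_false(check_demultiplexing(24, 24)$single_file_multisample)
  expect_false(check_demultiplexing(1, 1)$single_file_multisample)
})

test_that("the manifest audit aggregates per-study faults", {
  set.seed(23)
  dir <- withr::local_tempdir()
  fwd <- default_primers()$sequence[1]
  concrete <- gsub("Y", "C", gsub("M", "C", fwd))
  mkfile <- function(name, seqs, quals = NULL) {
    if (is.null(quals)) {
      quals <- vapply(nchar(seqs), function(n) {
        intToUtf8(sample(53:73, n, replace = TRUE))
      }, character(1))
    }
    writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n", quals),
               file.path(dir, name))
    name
  }
  clean_reads <- function(n) replicate(n, random_dna_string(80))
  mkfile("s1_r1.fastq", clean_reads(30))
  mkfile("s1_r2.fastq", clean_reads(30))
  # s2: paired label but one file; constant qualities; primer-bearing reads
  s2 <- replicate(30, paste0(concrete, random_dna_string(60)))
  mkfile("s2_r1.fastq", s2, strrep("#", nchar(s2)))
  # s3: one pooled file for 4 declared samples with 4 barcodes
  bcs <- vapply(1:4, function(i) random_dna_string(8), character(1))
  s3 <- vapply(rep(bcs, 8), function(b) paste0(b, concrete, random_dna_string(50)),
               character(1))
  mkfile("s3_pool.fastq", s3)

  manifest <- tibble::tibble(
    study_accession = c("SRP000001", "SRP000001", "SRP000002", "SRP000003"),
    run_accession = c("SRR000001", "SRR000001", "SRR000011", "SRR000021"),
    file_path = c("s1_r1.fastq", "s1_r2.fastq", "s2_r1.fastq", "s3_pool.fastq"),
    mate_role = c("forward", "reverse", "forward", "single"),
    declared_layout = c("PAIRED", "PAIRED", "PAIRED", "SINGLE"),
    n_samples_declared = c(2L, 2L, 1L, 4L)
  )
  out <- audit_fastq_manifest(manifest, cfg, root = dir)
  s <- out$per_study
  s1 <- s[s$study_accession == "SRP000001", ]
  expect_false(s1$has_quality_fault)
  expect_false(s1$primers_present)
  expect_false(s1$paired_label_inconsistent)
  s2r <- s[s$study_accession == "SRP000002", ]
  expect_true(s2r$has_quality_fault)
  expect_true(s2r$primers_present)
  expect_true(s2r$paired_label_inconsistent)
  expect_false(s2r$single_file_multisample)
  s3r <- s[s$study_accession == "SRP000003", ]
  expect_true(s3r$single_file_multisample)
  expect_equal(s3r$distinct_barcodes, 4L)
  expect_false(s3r$paired_label_inconsistent)
})
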