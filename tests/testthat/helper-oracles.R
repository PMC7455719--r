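# Independent oracles and fixture builders used across the suite. The
# oracles deliberately share no code with the implementation: the primer
# oracle enumerates every alignment with character-level IUPAC set
# membership, and the mention oracle slides over every text position
# without regular expressions.

# Exhaustive primer scorer: every offset, mismatches recomputed from IUPAC
# set membership. Returns list(offset, mismatches, overlap) or NULL.
oracle_find_primer <- function(read, primer, orientation = "forward",
                               rate = 0.2, min_overlap = 10) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  if (orientation == "reverse_complement") {
    primer <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(primer))
    )
  }
  r <- strsplit(read, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  n <- length(r)
  L <- length(p)
  if (n < min_overlap || L < min_overlap) return(NULL)
  best <- NULL
  for (off in 0:(n - min_overlap)) {
    w <- min(L, n - off)
    mism <- 0L
    for (t in seq_len(w)) {
      base <- r[off + t]
      ok <- base == "N" ||
        grepl(base, iupac[[p[t]]], fixed = TRUE)
      if (!ok) mism <- mism + 1L
    }
    if (mism <= floor(rate * w)) {
      if (is.null(best) || mism < best$mismatches) {
        best <- list(offset = off, mismatches = mism, overlap = w)
      }
    }
  }
  best
}

# Regex-free accession mention scanner sliding over all positions.
# Longest prefix wins at each position; word boundaries enforced.
oracle_scan_mentions <- function(text, max_digits = 9) {
  simple <- c("SAMND", "SAMN", "SAME", "ERP", "DRP", "SRP", "ERS", "ERX",
              "DRX", "SRX", "DRR", "SRR", "ERZ", "DRZ", "SRZ")
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  is_alnum <- function(ch) length(ch) == 1 && grepl("[A-Za-z0-9]", ch)
  out <- list()
  for (i in seq_len(n)) {
    if (i > 1 && is_alnum(chars[i - 1])) next
    # candidate prefixes at this position, longest first
    cands <- character()
    if (i + 4 <= n && paste(chars[i:(i + 2)], collapse = "") == "PRJ" &&
        grepl("[A-Z]", chars[i + 3]) && grepl("[A-Z]", chars[i + 4])) {
      cands <- c(cands, paste(chars[i:(i + 4)], collapse = ""))
    }
    for (pre in simple) {
      lp <- nchar(pre)
      if (i + lp - 1 <= n &&
          paste(chars[i:(i + lp - 1)], collapse = "") == pre) {
        cands <- c(cands, pre)
      }
    }
    if (i + 2 <= n && paste(chars[i:(i + 2)], collapse = "") == "PRJ") {
      cands <- c(cands, "PRJ")
    }
    cands <- cands[order(-nchar(cands))]
    for (pre in cands) {
      j <- i + nchar(pre)
      nd <- 0L
      while (j <= n && grepl("[0-9]", chars[j]) && nd < max_digits) {
        nd <- nd + 1L
        j <- j + 1L
      }
      if (nd < 1) next
      if (j <= n && is_alnum(chars[j])) next
      out[[length(out) + 1]] <- data.frame(
        raw = paste(chars[i:(j - 1)], collapse = ""),
        prefix = pre, start = i - 1L, end = j - 1L,
        stringsAsFactors = FALSE
      )
      break
    }
  }
  if (length(out) == 0) {
    return(data.frame(raw = character(), prefix = character(),
                      start = integer(), end = integer()))
  }
  do.call(rbind, out)
}

# Write a 4-line FASTQ file (optionally gzipped) from sequence/quality
# vectors; returns the path.
write_fastq_fixture <- function(seqs, quals = NULL, gz = FALSE,
                                dir = tempdir()) {
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n) {
      paste(rep("I", n), collapse = "")
    }, character(1))
  }
  path <- tempfile("reads", tmpdir = dir,
                   fileext = if (gz) ".fastq.gz" else ".fastq")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n", quals), con)
  close(con)
  path
}

random_dna_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Minimal TEI document with a title, abstract, body and bibliography.
tei_fixture <- function(title = "Soil communities",
                        abstract = "We sequenced 16S rRNA amplicons.",
                        body = "Reads were deposited under SRP123456.",
                        bibl = "Old study under ERP000999.") {
  sprintf(
    '<?xml version="1.0" encoding="UTF-8"?>
<TEI xmlns="http://www.tei-c.org/ns/1.0">
  <teiHeader><fileDesc><titleStmt><title>%s</title></titleStmt></fileDesc>
    <profileDesc><abstract><p>%s</p></abstract></profileDesc>
  </teiHeader>
  <text>
    <body><div><p>%s</p></div></body>
    <back><listBibl><bibl>%s</bibl></listBibl></back>
  </text>
</TEI>', title, abstract, body, bibl
  )
}

# A small in-memory run table fixture.
run_table_fixture <- function() {
  tibble::tibble(
    run_accession = sprintf("SRR%06d", 1:6),
    study_accession = rep(c("SRP000001", "SRP000002"), each = 3),
    biosample_accession = sprintf("SAMN%08d", 1:6),
    library_strategy = c(rep("AMPLICON", 3), "WGS", "AMPLICON", "AMPLICON"),
    library_layout = c(rep("SINGLE", 3), rep("PAIRED", 3)),
    platform = "ILLUMINA",
    n_files = c(1L, 1L, 1L, 2L, 2L, 2L),
    is_public_data = TRUE,
    is_public_metadata = TRUE,
    spots = 1000L
  )
}
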