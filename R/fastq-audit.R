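# Auditing of sampled raw reads: strict 4-line FASTQ ingestion, quality
# score presence, IUPAC-degenerate primer detection (mismatch-only, minimum
# overlap), barcode inference, layout and demultiplexing checks.

#' Sample the first reads of a FASTQ file
#'
#' Reads the first `n` records of a plain or gzip-compressed FASTQ file, in
#' file order (fewer if the file is shorter), enforcing the strict 4-line
#' record dialect emitted by sequence archives: wrapped/multi-line FASTQ is
#' rejected, a record whose sequence and quality lengths differ or whose
#' marker lines are malformed raises an error naming the record index.
#'
#' @param path FASTQ file (`.fastq` or `.fastq.gz`).
#' @param n Maximum number of reads to take (default 1000, the audit's
#'   sampling depth).
#' @param run_accession,mate_role Provenance attached as attributes.
#' @return Tibble with columns `read_index`, `sequence` (uppercased, over
#'   `A`/`C`/`G`/`T`/`N`), `quality`; attributes `run_accession`,
#'   `mate_role`, `n_requested`.
#' @export
sample_reads <- function(path, n = 1000L, run_accession = NA_character_,
                         mate_role = c("single", "forward", "reverse")) {
  mate_role <- match.arg(mate_role)
  stopifnot(n >= 1L)
  if (!file.exists(path)) {
    audit_abort(sprintf("FASTQ file not found: %s", path),
                class = "ampliaudit_missing_file")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, n = 4L * n, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    audit_abort(
      sprintf("truncated FASTQ record %d in %s", length(lines) %/% 4L + 1L, path),
      class = "ampliaudit_bad_fastq"
    )
  }
  n_rec <- length(lines) %/% 4L
  if (n_rec == 0L) {
    return(structure(
      tibble::tibble(read_index = integer(), sequence = character(),
                     quality = character()),
      run_accession = run_accession, mate_role = mate_role,
      n_requested = as.integer(n)
    ))
  }
  headers <- lines[seq(1L, by = 4L, length.out = n_rec)]
  seqs <- lines[seq(2L, by = 4L, length.out = n_rec)]
  plus <- lines[seq(3L, by = 4L, length.out = n_rec)]
  quals <- lines[seq(4L, by = 4L, length.out = n_rec)]
  bad <- which(
    !startsWith(headers, "@") | !startsWith(plus, "+") |
      nchar(seqs) != nchar(quals) | nchar(seqs) == 0L |
      !grepl("^[ACGTNacgtn]+$", seqs)
  )
  if (length(bad) > 0) {
    audit_abort(
      sprintf("malformed FASTQ record %d in %s", bad[1], path),
      class = "ampliaudit_bad_fastq"
    )
  }
  structure(
    tibble::tibble(
      read_index = seq_len(n_rec),
      sequence = toupper(seqs),
      quality = quals
    ),
    run_accession = run_accession, mate_role = mate_role,
    n_requested = as.integer(n)
  )
}

#' Check for standard quality scores
#'
#' A read sample fails the quality-presence check when (a) any quality
#' character falls outside the printable Phred+33 range `!`..`~`, or (b) the
#' whole sample realizes at most one distinct quality character (a constant
#' dummy string carries no quality information). The check is
#' order-invariant over reads.
#'
#' @param sample Read tibble from [sample_reads()] (nonempty).
#' @return One-row tibble: `has_standard_qualities`,
#'   `distinct_quality_chars`, `out_of_range`.
#' @export
check_quality_scores <- function(sample) {
  stopifnot(is.data.frame(sample), "quality" %in% names(sample))
  if (nrow(sample) == 0) {
    audit_abort("cannot assess quality of an empty read sample",
                class = "ampliaudit_empty_sample")
  }
  codes <- utf8ToInt(paste(sample$quality, collapse = ""))
  distinct <- length(unique(codes))
  out_of_range <- any(codes < 33L | codes > 126L)
  tibble::tibble(
    has_standard_qualities = !out_of_range && distinct > 1L,
    distinct_quality_chars = distinct,
    out_of_range = out_of_range
  )
}

# Scan one encoded read against one encoded primer over every alignment
# offset (including 3'-overhanging ones), returning mismatch counts per
# offset. Bits: A=1 C=2 G=4 T=8; a primer code matches a read base iff the
# bitwise AND is nonzero.
.scan_offsets <- function(read_bits, primer_bits, max_error_rate, min_overlap) {
  n <- length(read_bits)
  L <- length(primer_bits)
  if (n < min_overlap || L < min_overlap) return(NULL)
  offs <- 0:(n - min_overlap)
  idx <- outer(seq_len(L), offs, `+`)
  padded <- c(read_bits, rep(NA_integer_, L))
  windows <- matrix(padded[idx], nrow = L)
  mism_mat <- bitwAnd(windows, primer_bits) == 0L  # bitwAnd drops dim
  dim(mism_mat) <- dim(windows)
  mismatches <- colSums(mism_mat, na.rm = TRUE)
  overlap <- pmin(L, n - offs)
  budget <- floor(max_error_rate * overlap)
  ok <- mismatches <= budget
  list(offsets = offs, mismatches = as.integer(mismatches),
       overlap = as.integer(overlap), ok = ok)
}

.encode_read <- function(seq, strict) {
  bits <- encode_iupac(seq, n_matches_any = !strict)
  bits[is.na(bits)] <- 0L
  bits
}

#' Find a degenerate primer in a read
#'
#' IUPAC-aware, mismatch-only primer search: the primer (or its reverse
#' complement) is slid over every alignment against the read, including
#' 3'-overhanging ones, keeping alignments with overlap of at least
#' `config$min_overlap` bases. A primer code matches a read base iff the
#' base belongs to the code's set; an `N` in the read matches any code (and
#' counts as a match) unless `config$strict_grammar` is set, in which case
#' it always counts as a mismatch. An alignment of overlap `w` is accepted
#' when its mismatch count is at most `floor(config$max_error_rate * w)`;
#' among accepted alignments the one with fewest mismatches wins, ties going
#' to the smallest read offset. No indels are considered.
#'
#' @param sequence Read sequence (character scalar over A/C/G/T/N).
#' @param primer Degenerate primer sequence (IUPAC codes), or a one-row
#'   data frame with columns `name`, `sequence`.
#' @param orientation `"forward"` or `"reverse_complement"` (search for the
#'   primer's reverse complement).
#' @param config An [audit_config()] supplying `max_error_rate`,
#'   `min_overlap`, `strict_grammar`.
#' @return One-row tibble `primer_name`, `orientation`, `read_offset`
#'   (0-based), `overlap_len`, `mismatches` — or a zero-row tibble when no
#'   alignment satisfies the budget.
#' @export
#' @examples
#' cfg <- audit_config()
#' find_primer("GTGCCAGCAGCCGCGGTAAAACGT", "GTGYCAGCMGCCGCGGTAA", config = cfg)
find_primer <- function(sequence, primer,
                        orientation = c("forward", "reverse_complement"),
                        config = audit_config()) {
  orientation <- match.arg(orientation)
  if (is.data.frame(primer)) {
    stopifnot(nrow(primer) == 1L)
    primer_name <- primer$name
    primer <- primer$sequence
  } else {
    primer_name <- "primer"
  }
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(primer))
  searched <- if (orientation == "reverse_complement") revcomp(primer) else primer
  scan <- .scan_offsets(
    .encode_read(sequence, config$strict_grammar),
    encode_iupac(searched),
    config$max_error_rate, config$min_overlap
  )
  empty <- tibble::tibble(
    primer_name = character(), orientation = character(),
    read_offset = integer(), overlap_len = integer(), mismatches = integer()
  )
  if (is.null(scan) || !any(scan$ok)) return(empty)
  cand <- which(scan$ok)
  best <- cand[order(scan$mismatches[cand], scan$offsets[cand])][1]
  tibble::tibble(
    primer_name = primer_name, orientation = orientation,
    read_offset = scan$offsets[best], overlap_len = scan$overlap[best],
    mismatches = scan$mismatches[best]
  )
}

# Best primer match per read across all primers and both orientations.
# Returns one row per read; unmatched reads have NA match columns.
.best_matches <- function(sample, primers, config) {
  combos <- tidyr::expand_grid(
    primers, orientation = c("forward", "reverse_complement")
  )
  combos$searched <- ifelse(
    combos$orientation == "reverse_complement",
    vapply(combos$sequence, revcomp, character(1)),
    combos$sequence
  )
  combo_bits <- lapply(combos$searched, encode_iupac)
  nr <- nrow(sample)
  matched <- logical(nr)
  primer_name <- rep(NA_character_, nr)
  orientation <- rep(NA_character_, nr)
  read_offset <- rep(NA_integer_, nr)
  overlap_len <- rep(NA_integer_, nr)
  mismatches <- rep(NA_integer_, nr)
  for (i in seq_len(nr)) {
    read_bits <- .encode_read(sample$sequence[i], config$strict_grammar)
    for (j in seq_len(nrow(combos))) {
      scan <- .scan_offsets(read_bits, combo_bits[[j]],
                            config$max_error_rate, config$min_overlap)
      if (is.null(scan)) next
      cand <- which(scan$ok)
      if (length(cand) == 0) next
      k <- cand[order(scan$mismatches[cand], scan$offsets[cand])][1]
      if (!matched[i] ||
          scan$mismatches[k] < mismatches[i] ||
          (scan$mismatches[k] == mismatches[i] &&
           scan$offsets[k] < read_offset[i])) {
        matched[i] <- TRUE
        primer_name[i] <- combos$name[j]
        orientation[i] <- combos$orientation[j]
        read_offset[i] <- scan$offsets[k]
        overlap_len[i] <- scan$overlap[k]
        mismatches[i] <- scan$mismatches[k]
      }
      # a full-overlap perfect match at offset 0 cannot be beaten
      if (matched[i] && mismatches[i] == 0L && read_offset[i] == 0L) break
    }
  }
  tibble::tibble(
    read_index = sample$read_index, matched = matched,
    primer_name = primer_name, orientation = orientation,
    read_offset = read_offset, overlap_len = overlap_len,
    mismatches = mismatches
  )
}

#' Audit primer prevalence in a read sample
#'
#' Searches every sampled read for the forward and reverse degenerate
#' primers in both orientations and summarizes prevalence. The study-level
#' "primers present" flag fires when the fraction of reads carrying any
#' primer reaches `config$primer_prevalence_threshold` (default 0.5), which
#' keeps the flag robust to small contaminating minorities.
#'
#' @param sample Read tibble from [sample_reads()].
#' @param primers Tibble with columns `name`, `sequence` (default the
#'   config's pair).
#' @param config An [audit_config()].
#' @return List of class `primer_prevalence`: `per_read` (best match per
#'   read), `counts` (reads matched per primer/orientation),
#'   `frac_reads_with_any_primer`, `study_flag_primers_present`, `n_reads`.
#' @export
audit_primers <- function(sample, primers = NULL, config = audit_config()) {
  stopifnot(is.data.frame(sample), "sequence" %in% names(sample))
  if (is.null(primers)) primers <- config$primers
  if (nrow(sample) == 0) {
    return(structure(
      list(
        per_read = tibble::tibble(), counts = tibble::tibble(),
        frac_reads_with_any_primer = NA_real_,
        study_flag_primers_present = FALSE, n_reads = 0L
      ),
      class = "primer_prevalence"
    ))
  }
  per_read <- .best_matches(sample, primers, config)
  counts <- per_read |>
    dplyr::filter(.data$matched) |>
    dplyr::count(.data$primer_name, .data$orientation, name = "n_reads_matched")
  frac <- mean(per_read$matched)
  structure(
    list(
      per_read = per_read,
      counts = counts,
      frac_reads_with_any_primer = frac,
      study_flag_primers_present = frac >= config$primer_prevalence_threshold,
      n_reads = nrow(sample)
    ),
    class = "primer_prevalence"
  )
}

#' @export
print.primer_prevalence <- function(x, ...) {
  cat(sprintf(
    "<primer_prevalence: %d reads, %.1f%% with a primer, study flag %s>\n",
    x$n_reads, 100 * x$frac_reads_with_any_primer,
    x$study_flag_primers_present
  ))
  invisible(x)
}

#' Infer candidate barcodes upstream of primer matches
#'
#' For every read whose best primer match starts at offset `k` with
#' `config$barcode_len[1] <= k <= config$barcode_len[2]`, the read prefix
#' before the primer is a candidate barcode. Reads whose primer sits at
#' offset 0 contribute none. The number of distinct candidate barcodes per
#' study corroborates a non-demultiplexed (pooled multi-sample) upload.
#'
#' @param sample Read tibble from [sample_reads()].
#' @param primers Primer tibble (`name`, `sequence`).
#' @param config An [audit_config()].
#' @param prevalence Optional precomputed [audit_primers()] result for
#'   `sample`, to avoid re-scanning.
#' @return List of class `barcode_report`: `n_reads_with_barcode`,
#'   `distinct_barcodes`, `barcode_length_range`, `barcodes` (count table).
#' @export
infer_barcodes <- function(sample, primers = NULL, config = audit_config(),
                           prevalence = NULL) {
  if (is.null(primers)) primers <- config$primers
  if (is.null(prevalence)) prevalence <- audit_primers(sample, primers, config)
  lo <- config$barcode_len[1]
  hi <- config$barcode_len[2]
  hits <- prevalence$per_read
  hits <- hits[!is.na(hits$read_offset) &
                 hits$read_offset >= lo & hits$read_offset <= hi, ,
               drop = FALSE]
  barcodes <- if (nrow(hits) > 0) {
    substr(sample$sequence[match(hits$read_index, sample$read_index)],
           1L, hits$read_offset)
  } else {
    character()
  }
  tab <- if (length(barcodes) > 0) {
    dplyr::count(tibble::tibble(barcode = barcodes), .data$barcode, name = "n")
  } else {
    tibble::tibble(barcode = character(), n = integer())
  }
  structure(
    list(
      n_reads_with_barcode = length(barcodes),
      distinct_barcodes = length(unique(barcodes)),
      barcode_length_range = c(lo, hi),
      barcodes = tab
    ),
    class = "barcode_report"
  )
}

#' @export
print.barcode_report <- function(x, ...) {
  cat(sprintf(
    "<barcode_report: %d reads with a %d-%d nt barcode, %d distinct>\n",
    x$n_reads_with_barcode, x$barcode_length_range[1],
    x$barcode_length_range[2], x$distinct_barcodes
  ))
  invisible(x)
}

#' Check declared layout against deposited files
#'
#' A run declared `PAIRED` is consistent only when at least two read files
#' (forward and reverse mates) were deposited for it; `SINGLE` runs are
#' always consistent. Vectorized over runs.
#'
#' @param declared_layout Character vector over `SINGLE`/`PAIRED`.
#' @param files_per_run Integer vector of deposited read files per run.
#' @return Logical vector `consistent`.
#' @export
#' @examples
#' check_layout_consistency(c("PAIRED", "PAIRED", "SINGLE"), c(2, 1, 1))
check_layout_consistency <- function(declared_layout, files_per_run) {
  stopifnot(length(declared_layout) == length(files_per_run))
  if (!all(declared_layout %in% c("SINGLE", "PAIRED"))) {
    audit_abort("declared_layout must be SINGLE or PAIRED",
                class = "ampliaudit_bad_layout")
  }
  declared_layout == "SINGLE" | files_per_run >= 2L
}

#' Check the demultiplexing state of a study
#'
#' Flags studies that expose exactly one sequence file while declaring more
#' than one sample: archives require demultiplexed (per-sample) uploads, so
#' a single pooled file renders the data unusable. A barcode report with
#' more than one distinct barcode corroborates the pooled state.
#'
#' @param n_files_study Total sequence files exposed by the study.
#' @param n_samples_declared Declared number of samples (>= 1).
#' @param barcode_report Optional [infer_barcodes()] result.
#' @return One-row tibble: `single_file_multisample`,
#'   `barcode_corroborated` (`NA` when no report supplied).
#' @export
#' @examples
#' check_demultiplexing(1, 24)
#' check_demultiplexing(24, 24)
check_demultiplexing <- function(n_files_study, n_samples_declared,
                                 barcode_report = NULL) {
  stopifnot(n_samples_declared >= 1, n_files_study >= 0)
  tibble::tibble(
    single_file_multisample = n_files_study == 1L && n_samples_declared > 1L,
    barcode_corroborated = if (is.null(barcode_report)) NA else
      barcode_report$distinct_barcodes > 1L
  )
}

#' Audit the FASTQ files of a study manifest
#'
#' Runs the full raw-read audit over a manifest: per file, sampling and the
#' quality-score check; per study, primer prevalence over all sampled reads,
#' paired-layout consistency per run, the demultiplexing check, and barcode
#' inference for single-file studies.
#'
#' @param manifest Tibble with columns `study_accession`, `run_accession`,
#'   `file_path`, `mate_role` (single/forward/reverse), `declared_layout`,
#'   `n_samples_declared` — or a path to such a TSV.
#' @param config An [audit_config()]; `config$n_reads` reads are sampled per
#'   file.
#' @param root Directory against which relative `file_path`s are resolved
#'   (defaults to the manifest's directory when `manifest` is a path, else
#'   the working directory).
#' @return List with `per_file` and `per_study` tibbles. `per_study` has
#'   columns `study_accession`, `n_runs`, `n_files`, `n_samples_declared`,
#'   `has_quality_fault`, `frac_reads_with_primer`, `primers_present`,
#'   `paired_label_inconsistent`, `single_file_multisample`,
#'   `distinct_barcodes`.
#' @export
audit_fastq_manifest <- function(manifest, config = audit_config(),
                                 root = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (is.null(root)) root <- dirname(manifest)
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  if (is.null(root)) root <- "."
  need <- c("study_accession", "run_accession", "file_path", "mate_role",
            "declared_layout", "n_samples_declared")
  stopifnot(is.data.frame(manifest), all(need %in% names(manifest)))
  if (nrow(manifest) == 0) {
    return(list(per_file = tibble::tibble(), per_study = tibble::tibble()))
  }
  paths <- ifelse(
    grepl("^(/|[A-Za-z]:)", manifest$file_path),
    manifest$file_path,
    file.path(root, manifest$file_path)
  )

  samples <- purrr::map(seq_len(nrow(manifest)), function(i) {
    sample_reads(paths[i], n = config$n_reads,
                 run_accession = manifest$run_accession[i],
                 mate_role = manifest$mate_role[i])
  })
  per_file <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    qc <- check_quality_scores(samples[[i]])
    tibble::tibble(
      study_accession = manifest$study_accession[i],
      run_accession = manifest$run_accession[i],
      file_path = manifest$file_path[i],
      mate_role = manifest$mate_role[i],
      n_reads_sampled = nrow(samples[[i]]),
      has_standard_qualities = qc$has_standard_qualities,
      distinct_quality_chars = qc$distinct_quality_chars
    )
  })

  per_study <- manifest |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$study_accession) |>
    dplyr::group_map(function(g, key) {
      study <- key$study_accession
      reads <- dplyr::bind_rows(samples[g$.row])
      reads$read_index <- seq_len(nrow(reads))
      prevalence <- audit_primers(reads, config$primers, config)
      files_per_run <- g |>
        dplyr::count(.data$run_accession, .data$declared_layout,
                     name = "n_files")
      paired_bad <- !all(check_layout_consistency(
        files_per_run$declared_layout, files_per_run$n_files
      ))
      n_files <- nrow(g)
      n_samples <- g$n_samples_declared[1]
      barcodes <- if (n_files == 1L) {
        infer_barcodes(reads, config$primers, config, prevalence = prevalence)
      } else {
        NULL
      }
      demux <- check_demultiplexing(n_files, n_samples, barcodes)
      quality_fault <- any(!per_file$has_standard_qualities[
        per_file$study_accession == study
      ])
      tibble::tibble(
        study_accession = study,
        n_runs = dplyr::n_distinct(g$run_accession),
        n_files = n_files,
        n_samples_declared = n_samples,
        has_quality_fault = quality_fault,
        frac_reads_with_primer = prevalence$frac_reads_with_any_primer,
        primers_present = prevalence$study_flag_primers_present,
        paired_label_inconsistent = paired_bad,
        single_file_multisample = demux$single_file_multisample,
        distinct_barcodes = if (is.null(barcodes)) NA_integer_ else
          barcodes$distinct_barcodes
      )
    }) |>
    dplyr::bind_rows()

  list(per_file = per_file, per_study = per_study)
}
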