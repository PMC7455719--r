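# Synthetic test-world generation: article texts with planted accession
# mentions, a mock repository (run + biosample tables), FASTQ files with
# planted faults, and the ground-truth fault ledger.

# Exclusive "availability" faults: a study carries at most one of these,
# and none of the formatting/labeling faults, because absent or private
# data exposes no reads to audit.
EXCLUSIVE_FLAGS <- c(
  "loc_not_deposited", "loc_alternative_db", "dep_placeholder_accession",
  "dep_accession_not_found", "dep_metadata_private", "dep_data_private"
)
DOWNSTREAM_FLAGS <- c(
  "fmt_not_demultiplexed", "fmt_no_quality_scores", "fmt_primers_present",
  "lab_strategy_mislabeled", "lab_paired_mislabeled"
)

#' Specification of a synthetic audit corpus
#'
#' Bundles the study count, year range, per-flag fault prevalences, read
#' geometry and seed from which [generate_corpus()] builds a complete
#' offline test world. Default prevalences mirror the fault shares observed
#' in published audits of V3-V4 amplicon studies (19% never deposited, 6.3%
#' in alternative databases, about 6% deposition errors, 8.9% pooled
#' single-file uploads, 11.5% retained primers, and labeling faults around
#' 8-12%).
#'
#' @param n_studies Number of studies.
#' @param years Integer vector of publication years to draw from.
#' @param prevalence Named numeric vector/list over [FAULT_FLAGS]; missing
#'   flags default to 0. Prevalences of the mutually exclusive availability
#'   faults must sum to at most 1.
#' @param reads_per_run Reads written per FASTQ file.
#' @param read_length Read length in bases.
#' @param barcode_length Barcode length planted in pooled files.
#' @param n_samples Samples (= runs) per ordinary study.
#' @param n_samples_multiplexed Samples pooled into a single-file study.
#' @param paired_fraction Fraction of ordinary studies with paired layout.
#' @param range_fraction Fraction of deposited studies whose article cites
#'   its runs as an accession range instead of a project accession.
#' @param mode `"fixed_count"` (exact planted counts via seeded shuffling;
#'   what acceptance-style checks use) or `"sampled"` (independent
#'   Bernoulli draws per flag).
#' @param seed RNG seed; identical (spec, seed) yields byte-identical
#'   outputs.
#' @return List of class `corpus_spec`.
#' @export
corpus_spec <- function(n_studies = 200L,
                        years = 2015:2019,
                        prevalence = c(
                          loc_not_deposited = 0.19,
                          loc_alternative_db = 0.063,
                          dep_placeholder_accession = 0.011,
                          dep_accession_not_found = 0.02,
                          dep_metadata_private = 0.015,
                          dep_data_private = 0.015,
                          fmt_not_demultiplexed = 0.089,
                          fmt_no_quality_scores = 0.011,
                          fmt_primers_present = 0.115,
                          lab_strategy_mislabeled = 0.083,
                          lab_paired_mislabeled = 0.117
                        ),
                        reads_per_run = 100L,
                        read_length = 150L,
                        barcode_length = 8L,
                        n_samples = 3L,
                        n_samples_multiplexed = 8L,
                        paired_fraction = 0.3,
                        range_fraction = 0.15,
                        mode = c("fixed_count", "sampled"),
                        seed = 1L) {
  mode <- match.arg(mode)
  prev <- stats::setNames(rep(0, length(FAULT_FLAGS)), FAULT_FLAGS)
  prevalence <- unlist(prevalence)
  unknown <- setdiff(names(prevalence), FAULT_FLAGS)
  if (length(unknown) > 0) {
    audit_abort(sprintf("unknown fault flag(s) in prevalence: %s",
                        paste(unknown, collapse = ", ")),
                class = "ampliaudit_bad_spec")
  }
  prev[names(prevalence)] <- prevalence
  stopifnot(all(prev >= 0), all(prev <= 1))
  if (sum(prev[EXCLUSIVE_FLAGS]) > 1) {
    audit_abort("exclusive fault prevalences sum to more than 1",
                class = "ampliaudit_bad_spec")
  }
  stopifnot(n_studies >= 1, reads_per_run >= 1, read_length >= 30,
            barcode_length >= 4, barcode_length <= 30,
            n_samples >= 1, n_samples_multiplexed >= 2,
            paired_fraction >= 0, paired_fraction <= 1,
            range_fraction >= 0, range_fraction <= 1)
  structure(
    list(
      n_studies = as.integer(n_studies), years = as.integer(years),
      prevalence = prev, reads_per_run = as.integer(reads_per_run),
      read_length = as.integer(read_length),
      barcode_length = as.integer(barcode_length),
      n_samples = as.integer(n_samples),
      n_samples_multiplexed = as.integer(n_samples_multiplexed),
      paired_fraction = paired_fraction, range_fraction = range_fraction,
      mode = mode, seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

# Draw the planted flag matrix honoring exclusivity. Returns a tibble of
# logical flag columns, n_studies rows.
.draw_flags <- function(spec) {
  n <- spec$n_studies
  flags <- tibble::as_tibble(
    stats::setNames(replicate(length(FAULT_FLAGS), rep(FALSE, n),
                              simplify = FALSE), FAULT_FLAGS)
  )
  if (spec$mode == "fixed_count") {
    counts <- stats::setNames(
      as.integer(round_half_up(spec$prevalence * n)), FAULT_FLAGS
    )
    if (sum(counts[EXCLUSIVE_FLAGS]) > n) {
      audit_abort("infeasible prevalence combination: exclusive counts exceed n",
                  class = "ampliaudit_bad_spec")
    }
    order <- sample.int(n)
    at <- 0L
    for (flag in EXCLUSIVE_FLAGS) {
      k <- counts[[flag]]
      if (k > 0) flags[[flag]][order[(at + 1L):(at + k)]] <- TRUE
      at <- at + k
    }
    pool <- if (at >= n) integer(0) else order[(at + 1L):n]
    for (flag in DOWNSTREAM_FLAGS) {
      k <- counts[[flag]]
      if (k > length(pool)) {
        audit_abort(
          sprintf("infeasible prevalence: %s needs %d clean studies, %d left",
                  flag, k, length(pool)),
          class = "ampliaudit_bad_spec"
        )
      }
      if (k > 0) flags[[flag]][pool[sample.int(length(pool), k)]] <- TRUE
    }
  } else {
    p_excl <- spec$prevalence[EXCLUSIVE_FLAGS]
    draw <- sample(
      c(EXCLUSIVE_FLAGS, "none"), n, replace = TRUE,
      prob = c(p_excl, 1 - sum(p_excl))
    )
    for (flag in EXCLUSIVE_FLAGS) flags[[flag]] <- draw == flag
    clean <- draw == "none"
    for (flag in DOWNSTREAM_FLAGS) {
      flags[[flag]] <- clean & stats::runif(n) < spec$prevalence[[flag]]
    }
  }
  # a pooled legacy file physically contains barcode+primer reads, so the
  # primer flag is implied for non-demultiplexed studies
  flags$fmt_primers_present <- flags$fmt_primers_present |
    flags$fmt_not_demultiplexed
  # single-run pooled uploads cannot simultaneously exhibit a per-run
  # paired-file mismatch
  flags$lab_paired_mislabeled <- flags$lab_paired_mislabeled &
    !flags$fmt_not_demultiplexed
  flags
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Resolve a degenerate IUPAC sequence to a concrete realization, each code
# drawn uniformly from its base set.
realize_iupac <- function(seq) {
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(toupper(seq), "")[[1]]], "")
  paste(vapply(sets, function(s) sample(s, 1L), character(1)), collapse = "")
}

.healthy_quality <- function(len) {
  intToUtf8(sample(53:73, len, replace = TRUE))
}

# One read: optional barcode prefix, optional realized primer, random rest.
.make_read <- function(spec, primer = NULL, barcode = "") {
  core <- if (is.null(primer)) "" else realize_iupac(primer)
  pre <- paste0(barcode, core)
  rest <- spec$read_length - nchar(pre)
  paste0(pre, if (rest > 0) .random_dna(rest) else "")
}

.write_fastq <- function(path, reads, qualities) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  txt <- paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qualities)
  writeLines(txt, con)
}

#' Generate one synthetic article text
#'
#' Produces a deterministic templated article for a single study: a 16S
#' rRNA sentence, a platform sentence, a 515F/806R primer sentence, filler
#' method text, the accession sentence dictated by the study's planted
#' faults (a project accession, a run range, a placeholder, an
#' alternative-database mention, or nothing), and a references section
#' containing a decoy accession that a correct parser must strip.
#'
#' @param truth One-row tibble of the study's ground truth (flags plus
#'   `study_id`, `study_accession`, `first_run`, `last_run`, `alt_db_name`,
#'   `cites_range`, `platform_name`).
#' @return Character scalar: the article's plain text.
#' @export
generate_article <- function(truth) {
  stopifnot(is.data.frame(truth), nrow(truth) == 1L)
  accession_sentence <- if (truth$loc_not_deposited) {
    "Sequence data are described in the main text."
  } else if (truth$loc_alternative_db) {
    sprintf("Sequence data are available from the %s database.",
            truth$alt_db_name)
  } else if (truth$dep_placeholder_accession) {
    "Raw reads were deposited in the NCBI SRA under accession SRPXXXXXX."
  } else if (truth$cites_range) {
    sprintf("Raw reads are available under run accessions %s to %s.",
            truth$first_run, truth$last_run)
  } else {
    sprintf("Raw reads were deposited in the NCBI SRA under accession %s.",
            truth$study_accession)
  }
  paste(
    sprintf("Microbial community composition of site %s", truth$study_id),
    "",
    "Abstract",
    paste("We characterized prokaryotic communities by high-throughput",
          "sequencing of the 16S rRNA gene."),
    "",
    "Methods",
    paste("The V4 region of the 16S rRNA gene was amplified with primers",
          "515F and 806R and sequenced on an",
          sprintf("%s instrument.", truth$platform_name)),
    sprintf("DNA was extracted from %d samples following standard protocols.",
            truth$n_samples_declared),
    accession_sentence,
    "",
    "References",
    "1. Doe J. et al. Community survey methods. J. Microb. Methods (2014).",
    "2. Roe R. Archived data reuse, deposited under SRP999999. (2013).",
    sep = "\n"
  )
}

#' Generate a complete synthetic audit world
#'
#' From a [corpus_spec()], generates under `out_dir`: `articles/*.txt`
#' (one templated article per study), `runs.tsv` (mock run-level
#' repository metadata), `biosamples.tsv` (biosample attributes),
#' `fastq/*.fastq.gz` (sampled-size read files with planted faults),
#' `manifest.tsv` (study/run/file manifest for the read audit),
#' `articles.tsv` (article id, DOI, publication year) and
#' `ground_truth.csv` (the planted fault ledger with expected fates).
#'
#' Fault planting: never-deposited and alternative-database studies leave no
#' repository trace; placeholder and unfindable accessions appear only in
#' the article; private studies appear in the run table with public flags
#' off and no read files; mislabeled studies carry a non-AMPLICON library
#' strategy or a PAIRED layout with single files; pooled studies expose one
#' file whose reads carry per-sample barcodes in front of the primer;
#' primer-retaining studies realize the degenerate primer at the read
#' start; quality-stripped studies have a constant quality character.
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with `ground_truth` (tibble), `paths` (named
#'   list of the files written) and `spec`.
#' @export
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (dir.exists(out_dir) &&
      length(list.files(out_dir, all.files = TRUE, no.. = TRUE)) > 0) {
    audit_abort(sprintf("output directory '%s' is not empty", out_dir),
                class = "ampliaudit_bad_output")
  }
  dir.create(file.path(out_dir, "articles"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "fastq"), showWarnings = FALSE)

  withr::with_seed(spec$seed, {
    n <- spec$n_studies
    flags <- .draw_flags(spec)
    deposited <- !(flags$loc_not_deposited | flags$loc_alternative_db |
                     flags$dep_placeholder_accession)
    in_repo <- deposited & !flags$dep_accession_not_found

    truth <- dplyr::bind_cols(
      tibble::tibble(
        study_id = sprintf("study%04d", seq_len(n)),
        study_accession = sprintf("SRP%06d", seq_len(n)),
        year = sample(spec$years, n, replace = TRUE)
      ),
      flags
    )
    truth$n_samples_declared <- ifelse(
      truth$fmt_not_demultiplexed, spec$n_samples_multiplexed, spec$n_samples
    )
    truth$paired <- ifelse(
      truth$lab_paired_mislabeled, TRUE,
      ifelse(truth$fmt_not_demultiplexed, FALSE,
             stats::runif(n) < spec$paired_fraction)
    )
    truth$cites_range <- deposited & !truth$fmt_not_demultiplexed &
      spec$n_samples >= 2 & stats::runif(n) < spec$range_fraction
    truth$alt_db_name <- sample(c("MG-RAST", "figshare", "Qiita"), n,
                                replace = TRUE)
    truth$platform_name <- sample(c("Illumina MiSeq", "Illumina HiSeq",
                                    "454 GS FLX"), n, replace = TRUE,
                                  prob = c(0.6, 0.25, 0.15))

    run_counter <- 0L
    sample_counter <- 0L
    runs <- list()
    biosamples <- list()
    manifest <- list()
    truth$first_run <- NA_character_
    truth$last_run <- NA_character_

    primers <- default_primers()
    fwd <- primers$sequence[primers$name == "515F"]
    rev_ <- primers$sequence[primers$name == "806R"]

    for (i in seq_len(n)) {
      if (!deposited[i]) next
      n_runs <- if (truth$fmt_not_demultiplexed[i]) 1L else spec$n_samples
      run_acc <- sprintf("SRR%06d", run_counter + seq_len(n_runs))
      run_counter <- run_counter + n_runs
      truth$first_run[i] <- run_acc[1]
      truth$last_run[i] <- run_acc[n_runs]
      if (!in_repo[i]) next

      n_samp <- truth$n_samples_declared[i]
      bios_acc <- sprintf("SAMN%08d", sample_counter + seq_len(n_samp))
      sample_counter <- sample_counter + n_samp
      meta_public <- !truth$dep_metadata_private[i]
      data_public <- meta_public && !truth$dep_data_private[i]
      layout <- if (truth$paired[i]) "PAIRED" else "SINGLE"
      strategy <- if (truth$lab_strategy_mislabeled[i]) "WGS" else "AMPLICON"
      platform <- if (grepl("454", truth$platform_name[i])) "LS454" else
        "ILLUMINA"
      files_per_run <- if (!data_public) 0L else
        if (truth$paired[i] && !truth$lab_paired_mislabeled[i]) 2L else 1L

      runs[[length(runs) + 1L]] <- tibble::tibble(
        run_accession = run_acc,
        study_accession = truth$study_accession[i],
        biosample_accession = bios_acc[seq_len(n_runs)],
        library_strategy = strategy,
        library_layout = layout,
        platform = platform,
        n_files = files_per_run,
        is_public_data = data_public,
        is_public_metadata = meta_public,
        spots = spec$reads_per_run
      )
      env <- sample(c("soil", "rhizosphere", "marine water", "human gut"), 1L)
      biosamples[[length(biosamples) + 1L]] <- tibble::tibble(
        study_accession = truth$study_accession[i],
        biosample_accession = rep(bios_acc, each = 2L),
        attribute_name = rep(c("env_material", "collection_year"), n_samp),
        attribute_value = rep(c(env, as.character(truth$year[i])), n_samp)
      )
      if (!data_public) next

      barcodes <- if (truth$fmt_not_demultiplexed[i]) {
        vapply(seq_len(n_samp), function(j) .random_dna(spec$barcode_length),
               character(1))
      } else {
        NULL
      }
      for (r in seq_len(n_runs)) {
        mates <- if (files_per_run == 2L) c("forward", "reverse") else
          if (layout == "PAIRED") "forward" else "single"
        for (m in seq_along(mates)) {
          file_name <- if (length(mates) == 2L) {
            sprintf("%s_%d.fastq.gz", run_acc[r], m)
          } else {
            sprintf("%s.fastq.gz", run_acc[r])
          }
          primer_here <- if (!truth$fmt_primers_present[i]) NULL else
            if (mates[m] == "reverse") rev_ else fwd
          reads <- vapply(seq_len(spec$reads_per_run), function(k) {
            bc <- if (is.null(barcodes)) "" else
              barcodes[(k - 1L) %% n_samp + 1L]
            .make_read(spec, primer = primer_here, barcode = bc)
          }, character(1))
          quals <- if (truth$fmt_no_quality_scores[i]) {
            strrep("#", nchar(reads))
          } else {
            vapply(nchar(reads), .healthy_quality, character(1))
          }
          .write_fastq(file.path(out_dir, "fastq", file_name), reads, quals)
          manifest[[length(manifest) + 1L]] <- tibble::tibble(
            study_accession = truth$study_accession[i],
            run_accession = run_acc[r],
            file_path = file.path("fastq", file_name),
            mate_role = mates[m],
            declared_layout = layout,
            n_samples_declared = n_samp
          )
        }
      }
    }

    for (i in seq_len(n)) {
      writeLines(
        generate_article(truth[i, ]),
        file.path(out_dir, "articles", paste0(truth$study_id[i], ".txt"))
      )
    }
    readr::write_tsv(dplyr::bind_rows(runs), file.path(out_dir, "runs.tsv"))
    readr::write_tsv(dplyr::bind_rows(biosamples),
                     file.path(out_dir, "biosamples.tsv"))
    readr::write_tsv(dplyr::bind_rows(manifest),
                     file.path(out_dir, "manifest.tsv"))
    readr::write_tsv(
      tibble::tibble(
        article_id = truth$study_id,
        doi = paste0("10.9999/synthetic.", truth$study_id),
        year = truth$year
      ),
      file.path(out_dir, "articles.tsv")
    )
    ground_truth <- truth |>
      dplyr::select("study_id", "study_accession", "year",
                    dplyr::all_of(FAULT_FLAGS)) |>
      classify_fate()
    readr::write_csv(ground_truth, file.path(out_dir, "ground_truth.csv"))

    invisible(list(
      ground_truth = ground_truth,
      paths = list(
        articles = file.path(out_dir, "articles"),
        runs = file.path(out_dir, "runs.tsv"),
        biosamples = file.path(out_dir, "biosamples.tsv"),
        manifest = file.path(out_dir, "manifest.tsv"),
        article_meta = file.path(out_dir, "articles.tsv"),
        ground_truth = file.path(out_dir, "ground_truth.csv")
      ),
      spec = spec
    ))
  })
}

#' Build a fault ledger with exact planted counts
#'
#' Constructs a ledger of `n` studies in which each named flag is `TRUE`
#' for exactly the requested number of studies, assigned to disjoint blocks
#' in order; remaining studies are clean. Useful for reproducing reported
#' percentages from printed counts.
#'
#' @param n Number of studies.
#' @param counts Named integer vector over [FAULT_FLAGS]; `sum(counts)`
#'   must not exceed `n`.
#' @param years Optional integer vector recycled over studies.
#' @return A `FaultLedger` tibble.
#' @export
#' @examples
#' ledger_from_counts(2015, c(dep_data_private = 146))
ledger_from_counts <- function(n, counts, years = NA_integer_) {
  stopifnot(n >= 1, all(names(counts) %in% FAULT_FLAGS), all(counts >= 0))
  if (sum(counts) > n) {
    audit_abort("planted counts exceed the corpus size",
                class = "ampliaudit_bad_spec")
  }
  ledger <- tibble::tibble(
    study_id = sprintf("study%05d", seq_len(n)),
    year = rep_len(as.integer(years), n)
  )
  for (flag in FAULT_FLAGS) ledger[[flag]] <- FALSE
  at <- 0L
  for (flag in names(counts)) {
    k <- as.integer(counts[[flag]])
    if (k > 0) ledger[[flag]][(at + 1L):(at + k)] <- TRUE
    at <- at + k
  }
  ledger
}
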