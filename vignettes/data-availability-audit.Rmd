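---
title: "Auditing the availability and reusability of amplicon sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the availability and reusability of amplicon sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliaudit)
```

## The problem

Public sequence archives (the INSDC trio: SRA, ENA, DRA) are the canonical
home for 16S rRNA gene amplicon data, and meta-analyses in microbial ecology
depend on that data being findable and reusable. In practice, a study's data
can be lost to reuse at four places: **location** (never deposited, or
deposited to a platform not designed for archival, such as MG-RAST,
figshare or Qiita), **deposition** (placeholder or unfindable accession
numbers, data or metadata kept private), **formatting** (a single pooled
file uploaded for a multi-sample project, reads stripped of quality scores,
primer/barcode sequence retained in the reads), and **labeling** (amplicon
runs not labeled with the `AMPLICON` library strategy, paired-end labels
without reverse-read files).

`ampliaudit` implements this audit as an offline, fully testable pipeline:
it mines article full texts for accession mentions, audits repository
metadata and sampled raw reads, reduces each study to a boolean *fault
ledger*, and classifies each study's *fate* — `reusable`,
`partially_usable`, or `not_available`.

## Pipeline stages and their assumptions

1. **Text mining** (`parse_article()`, `extract_accession_mentions()`,
   `detect_keywords()`). Accessions are matched case-sensitively with the
   uppercase INSDC prefixes (PRJ with an optional two-letter project
   qualifier, ERP/DRP/SRP, SAME/SAMND/SAMN, ERS, ERX/DRX/SRX, DRR/SRR,
   ERZ/DRZ/SRZ) followed by digits, with word boundaries on both sides.
   Reference and supplementary sections are stripped first — for TEI input
   structurally, for plain text from the last heading matching a small
   case-insensitive list (References, Bibliography, Literature Cited,
   Supplementary …). Grammar-shaped tokens whose digit positions carry
   filler characters (`X`, `#`, `?`) are captured separately as
   *placeholders*: a manuscript that went to press with `SRPXXXXXX` has a
   deposition fault that a digits-only grammar would miss entirely.
2. **Accession resolution** (`validate_accession()`, `detect_ranges()`,
   `expand_range()`). Same-prefix mentions within one article are treated
   as a candidate range spanning their numeric extremes; widths are
   normalized by zero-padding. Ranges of more than 40 accessions are still
   expanded but flagged `needs_manual_check` — the pipeline flags, humans
   verify. A hard cap (default 10,000) guards expansion memory.
3. **Repository audit** (`fetch_run_metadata()`, `audit_study_metadata()`).
   The mandatory provider contract is an offline runinfo-style TSV; *not
   found* (no rows) is kept distinct from *found but private* throughout,
   because the two feed different fault flags. A study is correctly labeled
   only when **every** run carries the exact vocabulary token `AMPLICON`;
   a lenient case-insensitive mode exists but is off by default. Private
   metadata is modeled as a third state: the accession resolves,
   `is_public_metadata` is false, and the strategy judgment is undefined
   (`NA`) rather than false.
4. **Read audit** (`sample_reads()`, `check_quality_scores()`,
   `find_primer()`, `audit_primers()`, `infer_barcodes()`,
   `check_layout_consistency()`, `check_demultiplexing()`). The first 1,000
   reads of each file are sampled in file order. Quality scores are deemed
   missing when any character leaves the printable Phred+33 range or when
   the whole sample realizes at most one distinct character — a constant
   dummy string carries no information. This two-condition rule is this
   package's own operationalization of "lacks standard quality scores".
5. **Classification and statistics** (`assemble_fault_ledger()`,
   `classify_fate()`, `summarize_corpus()`, `chi2_trend()`). See below.

## The primer matcher

Degenerate primer detection is the one genuinely algorithmic primitive and
is implemented directly: the primer (or its reverse complement) is slid
over every alignment against the read, including 3'-overhanging ones, an
alignment of overlap $w$ is accepted when its mismatch count is at most
$\lfloor 0.2\,w \rfloor$ with $w \ge 10$, and among accepted alignments the
fewest mismatches win, ties going to the smallest offset. Matching is
IUPAC-aware via bit sets (a primer code matches a base iff the base belongs
to the code's set); an `N` in the read matches any code by default and
counts as a mismatch only in strict mode, so sequencing ambiguity does not
inflate mismatch counts. Deliberately, **no indels** are considered: a
mismatch-only scorer is deterministic and verifiable against an exhaustive
offset-enumeration oracle, which the test suite does on hundreds of seeded
random reads. The whole read is scanned, not just its ends, since barcodes
displace primers inward. Default primers are the 515F/806R pair in
degenerate IUPAC form (`GTGYCAGCMGCCGCGGTAA` / `GGACTACNVGGGTWTCTAAT`);
they are configuration data, not constants.

Barcodes are inferred as read prefixes upstream of a primer match at
offsets 4–30; the study-level "primers present" flag requires at least half
of the sampled reads to carry a primer (configurable), keeping the flag
robust to chimeric minorities.

## Classification policy

Fates are exclusive and exhaustive. Availability faults dominate: any of
{never deposited, alternative database only, placeholder accession,
accession not found, data private, metadata private, not demultiplexed,
no quality scores} makes a study `not_available`. Otherwise any of
{primers retained, strategy mislabeled, paired label mismatch} makes it
`partially_usable`; otherwise it is `reusable`. Multiple faults within the
partial tier count once. This precedence is the only reading under which
the four reported loss-category percentages are additive, and it makes the
fate ordering monotone: setting any additional fault flag can never move a
study to a better category (a property the test suite checks exhaustively).

One corpus-bookkeeping quirk is worth stating: the published fate counts
for the 635-study V3–V4 subset are 216 + 162 + 256 = 634, one short of the
corpus. The classifier enforces exact conservation, so the reproduction
fixtures plant 634 studies and quote percentages against an explicit
denominator of 635, which `summarize_corpus()` supports directly.

## The trend test

`chi2_trend()` is the score test for a monotone trend of binomial
proportions across ordered groups: with pooled $\bar p$ and scores $s_i$,

$$\chi^2 = \frac{\left(\sum_i s_i x_i - \bar p \sum_i s_i n_i\right)^2}
{\bar p (1-\bar p)\left[\sum_i s_i^2 n_i - (\sum_i s_i n_i)^2 / \sum_i n_i\right]},
\qquad \mathrm{df} = 1,$$

with an upper-tail p-value and no continuity correction anywhere. For two
groups it equals the Pearson chi-squared of the 2×2 table, and it is
invariant under affine transformation of the scores; both properties are
tested against closed forms, and the implementation is cross-checked
against `stats::prop.trend.test()`. Degenerate inputs (pooled proportion 0
or 1, constant scores) raise classed errors rather than returning `NaN`.
Published multi-year trend statistics that depend on unpublished
intermediate-year counts are not reproducible from endpoint counts alone
and are therefore not asserted anywhere.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `max_error_rate` | 0.2 | primer mismatch budget per unit overlap (fraction) |
| `min_overlap` | 10 | minimum primer/read overlap (bases) |
| `barcode_len` | 4–30 | admissible inferred barcode lengths (bases) |
| `n_reads` | 1000 | reads sampled per FASTQ file |
| `range_auto_threshold` | 40 | accession-range size above which manual review is flagged |
| `max_digits` | 9 | maximum digits after an accession prefix (6 in strict mode) |
| `primer_prevalence_threshold` | 0.5 | read fraction for the study-level primer flag |
| `optional_field_threshold` | 0.25 | study fraction for "popular optional" metadata fields |

The strict-grammar mode (`strict_grammar = TRUE`) restores the six-digit
accession limit for replication-style runs; the default of nine digits
exists because modern run accessions routinely exceed six digits and a
replication-faithful grammar would silently truncate them.

## The synthetic world generator

`generate_corpus()` builds, from a seed and a prevalence map, a complete
offline test world: templated plain-text articles (16S sentence, platform
sentence, 515F/806R primer sentence, an accession sentence dictated by the
planted faults, and a references section containing a decoy accession that
a correct parser must strip), a runinfo-style run table, biosample
attributes, gzipped FASTQ files with planted faults, a manifest, and the
ground-truth ledger with expected fates. Two drawing modes exist:
`fixed_count` plants exactly `round(prevalence × n)` studies per flag via
seeded shuffling (used by the acceptance-style checks, removing Monte-Carlo
noise), and `sampled` draws independent Bernoulli flags.

Structural choices a reader should know:

* Availability faults (location + deposition) are mutually exclusive per
  study and exclude formatting/labeling faults. A study whose data is
  absent or private exposes no reads, so a formatting fault planted there
  could never be recovered; the fate precedence rule makes this restriction
  information-preserving.
* A pooled (non-demultiplexed) upload physically consists of
  barcode + primer + insert reads, so the primer-present flag is implied
  for such studies and the ground truth records it; pooled single-run
  studies likewise cannot exhibit a per-run paired-file mismatch.
* Healthy quality strings are drawn per position from Phred+33 offsets
  20–40, so they pass the two-condition quality rule non-trivially;
  quality-stripped studies use a constant `#`.
* Degenerate primer positions are realized uniformly at random per read,
  exercising the IUPAC matcher rather than a single concrete sequence.
* Default prevalences mirror the fault shares observed in published audits
  of V3–V4 amplicon studies; default geometry is 100 reads of 150 nt per
  run, 3 samples per ordinary study, 8 pooled samples with 8-nt barcodes,
  publication years 2015–2019. These sizes make a 200-study world generate
  and audit in about a minute on one CPU while every flag remains
  represented; the test suite uses 12–40-study worlds for the faster
  checks.

What the generator does **not** emulate: real biological sequence content
(reads are random DNA apart from planted structure), archive-mirror quirks,
PDF/OCR noise in article text, and live-database drift. Passing the
recovery tests therefore demonstrates that the audit logic is exact on
cleanly planted faults — not that real-world mining achieves perfect
recall, which also depends on document conversion quality outside this
package's scope.

## Numerical and edge-case choices

* All reported percentages use half-up rounding (`round_half_up()`), not
  banker's rounding, at 1 decimal by default (0 decimals available to match
  whole-percent reporting).
* The non-deposition extrapolation is `round(k/n × pool)`, half-up; the
  pool size is always an explicit input, never a built-in constant.
* FASTQ ingestion accepts the strict 4-line dialect only (what archives
  export); wrapped records, length mismatches and truncated records raise
  errors naming the record index.
* `SAMND` (as listed in the prefix vocabulary) and `SAMN` are both
  accepted and flagged distinctly; ENA biosample accessions of the
  `SAMEA…` form are outside the stated grammar (`SAME` + digits) and are a
  known limitation.
* Alternative-database mentions are always recorded together with an
  `insdc_absent` context flag, rather than only being searched when no
  accession exists — strictly more information, and replication-style
  filtering remains a downstream selection.
* Studies without a publication year are excluded from trend tests only;
  they still classify and summarize.

## Limitations

The audit flags; it does not judge. Manual-curation steps of the original
protocol (verifying large ranges, confirming edge-case accessions on the
web portal) are represented as flags for review, not automated decisions.
Live EDirect-style retrieval is out of contract — the offline TSV provider
is the tested surface, and a live snapshot should be recorded to that
format. Indel-tolerant primer matching (as an aligner-backed trimmer would
do) is a possible extension, not the default.
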