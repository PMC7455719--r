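# Internal numeric and sequence helpers shared across modules.

#' Round half away from zero
#'
#' Classical "half-up" rounding at a fixed number of decimal digits, used for
#' all reported percentages. `base::round()` rounds half to even, which does
#' not reproduce conventionally reported survey percentages (e.g. 25.55 must
#' report as 25.6).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.5)   # 3, not 2
#' round_half_up(40.35, 1)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator
#'
#' @param count,denominator Non-negative counts; `denominator > 0`.
#' @param digits Reporting precision (decimal digits), half-up rounded.
#' @return Numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' percent_of(146, 2015)       # 7.2
#' percent_of(216, 635)        # 34.0
#' percent_of(469, 2656, 0)    # 18
percent_of <- function(count, denominator, digits = 1) {
  stopifnot(all(denominator > 0))
  round_half_up(100 * count / denominator, digits)
}

# Bit encoding of IUPAC nucleotide codes: A=1, C=2, G=4, T=8; degenerate
# codes are unions. Derived from Biostrings' published code map so the two
# can never drift apart.
.iupac_bits_table <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  bits <- vapply(
    strsplit(unname(map), ""),
    function(bases) sum(base_bit[bases]),
    integer(1)
  )
  stats::setNames(as.integer(bits), names(map))
})

# Encode a nucleotide string as an integer bit vector. Unknown characters
# encode as NA. `n_matches_any = FALSE` encodes read 'N' as 0 so it can never
# satisfy a bitwise AND (strict mode of the primer matcher).
encode_iupac <- function(seq, n_matches_any = TRUE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bits <- unname(.iupac_bits_table[chars])
  if (!n_matches_any) bits[chars == "N"] <- 0L
  bits
}

# IUPAC-aware reverse complement of a character string.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Abort with a classed condition so callers can test on error class.
audit_abort <- function(msg, class) {
  rlang::abort(msg, class = class)
}
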