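# DNA alphabet utilities: IUPAC matching, reverse complement, frame-aware
# translation. Target sequences must be concrete (A/C/G/T); IUPAC ambiguity
# codes are legal only in PAM patterns.

.IUPAC_SETS <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Normalize a DNA string
#'
#' Upper-cases the input and converts U to T. By default any character outside
#' A/C/G/T is rejected: the matching method requires concrete alleles, so
#' ambiguity codes are only legal in PAM patterns (`pattern = TRUE`).
#'
#' @param x character vector of DNA strings.
#' @param pattern logical; if TRUE, IUPAC ambiguity codes are allowed.
#' @param what label used in error messages.
#' @return normalized character vector.
#' @export
normalize_dna <- function(x, pattern = FALSE, what = "sequence") {
  x <- chartr("u", "t", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  alphabet <- if (pattern) names(.IUPAC_SETS) else c("A", "C", "G", "T")
  bad <- regexpr(sprintf("[^%s]", paste(alphabet, collapse = "")), x)
  if (any(bad > 0 & nzchar(x))) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid character '%s' at position %d of %s",
                 substr(x[i], bad[i], bad[i]), bad[i], what), call. = FALSE)
  }
  x
}

#' Match a site against an IUPAC pattern
#'
#' Position-wise comparison of a concrete DNA site against an IUPAC degenerate
#' pattern of the same length (N matches any base, R matches A/G, ...).
#'
#' @param pattern IUPAC pattern (single string).
#' @param site concrete DNA string(s) of the same length; vectorized.
#' @return logical vector, one element per site.
#' @examples
#' iupac_match("NGG", "AGG")
#' iupac_match("NNGRRT", "TTGAGT")
#' iupac_match("TTTV", "TTTT")
#' @export
iupac_match <- function(pattern, site) {
  pattern <- normalize_dna(pattern, pattern = TRUE, what = "pattern")
  site <- normalize_dna(site, what = "site")
  if (any(nchar(site) != nchar(pattern)))
    stop("pattern and site must have equal length", call. = FALSE)
  pat <- strsplit(pattern, "")[[1]]
  out <- rep(TRUE, length(site))
  for (k in seq_along(pat)) {
    ok <- substr(site, k, k) %in% .IUPAC_SETS[[pat[k]]]
    out <- out & ok
  }
  out
}

#' Reverse complement
#'
#' @param seq character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_dna(seq)
  if (length(seq) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- NULL
  # DNAStringSet cannot hold empty strings uniformly across versions; guard:
  out[!nzchar(seq)] <- ""
  out
}

.complement_base <- function(b) unname(.COMPLEMENT[b])

#' Translate a coding sequence
#'
#' Translates complete codons starting at `frame_offset` (0, 1 or 2 skipped
#' bases before the first full codon) using the standard nuclear genetic code;
#' stop codons are rendered '*' and a trailing partial codon is dropped.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param frame_offset integer in 0:2.
#' @return single protein string.
#' @examples
#' translate_cds("ATGAAA")        # "MK"
#' translate_cds("TATGAAA", 1)    # "MK"
#' translate_cds("ACTCTA")        # "TL"
#' @export
translate_cds <- function(sequence, frame_offset = 0) {
  sequence <- normalize_dna(sequence)
  stopifnot(length(sequence) == 1, frame_offset %in% 0:2)
  n <- nchar(sequence)
  n_codons <- (n - frame_offset) %/% 3
  if (n_codons <= 0) return("")
  starts <- frame_offset + 1 + 3 * (seq_len(n_codons) - 1)
  codons <- substring(sequence, starts, starts + 2)
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# 1-based codon start for the codon containing position `pos`, or NA when the
# position falls before the frame offset or in a trailing partial codon.
.codon_start_at <- function(pos, frame_offset, seq_len) {
  if (pos <= frame_offset) return(NA_integer_)
  start <- frame_offset + 3 * ((pos - frame_offset - 1) %/% 3) + 1
  if (start + 2 > seq_len) return(NA_integer_)
  start
}
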