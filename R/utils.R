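# internal helpers shared across modules

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_canonical_peptide <- function(x) {
  !is.na(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGT]*$", x)
}

#' @importFrom Biostrings DNAStringSet reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide sequences to peptides
#'
#' Standard genetic code, frame 1, no ambiguity handling. Sequences whose
#' length is not a multiple of 3 yield `NA`.
#'
#' @param nt character vector of nucleotide sequences (A/C/G/T).
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(nt) {
  out <- rep(NA_character_, length(nt))
  ok <- !is.na(nt) & nchar(nt) %% 3L == 0L & is_dna(nt)
  full <- ok & nchar(nt) > 0L
  if (any(full)) {
    out[full] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[full]),
      no.init.codon = TRUE
    ))
  }
  out[ok & nchar(nt) == 0L] <- ""
  out
}

# Hamming distance between equal-length strings x (vector) and y (scalar).
hamming_to <- function(x, y) {
  ny <- nchar(y)
  yr <- charToRaw(y)
  vapply(x, function(s) {
    if (is.na(s) || nchar(s) != ny) return(NA_integer_)
    sum(charToRaw(s) != yr)
  }, integer(1), USE.NAMES = FALSE)
}

# count occurrences of fixed motif in each string (overlapping)
count_motif <- function(x, motif) {
  vapply(
    x,
    function(s) length(gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]) *
      (regexpr(motif, s, fixed = TRUE) > 0),
    numeric(1),
    USE.NAMES = FALSE
  )
}

# TRUE if string contains motif on either strand
has_motif_either_strand <- function(x, motifs) {
  if (length(motifs) == 0 || length(x) == 0) return(rep(FALSE, length(x)))
  hits <- rep(FALSE, length(x))
  for (m in motifs) {
    hits <- hits | grepl(m, x, fixed = TRUE) | grepl(revcomp(m), x, fixed = TRUE)
  }
  hits
}

`%||%` <- function(x, y) if (is.null(x)) y else x
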