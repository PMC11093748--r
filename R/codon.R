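# Mouse codon usage (relative synonymous frequencies, ~2 s.f., Kazusa-style).
# Only the relative weights within each amino acid matter for sampling.
mouse_codon_usage <- function() {
  tab <- c(
    A = "GCC:0.38,GCT:0.29,GCA:0.23,GCG:0.10",
    R = "AGA:0.22,AGG:0.22,CGG:0.19,CGC:0.17,CGA:0.12,CGT:0.09",
    N = "AAC:0.57,AAT:0.43",
    D = "GAC:0.56,GAT:0.44",
    C = "TGC:0.52,TGT:0.48",
    Q = "CAG:0.75,CAA:0.25",
    E = "GAG:0.60,GAA:0.40",
    G = "GGC:0.33,GGA:0.26,GGG:0.23,GGT:0.18",
    H = "CAC:0.59,CAT:0.41",
    I = "ATC:0.50,ATT:0.34,ATA:0.16",
    L = "CTG:0.39,CTC:0.20,CTT:0.13,TTG:0.13,CTA:0.08,TTA:0.07",
    K = "AAG:0.61,AAA:0.39",
    M = "ATG:1.0",
    F = "TTC:0.56,TTT:0.44",
    P = "CCT:0.31,CCC:0.31,CCA:0.28,CCG:0.10",
    S = "AGC:0.24,TCC:0.22,TCT:0.19,AGT:0.15,TCA:0.14,TCG:0.05",
    T = "ACC:0.35,ACA:0.29,ACT:0.25,ACG:0.10",
    W = "TGG:1.0",
    Y = "TAC:0.57,TAT:0.43",
    V = "GTG:0.46,GTC:0.25,GTT:0.17,GTA:0.12"
  )
  rows <- lapply(names(tab), function(aa) {
    parts <- strsplit(strsplit(tab[[aa]], ",")[[1]], ":")
    tibble::tibble(
      aa = aa,
      codon = vapply(parts, `[`, "", 1),
      weight = as.numeric(vapply(parts, `[`, "", 2))
    )
  })
  dplyr::bind_rows(rows)
}

codon_table_to_list <- function(codon_table) {
  split(codon_table[c("codon", "weight")], codon_table$aa)
}

#' Back-translate peptides into nucleotide inserts
#'
#' Codons are drawn at random weighted by codon usage (mouse by default),
#' deterministically for a given `seed`. The result always translates back
#' to the input peptide exactly. Forbidden restriction motifs (checked on
#' both strands) are removed by resampling only the codons overlapping an
#' occurrence; if a motif cannot be avoided within `max_attempts` resampling
#' rounds the function aborts.
#'
#' @param peptide character vector of peptides (20-letter alphabet; `""`
#'   yields `""`).
#' @param codon_table tibble with columns aa, codon, weight covering all 20
#'   residues; default [mouse_codon_usage()].
#' @param forbidden_motifs character vector of nucleotide motifs that must
#'   not occur in the output or its reverse complement (e.g. `"CGTCTC"` for
#'   BsmBI).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param max_attempts resampling rounds per occurrence before giving up.
#' @return character vector of nucleotide sequences, one per peptide.
#' @export
back_translate <- function(peptide, codon_table = mouse_codon_usage(),
                           forbidden_motifs = character(), seed = 1L,
                           max_attempts = 100L) {
  missing_aa <- setdiff(AA_ALPHABET, unique(codon_table$aa))
  if (length(missing_aa)) {
    rlang::abort(paste0("codon table missing residues: ",
                        paste(missing_aa, collapse = "")))
  }
  codons <- codon_table_to_list(codon_table)
  withr::with_seed(seed, {
    vapply(peptide, back_translate_one, "",
           codons = codons, forbidden = forbidden_motifs,
           max_attempts = max_attempts, USE.NAMES = FALSE)
  })
}

back_translate_one <- function(pep, codons, forbidden, max_attempts) {
  if (is.na(pep) || nchar(pep) == 0L) return("")
  if (!is_canonical_peptide(pep)) {
    rlang::abort(paste0("non-canonical residue in peptide: ", pep))
  }
  aa <- strsplit(pep, "")[[1]]
  draw <- function(a) {
    tab <- codons[[a]]
    tab$codon[sample.int(nrow(tab), 1L, prob = tab$weight)]
  }
  cds <- vapply(aa, draw, "", USE.NAMES = FALSE)
  if (length(forbidden) == 0) return(paste(cds, collapse = ""))
  motifs <- unique(c(forbidden, revcomp(forbidden)))
  for (attempt in seq_len(max_attempts)) {
    nt <- paste(cds, collapse = "")
    occ <- find_first_motif(nt, motifs)
    if (is.null(occ)) return(nt)
    # resample codons overlapping the occurrence
    idx <- seq.int(ceiling(occ$start / 3), ceiling(occ$end / 3))
    cds[idx] <- vapply(aa[idx], draw, "", USE.NAMES = FALSE)
  }
  rlang::abort(paste0("could not avoid forbidden motif in back-translation of ", pep))
}

find_first_motif <- function(nt, motifs) {
  best <- NULL
  for (m in motifs) {
    p <- regexpr(m, nt, fixed = TRUE)
    if (p > 0 && (is.null(best) || p < best$start)) {
      best <- list(start = as.integer(p), end = as.integer(p) + nchar(m) - 1L)
    }
  }
  best
}

#' Attach back-translated inserts to a library
#'
#' Convenience wrapper adding an `insert` column to an epitope library via
#' [back_translate()].
#'
#' @inheritParams back_translate
#' @param library epitope tibble / [sabr_library()].
#' @return the library with an `insert` column.
#' @export
add_inserts <- function(library, codon_table = mouse_codon_usage(),
                        forbidden_motifs = "CGTCTC", seed = 1L) {
  library$insert <- back_translate(library$peptide, codon_table,
                                   forbidden_motifs, seed = seed)
  library
}

#' Build a synthesis-ready oligo pool
#'
#' One oligo per epitope: `flank5 + insert + flank3`, where the constant
#' flanks carry the amplification / cloning overhangs. The library must
#' already hold back-translated inserts (see [add_inserts()]); inserts are
#' re-checked for forbidden motifs on both strands, and duplicate inserts
#' arising from distinct epitopes abort with a collision report.
#'
#' @param library epitope tibble with an `insert` column.
#' @param flank5,flank3 constant nucleotide flanks.
#' @param forbidden_motifs motifs that must not occur inside any insert.
#' @return tibble with columns id, insert, oligo; flanks and motifs kept as
#'   attributes.
#' @export
build_oligo_pool <- function(library, flank5, flank3,
                             forbidden_motifs = "CGTCTC") {
  if (!"insert" %in% names(library)) {
    rlang::abort("library has no `insert` column; run add_inserts() first")
  }
  stopifnot(all(is_dna(library$insert)))
  if (!all(translate_nt(library$insert) == library$peptide)) {
    rlang::abort("insert does not translate to its peptide")
  }
  if (anyDuplicated(library$insert)) {
    dup <- library$insert[duplicated(library$insert)]
    clash <- library$id[library$insert %in% dup]
    rlang::abort(paste0("insert collision between epitopes: ",
                        paste(clash, collapse = ", ")))
  }
  bad <- has_motif_either_strand(library$insert, forbidden_motifs)
  if (any(bad)) {
    rlang::abort(paste0("forbidden motif inside insert(s): ",
                        paste(library$id[bad], collapse = ", ")))
  }
  pool <- tibble::tibble(
    id = library$id,
    insert = library$insert,
    oligo = paste0(flank5, library$insert, flank3)
  )
  attr(pool, "flank5") <- flank5
  attr(pool, "flank3") <- flank3
  attr(pool, "forbidden_motifs") <- forbidden_motifs
  class(pool) <- unique(c("sabr_oligo_pool", class(pool)))
  pool
}

#' Write an oligo pool to FASTA and CSV
#'
#' @param pool tibble from [build_oligo_pool()].
#' @param fasta,csv output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_oligo_pool <- function(pool, fasta = NULL, csv = NULL) {
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(pool$oligo)
    names(dna) <- pool$id
    Biostrings::writeXStringSet(dna, fasta)
  }
  if (!is.null(csv)) {
    readr::write_csv(pool[c("id", "oligo", "insert")], csv)
  }
  invisible(c(fasta = fasta, csv = csv))
}
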