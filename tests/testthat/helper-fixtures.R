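# shared in-code fixtures; everything is generated at test time

fixture_reference <- function() {
  load_allele_reference(
    system.file("extdata", "tcr_reference_synthetic.fa", package = "sabrscreen")
  )
}

# tiny designed library with back-translated inserts
toy_library <- function(n = 6, seed = 7, forbidden = "CGTCTC") {
  peps <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 12, TRUE),
            collapse = "")
    }, "")
  })
  peps <- make.unique(peps, sep = "")  # peptides unique at this scale anyway
  lib <- sabr_library(
    tibble::tibble(id = sprintf("E%02d", seq_len(n)), peptide = peps),
    name = "toy", allele = "I-Ag7", length_bounds = c(9, 25)
  )
  add_inserts(lib, forbidden_motifs = forbidden, seed = seed)
}

toy_sheet <- function(n = 4) {
  idx7 <- c("ACGTACGT", "TTGCAATG", "GGATCCTA", "CATGCTAA",
            "AACCGGTT", "GTGTACAC", "TCAGGCTA", "CCTTAAGG")[seq_len(n)]
  idx5 <- c("TGCATGCA", "AATTCCGG", "CGTACGAT", "GGCCATTA",
            "TTAACCGG", "ACACGTGT", "AGGTCAGT", "GAATTCCA")[seq_len(n)]
  tibble::tibble(
    sample_id = sprintf("S%d", seq_len(n)),
    i7_index = idx7, i5_index = idx5,
    tcr_label = rep(c("TCRX", ""), length.out = n),
    role = rep(c("sorted", "unsorted"), length.out = n),
    replicate = rep(seq_len(ceiling(n / 2)), each = 2, length.out = n)
  )
}

toy_cfg <- function(...) {
  extraction_config(anchor5 = "ACTGGCTTCAGGAG", anchor3 = "GGATCAGAAGCTTG", ...)
}

# brute-force oracle: dual-index assignment by exhaustive Hamming scan
oracle_demux <- function(reads, sheet, tol) {
  ham <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  vapply(seq_len(nrow(reads)), function(i) {
    hits <- which(vapply(seq_len(nrow(sheet)), function(s) {
      ham(reads$i7[i], sheet$i7_index[s]) <= tol &&
        ham(reads$i5[i], sheet$i5_index[s]) <= tol
    }, TRUE))
    if (length(hits) == 1) sheet$sample_id[hits] else NA_character_
  }, "")
}

# overlapping occurrence count of a fixed motif
n_occurrences <- function(s, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  sum(hits > 0)
}
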