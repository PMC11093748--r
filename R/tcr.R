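# Standard P2A self-cleaving linker (in frame, 22 codons).
P2A_NT <- "GGAAGCGGAGCTACTAACTTCAGCCTGCTGAAGCAGGCTGGAGACGTGGAGGAGAACCCTGGACCT"

#' Load a V/J/C segment reference from IMGT-style FASTA
#'
#' Accepts nucleotide FASTA in the IMGT dialect (pipe-delimited headers with
#' the allele name in the second field, e.g.
#' `>X02935|TRAV1*01|Mus musculus|F|V-REGION|...`) or plain headers equal to
#' the allele name. Segment kind and chain are inferred from the allele name
#' (TRAV/TRAJ/TRAC/TRBV/TRBJ/TRBC). Sequences must be in frame; proteins are
#' derived by translation. Anchors are located on load: for V segments the
#' last cysteine within the C-terminal 15 residues (the IMGT CDR3 start);
#' for J segments the conserved F/W of the FGXG motif. Records failing
#' anchor location are kept but flagged unusable.
#'
#' @param fasta_paths one or more FASTA paths.
#' @return tibble with columns name, chain, kind, nt_seq, aa_seq, anchor
#'   (1-based residue index of the conserved C or F/W), usable.
#' @export
load_allele_reference <- function(fasta_paths) {
  recs <- lapply(fasta_paths, function(p) {
    dna <- Biostrings::readDNAStringSet(p)
    tibble::tibble(header = names(dna), nt_seq = unname(as.character(dna)))
  })
  ref <- dplyr::bind_rows(recs)
  fields <- strsplit(ref$header, "|", fixed = TRUE)
  ref$name <- vapply(fields, function(f) {
    if (length(f) >= 2) f[2] else strsplit(f[1], "\\s+")[[1]][1]
  }, "")
  ref$chain <- dplyr::case_when(
    startsWith(ref$name, "TRA") ~ "alpha",
    startsWith(ref$name, "TRB") ~ "beta",
    TRUE ~ NA_character_
  )
  ref$kind <- dplyr::case_when(
    grepl("^TR[AB]V", ref$name) ~ "V",
    grepl("^TR[AB]J", ref$name) ~ "J",
    grepl("^TR[AB]C", ref$name) ~ "C",
    TRUE ~ NA_character_
  )
  if (anyNA(ref$kind) || anyNA(ref$chain)) {
    bad <- ref$name[is.na(ref$kind) | is.na(ref$chain)]
    rlang::abort(paste0("cannot infer segment kind/chain from allele name: ",
                        paste(bad, collapse = ", ")))
  }
  if (any(nchar(ref$nt_seq) %% 3L != 0L)) {
    bad <- ref$name[nchar(ref$nt_seq) %% 3L != 0L]
    rlang::abort(paste0("reference sequences must be in frame: ",
                        paste(bad, collapse = ", ")))
  }
  ref$aa_seq <- translate_nt(ref$nt_seq)
  ref$anchor <- NA_integer_
  ref$usable <- TRUE
  for (i in seq_len(nrow(ref))) {
    if (ref$kind[i] == "V") {
      ref$anchor[i] <- v_anchor(ref$aa_seq[i])
    } else if (ref$kind[i] == "J") {
      ref$anchor[i] <- j_anchor(ref$aa_seq[i])
    }
    if (ref$kind[i] %in% c("V", "J") && is.na(ref$anchor[i])) {
      ref$usable[i] <- FALSE
      rlang::warn(paste0("segment ", ref$name[i],
                         " lacks its conserved anchor; flagged unusable"))
    }
  }
  dplyr::select(ref, "name", "chain", "kind", "nt_seq", "aa_seq", "anchor", "usable")
}

# last Cys within the C-terminal 15 residues (1-based index), NA if none
v_anchor <- function(aa) {
  n <- nchar(aa)
  window_start <- max(1L, n - 14L)
  pos <- gregexpr("C", aa, fixed = TRUE)[[1]]
  pos <- pos[pos >= window_start]
  if (length(pos) == 0 || pos[1] < 0) return(NA_integer_)
  as.integer(max(pos))
}

# conserved F/W of the FGXG motif (1-based index), NA if absent
j_anchor <- function(aa) {
  m <- regexpr("[FW]G.G", aa)
  if (m < 0) return(NA_integer_)
  as.integer(m)
}

#' Write a segment reference back to IMGT-style FASTA
#'
#' @param ref reference tibble from [load_allele_reference()].
#' @param path output FASTA path.
#' @export
write_allele_reference <- function(ref, path) {
  dna <- Biostrings::DNAStringSet(ref$nt_seq)
  names(dna) <- paste("REF", ref$name, "Mus musculus", "F",
                      paste0(ref$kind, "-REGION"), sep = "|")
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

lookup_segment <- function(ref, name, kind = NULL) {
  hit <- ref[ref$name == name, , drop = FALSE]
  if (nrow(hit) == 0) {
    cand <- ref$name
    near <- cand[order(utils::adist(name, cand))][seq_len(min(3L, length(cand)))]
    rlang::abort(paste0("unknown allele '", name, "'; nearest reference names: ",
                        paste(near, collapse = ", ")))
  }
  if (!is.null(kind) && hit$kind[1] != kind) {
    rlang::abort(paste0("allele '", name, "' is a ", hit$kind[1],
                        " segment, expected ", kind))
  }
  if (!hit$usable[1]) {
    rlang::abort(paste0("allele '", name, "' was flagged unusable at load"))
  }
  hit[1, ]
}

#' Reconstruct a full-length TCR chain from V/J allele names and a CDR3
#'
#' Uses the IMGT junction convention: the CDR3 includes the V-segment
#' conserved cysteine and the J-segment conserved F/W, so the V segment
#' contributes residues strictly before its anchor and the J segment
#' residues strictly after. The protein is
#' `V[1..anchor-1] + CDR3 + J[anchor+1..] + C`. Nucleotides reuse germline
#' codons wherever the CDR3 prefix/suffix matches germline (longest-match
#' trimming against the V tail and J head); the non-templated core is
#' back-translated with the library codon policy.
#'
#' @param v,j V and J allele names present in `ref`.
#' @param cdr3 CDR3 amino-acid sequence (IMGT junction, C...F/W). Must start
#'   with C unless `lenient = TRUE`.
#' @param c_allele constant-region allele name; `NULL` picks the chain's
#'   first C segment in the reference.
#' @param ref reference tibble from [load_allele_reference()].
#' @param lenient proceed with a warning when the CDR3 does not start with C.
#' @param codon_table,seed codon policy for non-templated residues.
#' @return list with `aa` (chain protein), `nt` (in-frame nucleotide) and
#'   `provenance` (segment names and junction coordinates).
#' @export
reconstruct_chain <- function(v, j, cdr3, c_allele = NULL, ref,
                              lenient = FALSE,
                              codon_table = mouse_codon_usage(), seed = 1L) {
  if (is.na(cdr3) || nchar(cdr3) == 0) rlang::abort("CDR3 must be non-empty")
  if (!is_canonical_peptide(cdr3)) {
    rlang::abort(paste0("CDR3 contains non-canonical residues: ", cdr3))
  }
  if (!startsWith(cdr3, "C")) {
    if (lenient) {
      rlang::warn(paste0("CDR3 does not start with C: ", cdr3))
    } else {
      rlang::abort(paste0("CDR3 does not start with C: ", cdr3,
                          " (use lenient = TRUE to force)"))
    }
  }
  vrec <- lookup_segment(ref, v, "V")
  jrec <- lookup_segment(ref, j, "J")
  chain <- vrec$chain
  if (jrec$chain != chain) rlang::abort("V and J segments come from different chains")
  crec <- if (is.null(c_allele)) {
    cand <- ref[ref$kind == "C" & ref$chain == chain, , drop = FALSE]
    if (nrow(cand) == 0) rlang::abort(paste0("no C segment for chain ", chain))
    cand[1, ]
  } else {
    lookup_segment(ref, c_allele, "C")
  }

  va <- vrec$anchor
  ja <- jrec$anchor
  v_frame_aa <- substr(vrec$aa_seq, 1L, va - 1L)
  j_tail_aa <- substr(jrec$aa_seq, ja + 1L, nchar(jrec$aa_seq))
  aa <- paste0(v_frame_aa, cdr3, j_tail_aa, crec$aa_seq)

  # germline codon reuse: longest CDR3 prefix matching the V tail (anchor on),
  # longest remaining suffix matching the J head (up to and incl. the anchor)
  v_tail <- substr(vrec$aa_seq, va, nchar(vrec$aa_seq))
  j_head <- substr(jrec$aa_seq, 1L, ja)
  n3 <- nchar(cdr3)
  p <- common_prefix_len(cdr3, v_tail)
  s <- common_suffix_len(substr(cdr3, p + 1L, n3), j_head)
  core <- substr(cdr3, p + 1L, n3 - s)
  core_nt <- if (nchar(core)) {
    back_translate(core, codon_table, seed = seed)
  } else ""
  nt <- paste0(
    substr(vrec$nt_seq, 1L, 3L * (va - 1L + p)),
    core_nt,
    substr(jrec$nt_seq, 3L * (ja - s) + 1L, nchar(jrec$nt_seq)),
    crec$nt_seq
  )
  if (count_motif_aa(aa, cdr3) != 1L) {
    rlang::abort(paste0("CDR3 does not occur exactly once in chain: ", cdr3))
  }
  stopifnot(translate_nt(nt) == aa)
  list(
    aa = aa, nt = nt,
    provenance = tibble::tibble(
      v = vrec$name, j = jrec$name, c = crec$name, chain = chain,
      cdr3 = cdr3, cdr3_start = nchar(v_frame_aa) + 1L,
      cdr3_end = nchar(v_frame_aa) + n3,
      germline_prefix = p, germline_suffix = s
    )
  )
}

common_prefix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  i <- 0L
  while (i < n && substr(x, i + 1L, i + 1L) == substr(y, i + 1L, i + 1L)) i <- i + 1L
  i
}

common_suffix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  i <- 0L
  while (i < n &&
         substr(x, nchar(x) - i, nchar(x) - i) == substr(y, nchar(y) - i, nchar(y) - i)) {
    i <- i + 1L
  }
  i
}

count_motif_aa <- function(s, motif) {
  sum(gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]] > 0)
}

#' Assemble a bicistronic TCRa-2A-TCRb construct
#'
#' Joins the reconstructed alpha chain, a 2A self-cleaving linker and the
#' beta chain truncated at the first occurrence of the constant-region
#' truncation motif (BlpI site by default, motif retained), and prepends the
#' 5' cloning flank (EcoRI by default). Internal occurrences of the flank
#' motif inside the coding sequence are removed by synonymous codon
#' resampling so the restriction site stays unique.
#'
#' @param alpha,beta chain lists from [reconstruct_chain()].
#' @param tcr_id construct identifier.
#' @param linker_2A in-frame 2A linker nucleotide sequence (default P2A).
#' @param flank5 5' cloning flank, also the motif kept unique (default
#'   EcoRI `GAATTC`).
#' @param beta_trunc_motif truncation motif in the beta constant region
#'   (default BlpI `GCTCAGC`).
#' @param codon_table,seed codon policy for synonymous resampling.
#' @return list of class `sabr_construct`: tcr_id, alpha_aa, beta_aa,
#'   construct_nt, features (flank/alpha/2A/beta spans), provenance.
#' @export
assemble_construct <- function(alpha, beta, tcr_id = "TCR",
                               linker_2A = P2A_NT, flank5 = "GAATTC",
                               beta_trunc_motif = "GCTCAGC",
                               codon_table = mouse_codon_usage(), seed = 1L) {
  cut <- regexpr(beta_trunc_motif, beta$nt, fixed = TRUE)
  if (cut < 0) {
    rlang::abort(paste0("truncation motif ", beta_trunc_motif,
                        " absent from beta chain"))
  }
  beta_nt <- substr(beta$nt, 1L, as.integer(cut) + nchar(beta_trunc_motif) - 1L)
  coding <- paste0(alpha$nt, linker_2A, beta_nt)
  coding <- resample_out_motif(coding, flank5, codon_table, seed)
  construct <- paste0(flank5, coding)
  features <- tibble::tibble(
    feature = c("flank5", "alpha", "2A", "beta"),
    start = cumsum(c(1L, nchar(flank5), nchar(alpha$nt), nchar(linker_2A))),
    end = cumsum(c(nchar(flank5), nchar(alpha$nt), nchar(linker_2A), nchar(beta_nt)))
  )
  structure(
    list(
      tcr_id = tcr_id, alpha_aa = alpha$aa, beta_aa = beta$aa,
      construct_nt = construct, features = features,
      provenance = dplyr::bind_rows(alpha = alpha$provenance,
                                    beta = beta$provenance, .id = "chain_role")
    ),
    class = "sabr_construct"
  )
}

# synonymously resample codons overlapping occurrences of motif in an
# in-frame coding sequence (a trailing partial codon is left untouched and
# may not overlap a motif occurrence)
resample_out_motif <- function(coding, motif, codon_table, seed,
                               max_attempts = 100L) {
  n_full <- (nchar(coding) %/% 3L) * 3L
  tail_nt <- substr(coding, n_full + 1L, nchar(coding))
  body <- substr(coding, 1L, n_full)
  aa <- strsplit(translate_nt(body), "")[[1]]
  codons <- codon_table_to_list(codon_table)
  cds <- substring(body, seq(1L, n_full - 2L, 3L), seq(3L, n_full, 3L))
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      full <- paste0(paste(cds, collapse = ""), tail_nt)
      occ <- find_first_motif(full, motif)
      if (is.null(occ)) return(full)
      if (occ$start > n_full - nchar(motif) + 1L && occ$end > n_full) {
        rlang::abort("flank motif overlaps the trailing partial codon; cannot resample")
      }
      idx <- seq.int(ceiling(occ$start / 3), min(ceiling(occ$end / 3), length(cds)))
      cds[idx] <- vapply(aa[idx], function(a) {
        tab <- codons[[a]]
        tab$codon[sample.int(nrow(tab), 1L, prob = tab$weight)]
      }, "")
    }
    rlang::abort("could not remove internal flank motif by synonymous resampling")
  })
}

#' Reconstruct full-length constructs for a clonotype table
#'
#' Runs [reconstruct_chain()] for both chains of every clonotype and
#' assembles each TCRa-2A-TCRb construct.
#'
#' @param clonotypes tibble with columns tcr_id, va, ja, cdr3a, vb, jb,
#'   cdr3b (allele names and amino-acid CDR3s, as emitted by single-cell
#'   V(D)J callers).
#' @param ref reference tibble from [load_allele_reference()].
#' @inheritParams assemble_construct
#' @inheritParams reconstruct_chain
#' @return tibble with one row per TCR: tcr_id, alpha_aa, beta_aa,
#'   construct_nt, and a `construct` list-column of `sabr_construct`
#'   objects.
#' @export
reconstruct_tcrs <- function(clonotypes, ref, lenient = FALSE,
                             linker_2A = P2A_NT, flank5 = "GAATTC",
                             beta_trunc_motif = "GCTCAGC",
                             codon_table = mouse_codon_usage(), seed = 1L) {
  clonotypes <- tibble::as_tibble(clonotypes)
  need <- c("tcr_id", "va", "ja", "cdr3a", "vb", "jb", "cdr3b")
  if (!all(need %in% names(clonotypes))) {
    rlang::abort(paste0("clonotype table needs columns: ",
                        paste(need, collapse = ", ")))
  }
  rows <- purrr::pmap(clonotypes[need], function(tcr_id, va, ja, cdr3a, vb, jb, cdr3b) {
    a <- reconstruct_chain(va, ja, cdr3a, ref = ref, lenient = lenient,
                           codon_table = codon_table, seed = seed)
    b <- reconstruct_chain(vb, jb, cdr3b, ref = ref, lenient = lenient,
                           codon_table = codon_table, seed = seed)
    cons <- assemble_construct(a, b, tcr_id = tcr_id, linker_2A = linker_2A,
                               flank5 = flank5,
                               beta_trunc_motif = beta_trunc_motif,
                               codon_table = codon_table, seed = seed)
    tibble::tibble(tcr_id = tcr_id, alpha_aa = a$aa, beta_aa = b$aa,
                   construct_nt = cons$construct_nt, construct = list(cons))
  })
  dplyr::bind_rows(rows)
}

#' Write reconstructed constructs
#'
#' Emits a construct FASTA, a feature-annotation TSV (flank/V/CDR3/J/C/2A
#' spans per construct) and a provenance JSON.
#'
#' @param constructs tibble from [reconstruct_tcrs()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_constructs <- function(constructs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "constructs.fa")
  dna <- Biostrings::DNAStringSet(constructs$construct_nt)
  names(dna) <- constructs$tcr_id
  Biostrings::writeXStringSet(dna, fa)
  feats <- dplyr::bind_rows(
    stats::setNames(purrr::map(constructs$construct, "features"), constructs$tcr_id),
    .id = "tcr_id"
  )
  feat_path <- file.path(out_dir, "features.tsv")
  readr::write_tsv(feats, feat_path)
  prov <- purrr::map(constructs$construct, "provenance")
  names(prov) <- constructs$tcr_id
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, dataframe = "rows", pretty = TRUE)
  invisible(c(fa, feat_path, prov_path))
}
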