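#' Enumerate cleavage products of a source protein
#'
#' Helper for building HIP fusion halves when only a protein sequence and a
#' set of cleavage positions are known. Left halves are the prefixes of the
#' protein ending at each declared cleavage position; right halves are the
#' suffixes starting at each position. Positions are 0-based offsets of the
#' cut site (a cut at position p splits `substr(1, p)` / `substr(p+1, n)`).
#'
#' @param protein amino-acid sequence.
#' @param source protein name recorded on each fragment.
#' @param cut_positions integer vector of cut offsets, `0 < p < nchar(protein)`.
#' @param end `"left"` for prefixes (N-terminal fusion halves) or `"right"`
#'   for suffixes (C-terminal halves).
#' @return tibble with columns source_protein, fragment, end.
#' @export
cleavage_products <- function(protein, source, cut_positions, end = c("left", "right")) {
  end <- match.arg(end)
  if (!is_canonical_peptide(protein)) rlang::abort("protein must be a canonical peptide")
  cut_positions <- as.integer(cut_positions)
  if (any(cut_positions <= 0L | cut_positions >= nchar(protein))) {
    rlang::abort("cut positions must lie strictly inside the protein")
  }
  frag <- if (end == "left") {
    substr(rep(protein, length(cut_positions)), 1L, cut_positions)
  } else {
    substr(rep(protein, length(cut_positions)), cut_positions + 1L, nchar(protein))
  }
  tibble::tibble(source_protein = source, fragment = frag, end = end)
}

#' Enumerate a theoretical hybrid insulin peptide (HIP) library
#'
#' Fuses every left-half fragment (insulin C-peptide cleavage products by
#' design intent) to every right-half fragment (secretory-granule protein
#' cleavage products), keeps fusions whose total length falls inside
#' `length_bounds`, records the fusion point as `junction_index` (the number
#' of left-derived residues), deduplicates identical peptides keeping the
#' first occurrence, and appends control epitopes unchanged.
#'
#' @param left tibble of left fragments as from [cleavage_products()]
#'   (`end == "left"`), or a character vector with names taken as sources.
#' @param right tibble of right fragments (`end == "right"`), or character
#'   vector.
#' @param length_bounds inclusive fused-peptide length bounds, default
#'   `c(12, 25)`.
#' @param controls optional epitope tibble of positive controls appended
#'   as-is.
#' @param allele MHC restriction label for the resulting library.
#' @param name library name.
#' @return a [sabr_library()] of HIP epitopes plus controls.
#' @export
generate_hip_library <- function(left, right, length_bounds = c(12L, 25L),
                                 controls = NULL, allele = "I-Ag7",
                                 name = "hip-library") {
  left <- as_fragment_tbl(left, "left")
  right <- as_fragment_tbl(right, "right")
  if (length(length_bounds) != 2 || length_bounds[1] > length_bounds[2]) {
    rlang::abort("length_bounds must be c(min, max) with min <= max")
  }
  if (nrow(left) == 0) {
    rlang::warn("no left fragments supplied; library contains controls only")
  }
  grid <- tidyr::expand_grid(
    li = seq_len(nrow(left)),
    ri = seq_len(nrow(right))
  )
  hips <- tibble::tibble(
    peptide = paste0(left$fragment[grid$li], right$fragment[grid$ri]),
    left_source = left$source_protein[grid$li],
    right_source = right$source_protein[grid$ri],
    junction_index = nchar(left$fragment[grid$li])
  )
  hips <- hips[nchar(hips$peptide) >= length_bounds[1] &
                 nchar(hips$peptide) <= length_bounds[2], , drop = FALSE]
  hips <- hips[!duplicated(hips$peptide), , drop = FALSE]
  hips <- tibble::tibble(
    id = sprintf("HIP%04d", seq_len(nrow(hips))),
    peptide = hips$peptide,
    category = "hip",
    left_source = hips$left_source,
    right_source = hips$right_source,
    junction_index = as.integer(hips$junction_index),
    notes = ""
  )
  out <- if (!is.null(controls) && nrow(controls) > 0) {
    ctl <- epitope_tbl(controls)
    ctl$category <- "control"
    dplyr::bind_rows(hips, ctl[!ctl$peptide %in% hips$peptide, , drop = FALSE])
  } else {
    hips
  }
  sabr_library(out, name = name, allele = allele, length_bounds = length_bounds)
}

as_fragment_tbl <- function(x, end) {
  if (is.character(x)) {
    src <- names(x) %||% rep(paste0(end, "_source"), length(x))
    x <- tibble::tibble(source_protein = src, fragment = unname(x), end = end)
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(source_protein = character(), fragment = character(),
                          end = character()))
  }
  if (!all(c("source_protein", "fragment") %in% names(x))) {
    rlang::abort("fragments need source_protein and fragment columns")
  }
  if (any(x$fragment == "") || !all(is_canonical_peptide(x$fragment))) {
    rlang::abort("fragments must be non-empty canonical peptides")
  }
  x
}

#' Design a junction-spanning validation epitope
#'
#' For single-SABR validation of a HIP hit, builds the 2k-mer made of the
#' last `k` residues of the left context followed by the first `k` residues
#' of the right context. With the default `k = 7` no 9-mer core of the
#' resulting 14-mer can derive wholly from either source protein, so MHC-II
#' binding necessarily spans the fusion junction.
#'
#' @param hip_left_context peptide providing the left half (length >= k).
#' @param hip_right_context peptide providing the right half (length >= k).
#' @param k residues taken from each side (default 7).
#' @param id epitope id.
#' @param left_source,right_source source protein names.
#' @return one-row epitope tibble with `junction_index = k`.
#' @export
make_junction_epitope <- function(hip_left_context, hip_right_context, k = 7L,
                                  id = "junction", left_source = "left",
                                  right_source = "right") {
  if (nchar(hip_left_context) < k) {
    rlang::abort(sprintf("left context too short: %d < k = %d",
                         nchar(hip_left_context), k))
  }
  if (nchar(hip_right_context) < k) {
    rlang::abort(sprintf("right context too short: %d < k = %d",
                         nchar(hip_right_context), k))
  }
  pep <- paste0(
    substr(hip_left_context, nchar(hip_left_context) - k + 1L, nchar(hip_left_context)),
    substr(hip_right_context, 1L, k)
  )
  epitope_tbl(tibble::tibble(
    id = id, peptide = pep, category = "hip",
    left_source = left_source, right_source = right_source,
    junction_index = as.integer(k)
  ))
}
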