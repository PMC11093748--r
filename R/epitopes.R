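#' Build an epitope table
#'
#' Epitopes are plain tibbles with one row per epitope, so they compose with
#' dplyr verbs. `epitope_tbl()` validates and normalises a data frame into
#' that shape; missing annotation columns are filled with defaults.
#'
#' @param x data frame with at least `id` and `peptide`; optional `category`
#'   (one of natural, mimotope, deamidated, hip, control), `left_source`,
#'   `right_source`, `junction_index` (0-based count of left-derived residues,
#'   HIPs only) and `notes`.
#' @return tibble with columns id, peptide, category, left_source,
#'   right_source, junction_index, notes.
#' @export
epitope_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("id", "peptide") %in% names(x))) {
    rlang::abort("epitope table needs `id` and `peptide` columns")
  }
  defaults <- list(
    category = "natural", left_source = "", right_source = "",
    junction_index = NA_integer_, notes = ""
  )
  for (col in names(defaults)) {
    if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  }
  x$id <- as.character(x$id)
  x$peptide <- toupper(as.character(x$peptide))
  x$junction_index <- as.integer(x$junction_index)
  bad_cat <- setdiff(unique(x$category),
                     c("natural", "mimotope", "deamidated", "hip", "control"))
  if (length(bad_cat)) {
    rlang::abort(paste0("unknown epitope category: ", paste(bad_cat, collapse = ", ")))
  }
  hips <- x$category == "hip"
  if (any(hips)) {
    ok <- !is.na(x$junction_index[hips]) &
      x$junction_index[hips] > 0L &
      x$junction_index[hips] < nchar(x$peptide[hips]) &
      x$left_source[hips] != "" & x$right_source[hips] != ""
    if (!all(ok)) {
      rlang::abort(paste0(
        "invalid HIP rows (junction_index must lie strictly inside the peptide, ",
        "both sources named): ", paste(x$id[hips][!ok], collapse = ", ")
      ))
    }
  }
  dplyr::select(x, "id", "peptide", "category", "left_source", "right_source",
                "junction_index", "notes", dplyr::everything())
}

#' Curate a raw epitope list for library synthesis
#'
#' Applies the defined-library curation rules: peptides are kept when their
#' length falls inside `length_bounds` (inclusive) and their modification
#' annotation is allowed; duplicated peptide sequences are collapsed keeping
#' the first occurrence. Deamidation is expected to be encoded directly in
#' the sequence (N->D / Q->E) because library inserts are genetically
#' encoded; a `modification` column, when present, is compared against
#' `allowed_mods` (empty string / NA meaning unmodified, always allowed).
#' Retained peptides containing non-canonical residues abort with the
#' offending ids.
#'
#' @param raw data frame with `id`, `peptide`, optional `modification` and
#'   any `epitope_tbl()` columns.
#' @param length_bounds integer length-2 vector, inclusive amino-acid length
#'   bounds (default `c(9, 25)`).
#' @param allowed_mods character vector of modification annotations to keep
#'   (default `c("deamidation", "hip")`).
#' @return curated epitope tibble (see [epitope_tbl()]).
#' @export
curate_epitopes <- function(raw, length_bounds = c(9L, 25L),
                            allowed_mods = c("deamidation", "hip")) {
  if (length(length_bounds) != 2 || length_bounds[1] > length_bounds[2]) {
    rlang::abort("length_bounds must be c(min, max) with min <= max")
  }
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0) {
    return(epitope_tbl(tibble::tibble(id = character(), peptide = character())))
  }
  if (!"modification" %in% names(raw)) raw$modification <- ""
  raw$modification[is.na(raw$modification)] <- ""
  keep <- nchar(raw$peptide) >= length_bounds[1] &
    nchar(raw$peptide) <= length_bounds[2] &
    (raw$modification == "" | raw$modification %in% allowed_mods)
  out <- raw[keep, , drop = FALSE]
  bad <- !is_canonical_peptide(out$peptide)
  if (any(bad)) {
    rlang::abort(paste0(
      "non-canonical residues in retained peptides: ",
      paste(out$id[bad], collapse = ", ")
    ))
  }
  dup <- duplicated(out$peptide)
  if (any(dup)) {
    rlang::warn(paste0(
      "dropping ", sum(dup), " duplicate peptide(s), keeping first occurrence: ",
      paste(utils::head(out$id[dup], 10), collapse = ", ")
    ))
  }
  out <- out[!dup, , drop = FALSE]
  out$modification <- NULL
  epitope_tbl(out)
}

#' Attach library-level metadata to an epitope table
#'
#' A SABR library is an epitope tibble carrying its name, MHC restriction
#' and design length bounds as attributes, plus (after back-translation) an
#' `insert` column of nucleotide sequences.
#'
#' @param epitopes epitope tibble.
#' @param name library name.
#' @param allele MHC restriction label, e.g. `"I-Ag7"` or `"HLA-DQ8"`.
#' @param length_bounds inclusive amino-acid length bounds of the design.
#' @return the epitope tibble with class `sabr_library`.
#' @export
sabr_library <- function(epitopes, name = "library", allele = "I-Ag7",
                         length_bounds = c(9L, 25L)) {
  epitopes <- epitope_tbl(epitopes)
  if (anyDuplicated(epitopes$peptide)) {
    rlang::abort("library peptides must be unique after curation")
  }
  attr(epitopes, "name") <- name
  attr(epitopes, "allele") <- allele
  attr(epitopes, "length_bounds") <- as.integer(length_bounds)
  class(epitopes) <- unique(c("sabr_library", class(epitopes)))
  epitopes
}

#' Read / write epitope tables
#'
#' CSV columns: id, peptide, category, left_source, right_source,
#' junction_index, notes. FASTA uses the id as header and peptide as
#' sequence.
#'
#' @param path file path.
#' @param x epitope tibble.
#' @return `read_epitopes()` returns an epitope tibble; writers return the
#'   path invisibly.
#' @export
read_epitopes <- function(path) {
  epitope_tbl(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_epitopes
#' @export
write_epitopes <- function(x, path) {
  readr::write_csv(epitope_tbl(x), path)
  invisible(path)
}

#' @rdname read_epitopes
#' @export
write_epitopes_fasta <- function(x, path) {
  x <- epitope_tbl(x)
  aa <- Biostrings::AAStringSet(x$peptide)
  names(aa) <- x$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Validate a HIP library manifest
#'
#' Checks a HIP-focused library manifest (for example one loaded from a
#' published supplementary table with [read_epitopes()]) against the design
#' rules of a theoretical HIP library: reports the epitope count, the count
#' of HIP-category entries, and whether every HIP peptide length lies inside
#' the declared bounds.
#'
#' @param manifest epitope tibble.
#' @param length_bounds inclusive length bounds (default `c(12, 25)`).
#' @return one-row tibble: n_epitopes, n_hip, min_len, max_len,
#'   all_in_bounds.
#' @export
check_hip_manifest <- function(manifest, length_bounds = c(12L, 25L)) {
  manifest <- epitope_tbl(manifest)
  hips <- manifest[manifest$category == "hip", , drop = FALSE]
  lens <- nchar(manifest$peptide)
  tibble::tibble(
    n_epitopes = nrow(manifest),
    n_hip = nrow(hips),
    min_len = if (nrow(manifest)) min(lens) else NA_integer_,
    max_len = if (nrow(manifest)) max(lens) else NA_integer_,
    all_in_bounds = all(nchar(hips$peptide) >= length_bounds[1] &
                          nchar(hips$peptide) <= length_bounds[2])
  )
}
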