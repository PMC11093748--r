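#' Read and validate a screen sample sheet
#'
#' Columns: sample_id, i7_index, i5_index, tcr_label (comma-separated when a
#' sorted sample held several TCRs), role (`sorted` or `unsorted`),
#' replicate. Index pairs must be unique and indexes equal length within
#' each column.
#'
#' @param path CSV path, or a data frame already in that shape.
#' @return validated tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  need <- c("sample_id", "i7_index", "i5_index", "tcr_label", "role", "replicate")
  if (!all(need %in% names(sheet))) {
    rlang::abort(paste0("sample sheet needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(sheet$sample_id)) rlang::abort("duplicate sample_id in sheet")
  if (anyDuplicated(paste(sheet$i7_index, sheet$i5_index))) {
    rlang::abort("duplicate index pair in sample sheet")
  }
  if (length(unique(nchar(sheet$i7_index))) != 1 ||
      length(unique(nchar(sheet$i5_index))) != 1) {
    rlang::abort("indexes must be equal length within each column")
  }
  if (!all(sheet$role %in% c("sorted", "unsorted"))) {
    rlang::abort("role must be 'sorted' or 'unsorted'")
  }
  sheet
}

#' Extraction configuration for anchored insert recovery
#'
#' The epitope insert sits between two constant amplicon flanks
#' (`anchor5`, `anchor3`). Extraction finds `anchor5`, then `anchor3`
#' downstream of it, each allowing up to `anchor_mismatch_tol`
#' substitutions (no indels), and returns the between-anchor substring.
#'
#' @param anchor5,anchor3 constant nucleotide flanks bounding the insert.
#' @param anchor_mismatch_tol allowed substitutions per anchor (default 1).
#' @param index_mismatch_tol allowed substitutions per sample index
#'   (default 1).
#' @param match_mode `"nt_exact"` (insert looked up verbatim against the
#'   designed library) or `"peptide"` (in-frame translation matched to the
#'   peptide index; error-tolerant to synonymous sequencing variants).
#' @return list of class `extraction_config`.
#' @export
extraction_config <- function(anchor5, anchor3, anchor_mismatch_tol = 1L,
                              index_mismatch_tol = 1L,
                              match_mode = c("nt_exact", "peptide")) {
  match_mode <- match.arg(match_mode)
  if (nchar(anchor5) == 0 || nchar(anchor3) == 0) {
    rlang::abort("anchors must be non-empty")
  }
  if (anchor_mismatch_tol < 0 || index_mismatch_tol < 0) {
    rlang::abort("tolerances must be >= 0")
  }
  structure(
    list(anchor5 = anchor5, anchor3 = anchor3,
         anchor_mismatch_tol = as.integer(anchor_mismatch_tol),
         index_mismatch_tol = as.integer(index_mismatch_tol),
         match_mode = match_mode),
    class = "extraction_config"
  )
}

#' Read amplicon FASTQ into a read table
#'
#' Reads R1 (gzip-transparent) and recovers the observed i7/i5 indexes
#' either from the Illumina header comment (`... 1:N:0:I7+I5`) or from
#' separate index FASTQ files. Phred qualities are ignored unless
#' `min_qual` is set, in which case reads whose mean quality falls below it
#' are dropped.
#'
#' @param r1 path to the read-1 FASTQ(.gz); only read 1 carries the insert.
#' @param i1,i2 optional paths to index FASTQ files (i7, i5); when `NULL`
#'   indexes are parsed from the R1 headers.
#' @param min_qual optional mean-Phred filter, default off.
#' @return tibble with columns read_id, seq, i7, i5.
#' @export
read_screen_fastq <- function(r1, i1 = NULL, i2 = NULL, min_qual = NULL) {
  if (!is.null(min_qual)) {
    q <- Biostrings::readQualityScaledDNAStringSet(r1)
    keep <- vapply(as(Biostrings::quality(q), "IntegerList"), mean, 0) >= min_qual
    q <- q[keep]
    reads <- tibble::tibble(header = names(q), seq = unname(as.character(q)))
  } else {
    dna <- Biostrings::readDNAStringSet(r1, format = "fastq")
    reads <- tibble::tibble(header = names(dna), seq = unname(as.character(dna)))
  }
  reads$read_id <- sub("\\s.*$", "", reads$header)
  if (is.null(i1)) {
    comment <- sub("^\\S+\\s*", "", reads$header)
    idx <- sub("^.*:", "", comment)
    parts <- strsplit(idx, "+", fixed = TRUE)
    reads$i7 <- vapply(parts, `[`, "", 1)
    reads$i5 <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
  } else {
    ix1 <- Biostrings::readDNAStringSet(i1, format = "fastq")
    ix2 <- Biostrings::readDNAStringSet(i2, format = "fastq")
    reads$i7 <- unname(as.character(ix1))
    reads$i5 <- unname(as.character(ix2))
  }
  reads[c("read_id", "seq", "i7", "i5")]
}

#' Demultiplex reads by unique dual index
#'
#' Assigns each read to the unique sample whose i7 and i5 indexes are both
#' within `tol` Hamming distance of the observed pair; reads matching no
#' sample, or more than one, stay unassigned (`NA`). Refuses to run when
#' the sample sheet itself is ambiguous at this tolerance (two samples with
#' both index distances <= 2*tol).
#'
#' @param reads tibble with columns i7, i5 (see [read_screen_fastq()]).
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param tol per-index Hamming tolerance (default 1).
#' @return `reads` with a `sample_id` column (`NA` = unassigned).
#' @export
demultiplex <- function(reads, sheet, tol = 1L) {
  sheet <- read_sample_sheet(sheet)
  n_s <- nrow(sheet)
  # sheet-level collision check
  for (a in seq_len(n_s - 1L)) {
    for (b in seq.int(a + 1L, n_s)) {
      d7 <- hamming_to(sheet$i7_index[a], sheet$i7_index[b])
      d5 <- hamming_to(sheet$i5_index[a], sheet$i5_index[b])
      if (d7 <= 2L * tol && d5 <= 2L * tol) {
        rlang::abort(paste0(
          "index collision at tol=", tol, ": samples ",
          sheet$sample_id[a], " and ", sheet$sample_id[b],
          " (i7 distance ", d7, ", i5 distance ", d5, ")"
        ))
      }
    }
  }
  if (nrow(reads) == 0) {
    reads$sample_id <- character(0)
    return(reads)
  }
  ok <- matrix(FALSE, nrow(reads), n_s)
  for (s in seq_len(n_s)) {
    d7 <- hamming_to(reads$i7, sheet$i7_index[s])
    d5 <- hamming_to(reads$i5, sheet$i5_index[s])
    ok[, s] <- !is.na(d7) & !is.na(d5) & d7 <= tol & d5 <= tol
  }
  n_match <- rowSums(ok)
  pick <- max.col(ok, ties.method = "first")
  reads$sample_id <- ifelse(n_match == 1L, sheet$sample_id[pick], NA_character_)
  reads
}

#' Extract the epitope insert from reads
#'
#' Vectorised anchored extraction (see [extraction_config()]): locates the
#' leftmost occurrence of `anchor5`, then the leftmost occurrence of
#' `anchor3` downstream of it, each within the configured substitution
#' tolerance, and returns the substring between them. `NA` when either
#' anchor is absent or out of order.
#'
#' @param seqs character vector of read sequences.
#' @param cfg an [extraction_config()].
#' @return character vector of inserts (`NA` = not extracted; an insert of
#'   length zero is `""`).
#' @export
extract_insert <- function(seqs, cfg) {
  if (length(seqs) == 0) return(character(0))
  dna <- Biostrings::DNAStringSet(seqs)
  m5 <- Biostrings::vmatchPattern(cfg$anchor5, dna,
                                  max.mismatch = cfg$anchor_mismatch_tol)
  m3 <- Biostrings::vmatchPattern(cfg$anchor3, dna,
                                  max.mismatch = cfg$anchor_mismatch_tol)
  out <- rep(NA_character_, length(seqs))
  s5 <- Biostrings::startIndex(m5)
  e5 <- Biostrings::endIndex(m5)
  s3 <- Biostrings::startIndex(m3)
  for (i in seq_along(seqs)) {
    if (is.null(s5[[i]]) || length(s5[[i]]) == 0) next
    a5_end <- e5[[i]][1]
    cand3 <- s3[[i]][!is.na(s3[[i]]) & s3[[i]] > a5_end]
    if (length(cand3) == 0) next
    out[i] <- substr(seqs[i], a5_end + 1L, cand3[1] - 1L)
  }
  out
}

#' Match extracted inserts to library epitopes
#'
#' In `nt_exact` mode the insert must equal a designed library insert
#' verbatim; in `peptide` mode the insert is translated in frame (frame set
#' by the anchor design, inserts with length not a multiple of 3 count as
#' unmatched) and looked up against the peptide index.
#'
#' @param inserts character vector of inserts (`NA` allowed).
#' @param library epitope library with an `insert` column.
#' @param mode `"nt_exact"` or `"peptide"`.
#' @return character vector of epitope ids (`NA` = no match).
#' @export
assign_epitope <- function(inserts, library, mode = c("nt_exact", "peptide")) {
  mode <- match.arg(mode)
  if (mode == "nt_exact") {
    if (!"insert" %in% names(library)) {
      rlang::abort("library has no `insert` column; run add_inserts() first")
    }
    library$id[match(inserts, library$insert)]
  } else {
    pep <- translate_nt(inserts)
    library$id[match(pep, library$peptide)]
  }
}

#' Count one demultiplexed sample
#'
#' Runs anchored extraction and library matching over a sample's reads and
#' tallies per-epitope counts (every library epitope present, zeros kept).
#'
#' @param seqs character vector of the sample's read sequences.
#' @param cfg an [extraction_config()].
#' @param library epitope library with inserts.
#' @return list with `counts` (tibble epitope_id, count), `assigned` and
#'   `unmatched_insert` read tallies.
#' @export
count_sample <- function(seqs, cfg, library) {
  ins <- extract_insert(seqs, cfg)
  ids <- assign_epitope(ins, library, mode = cfg$match_mode)
  tab <- table(factor(ids, levels = library$id))
  counts <- tibble::tibble(epitope_id = library$id, count = as.integer(tab))
  list(
    counts = counts,
    assigned = sum(!is.na(ids)),
    unmatched_insert = sum(is.na(ids))
  )
}

#' Merge per-sample counts into a count matrix
#'
#' Aligns per-sample tallies on the union of epitope ids (zero-filled) into
#' a wide epitope-by-sample tibble carrying per-sample totals and the
#' global unassigned-read tally as a `totals` attribute.
#'
#' @param columns named list of [count_sample()] results (names = sample
#'   ids).
#' @param unassigned_index number of reads no sample claimed at
#'   demultiplexing.
#' @return tibble of class `sabr_counts`: column `epitope_id` plus one
#'   integer column per sample; `attr(, "totals")` holds sample_id,
#'   assigned, unmatched_insert; `attr(, "unassigned_index")` the global
#'   tally.
#' @export
merge_counts <- function(columns, unassigned_index = 0L) {
  if (is.null(names(columns)) || anyDuplicated(names(columns))) {
    rlang::abort("columns must be uniquely named by sample_id")
  }
  long <- dplyr::bind_rows(purrr::map(columns, "counts"), .id = "sample_id")
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  totals <- tibble::tibble(
    sample_id = names(columns),
    assigned = unname(vapply(columns, function(x) as.integer(x$assigned), 1L)),
    unmatched_insert = unname(vapply(columns,
                                     function(x) as.integer(x$unmatched_insert), 1L))
  )
  attr(wide, "totals") <- totals
  attr(wide, "unassigned_index") <- as.integer(unassigned_index)
  class(wide) <- unique(c("sabr_counts", class(wide)))
  wide
}

#' Process a whole screen from reads to a count matrix
#'
#' Demultiplexes, extracts, matches and merges in one call; every sample in
#' the sheet yields a column even when it received no reads.
#'
#' @param reads read table (see [read_screen_fastq()]).
#' @param sheet sample sheet.
#' @param cfg an [extraction_config()].
#' @param library epitope library with inserts.
#' @param tol_index per-index Hamming tolerance.
#' @return `sabr_counts` tibble (see [merge_counts()]).
#' @export
process_screen_reads <- function(reads, sheet, cfg, library, tol_index = 1L) {
  sheet <- read_sample_sheet(sheet)
  dm <- demultiplex(reads, sheet, tol = tol_index)
  cols <- lapply(sheet$sample_id, function(sid) {
    count_sample(dm$seq[!is.na(dm$sample_id) & dm$sample_id == sid], cfg, library)
  })
  names(cols) <- sheet$sample_id
  merge_counts(cols, unassigned_index = sum(is.na(dm$sample_id)))
}

#' Read / write count matrices
#'
#' TSV layout: rows are epitopes, columns samples, first column
#' `epitope_id`. The run report JSON stores per-sample totals and the
#' unassigned tally.
#'
#' @param x `sabr_counts` tibble.
#' @param path TSV path.
#' @param report optional JSON run-report path for the writer.
#' @return reader: `sabr_counts` tibble (totals reconstructed from the
#'   report when given); writers return paths invisibly.
#' @export
write_counts <- function(x, path, report = NULL) {
  readr::write_tsv(tibble::as_tibble(x), path)
  if (!is.null(report)) {
    jsonlite::write_json(
      list(totals = attr(x, "totals"),
           unassigned_index = attr(x, "unassigned_index") %||% 0L),
      report, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, report = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(report)) {
    rep <- jsonlite::read_json(report, simplifyVector = TRUE)
    attr(x, "totals") <- tibble::as_tibble(rep$totals)
    attr(x, "unassigned_index") <- rep$unassigned_index
  }
  class(x) <- unique(c("sabr_counts", class(x)))
  x
}
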