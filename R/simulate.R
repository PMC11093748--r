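#' Parameters of a simulated SABR screen
#'
#' Defaults reflect the screen conditions the workflow is designed around:
#' a 1,000-epitope library with log-normal representation, cognate-carrying
#' cells at 0.05% of the co-incubation, a top-2% reporter sort gate, a
#' 6 SD reporter shift for cognate-presenting cells, and 10^5 reads per
#' sample.
#'
#' @param n_epitopes library size (>= 2).
#' @param abundance_sd log-normal dispersion (sdlog) of library
#'   representation; 0 gives a uniform library.
#' @param gate_fraction fraction of cells collected by the sort gate
#'   (default 0.02, i.e. the top 2%).
#' @param effect_size reporter-signal shift of cognate-presenting cells, in
#'   SDs of the background signal (default 6).
#' @param cognate_frequency pre-sort cell frequency pinned for each cognate
#'   epitope (default 5e-4); `NULL` leaves cognate representation to the
#'   library abundance draw.
#' @param reads_per_sample sequencing depth per sample (default 1e5).
#' @param n_cells cells entering each co-incubation (default 1e6).
#' @param index_error_rate,read_error_rate per-base substitution rates for
#'   simulated index and insert sequencing (default 0).
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_epitopes = 1000L, abundance_sd = 1, gate_fraction = 0.02,
                       effect_size = 6, cognate_frequency = 5e-4,
                       reads_per_sample = 1e5, n_cells = 1e6,
                       index_error_rate = 0, read_error_rate = 0) {
  if (gate_fraction <= 0 || gate_fraction > 1) {
    rlang::abort("gate_fraction must be in (0, 1]")
  }
  rates <- c(index_error_rate, read_error_rate)
  if (any(rates < 0 | rates > 1)) rlang::abort("error rates must be in [0, 1]")
  structure(
    list(n_epitopes = as.integer(n_epitopes), abundance_sd = abundance_sd,
         gate_fraction = gate_fraction, effect_size = effect_size,
         cognate_frequency = cognate_frequency,
         reads_per_sample = as.integer(reads_per_sample),
         n_cells = as.integer(n_cells),
         index_error_rate = index_error_rate, read_error_rate = read_error_rate),
    class = "sim_params"
  )
}

#' Simulate an epitope library with log-normal representation
#'
#' Draws `n_epitopes` random peptides (lengths uniform in
#' `length_bounds`), unique by construction, and a log-normal abundance
#' vector normalised to sum to one — emulating the unequal representation
#' of a cloned pooled library.
#'
#' @param params a [sim_params()].
#' @param seed integer seed (all randomness in the simulator is seeded
#'   explicitly; the caller's RNG state is untouched).
#' @param length_bounds peptide length range (default `c(12, 25)`).
#' @return [sabr_library()] tibble with an extra `abundance` column.
#' @export
simulate_library <- function(params = sim_params(), seed = 1L,
                             length_bounds = c(12L, 25L)) {
  n <- params$n_epitopes
  if (n < 2) rlang::abort("n_epitopes must be >= 2")
  withr::with_seed(seed, {
    lens <- sample(seq.int(length_bounds[1], length_bounds[2]), n, replace = TRUE)
    peps <- vapply(lens, function(l) {
      paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
    }, "")
    while (anyDuplicated(peps)) {
      dup <- which(duplicated(peps))
      peps[dup] <- vapply(lens[dup], function(l) {
        paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
      }, "")
    }
    ab <- if (params$abundance_sd == 0) {
      rep(1 / n, n)
    } else {
      raw <- stats::rlnorm(n, meanlog = 0, sdlog = params$abundance_sd)
      raw / sum(raw)
    }
    lib <- tibble::tibble(
      id = sprintf("EPI%05d", seq_len(n)),
      peptide = peps,
      category = "natural",
      abundance = ab
    )
  })
  sabr_library(lib, name = "simulated", allele = "I-Ag7",
               length_bounds = length_bounds)
}

#' Simulate one co-incubation and sort
#'
#' Cells take one epitope each (one SABR per cell), proportionally to
#' library abundance; when `cognate_frequency` is set, each epitope cognate
#' to a present TCR is instead pinned at exactly
#' `round(cognate_frequency * n_cells)` cells and the remainder drawn from
#' the other epitopes. Reporter signal is standard normal background plus
#' `effect_size` for cells presenting a cognate of any present TCR; the
#' sorted sample is the top `gate_fraction` of cells by signal, the
#' unsorted sample is all cells. Read counts are multinomial downsamples
#' of the cell compositions to `reads_per_sample`.
#'
#' @param library library from [simulate_library()] (needs `abundance`).
#' @param params a [sim_params()].
#' @param tcr_set character vector of TCR labels present in the
#'   co-incubation.
#' @param cognate_map named list, TCR label -> cognate epitope id(s).
#' @param seed integer seed.
#' @return list of class `sabr_true_state`: per-epitope `unsorted_cells`
#'   and `sorted_cells` (cell tallies, named by epitope id),
#'   `unsorted_counts` / `sorted_counts` (read tallies), `gate_size`,
#'   `cognate_ids`, and the parameters used.
#' @export
simulate_sort <- function(library, params = sim_params(), tcr_set = character(),
                          cognate_map = list(), seed = 1L) {
  n <- nrow(library)
  n_cells <- params$n_cells
  gate_n <- round(params$gate_fraction * n_cells)
  if (gate_n < 1) rlang::abort("sort gate smaller than one cell")
  cognate_ids <- unique(unlist(cognate_map[names(cognate_map) %in% tcr_set]))
  if (length(setdiff(cognate_ids, library$id))) {
    rlang::abort("cognate epitopes absent from library")
  }
  cog_idx <- match(cognate_ids, library$id)
  withr::with_seed(seed, {
    ab <- library$abundance
    if (!is.null(params$cognate_frequency) && length(cog_idx)) {
      n_cog_each <- round(params$cognate_frequency * n_cells)
      pinned <- rep(cog_idx, each = n_cog_each)
      rest_prob <- ab
      rest_prob[cog_idx] <- 0
      rest <- sample.int(n, n_cells - length(pinned), replace = TRUE,
                         prob = rest_prob)
      epi <- c(pinned, rest)
    } else {
      epi <- sample.int(n, n_cells, replace = TRUE, prob = ab)
    }
    signal <- stats::rnorm(n_cells)
    is_cog <- epi %in% cog_idx
    signal[is_cog] <- signal[is_cog] + params$effect_size
    thr <- -sort(-signal, partial = gate_n)[gate_n]
    in_gate <- which(signal >= thr)
    if (length(in_gate) > gate_n) in_gate <- in_gate[seq_len(gate_n)]
    unsorted_cells <- tabulate(epi, nbins = n)
    sorted_cells <- tabulate(epi[in_gate], nbins = n)
    unsorted_counts <- as.integer(stats::rmultinom(
      1, params$reads_per_sample, unsorted_cells / sum(unsorted_cells)))
    sorted_counts <- as.integer(stats::rmultinom(
      1, params$reads_per_sample, sorted_cells / sum(sorted_cells)))
  })
  names(unsorted_cells) <- names(sorted_cells) <- library$id
  names(unsorted_counts) <- names(sorted_counts) <- library$id
  structure(
    list(unsorted_cells = unsorted_cells, sorted_cells = sorted_cells,
         unsorted_counts = unsorted_counts, sorted_counts = sorted_counts,
         gate_size = length(in_gate), n_cells = n_cells,
         cognate_ids = cognate_ids, tcr_set = tcr_set, params = params),
    class = "sabr_true_state"
  )
}

#' Pin selected epitopes to a fixed library frequency
#'
#' Sets the abundance of `ids` to `frequency` each and rescales the
#' remaining epitopes so the vector still sums to one.
#'
#' @param library library with an `abundance` column.
#' @param ids epitope ids to pin.
#' @param frequency target frequency per pinned epitope.
#' @return the library with adjusted abundance.
#' @export
pin_abundance <- function(library, ids, frequency) {
  idx <- match(ids, library$id)
  if (anyNA(idx)) rlang::abort("epitope(s) to pin absent from library")
  if (frequency * length(idx) >= 1) rlang::abort("pinned mass must be < 1")
  ab <- library$abundance
  rest <- setdiff(seq_along(ab), idx)
  ab[rest] <- ab[rest] / sum(ab[rest]) * (1 - frequency * length(idx))
  ab[idx] <- frequency
  library$abundance <- ab
  library
}

#' Fold enrichment of an epitope between two compositions
#'
#' Ratio of the epitope's frequency in the post-sort composition to its
#' frequency pre sort. Inputs may be counts or frequencies; each vector is
#' renormalised.
#'
#' @param pre,post named numeric vectors (names = epitope ids).
#' @param epitope epitope id.
#' @return the fold enrichment (post frequency / pre frequency).
#' @export
enrichment_factor <- function(pre, post, epitope) {
  if (!epitope %in% names(pre) || !epitope %in% names(post)) {
    rlang::abort(paste0("epitope ", epitope, " absent from composition"))
  }
  f_pre <- pre[[epitope]] / sum(pre)
  if (f_pre <= 0) rlang::abort("pre-sort frequency must be > 0")
  f_post <- post[[epitope]] / sum(post)
  unname(f_post / f_pre)
}

mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1L), "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Emit simulated amplicon reads for counted molecules
#'
#' Each counted molecule of each sample becomes one read
#' `anchor5 + insert + anchor3`, with substitution errors applied to the
#' read at `read_error_rate` and to the observed sample indexes at
#' `index_error_rate`. Deterministic given the seed.
#'
#' @param sample_counts named list: sample_id -> named per-epitope read
#'   counts (e.g. `sorted_counts` / `unsorted_counts` of a
#'   [simulate_sort()] state).
#' @param library library with back-translated `insert`s.
#' @param sheet sample sheet giving each sample's i7/i5 indexes.
#' @param cfg an [extraction_config()] supplying the amplicon anchors.
#' @param params a [sim_params()] (error rates).
#' @param seed integer seed.
#' @param read_length optional fixed read length; an amplicon longer than
#'   it aborts (reads are emitted at full amplicon length otherwise).
#' @return read tibble (read_id, seq, i7, i5) as from
#'   [read_screen_fastq()].
#' @export
simulate_reads <- function(sample_counts, library, sheet, cfg,
                           params = sim_params(), seed = 1L,
                           read_length = NULL) {
  if (!"insert" %in% names(library)) {
    rlang::abort("library has no `insert` column; run add_inserts() first")
  }
  sheet <- read_sample_sheet(sheet)
  amplicons <- paste0(cfg$anchor5, library$insert, cfg$anchor3)
  if (!is.null(read_length) && max(nchar(amplicons)) > read_length) {
    rlang::abort("read length budget shorter than the longest amplicon")
  }
  withr::with_seed(seed, {
    out <- lapply(sheet$sample_id, function(sid) {
      cnt <- sample_counts[[sid]]
      if (is.null(cnt)) rlang::abort(paste0("no counts for sample ", sid))
      idx <- rep(match(names(cnt), library$id), cnt)
      if (length(idx) == 0) {
        return(tibble::tibble(read_id = character(), seq = character(),
                              i7 = character(), i5 = character()))
      }
      row <- sheet[sheet$sample_id == sid, ]
      tibble::tibble(
        read_id = paste0(sid, ":", seq_along(idx)),
        seq = mutate_bases(amplicons[idx], params$read_error_rate),
        i7 = mutate_bases(rep(row$i7_index, length(idx)), params$index_error_rate),
        i5 = mutate_bases(rep(row$i5_index, length(idx)), params$index_error_rate)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Write a read table as FASTQ
#'
#' Read 1 carries the amplicon; the observed index pair is stored in the
#' Illumina-style header comment (`1:N:0:I7+I5`). Constant Phred 40
#' qualities (no quality model is simulated). `.gz` paths are compressed.
#'
#' @param reads read tibble (read_id, seq, i7, i5).
#' @param r1 output FASTQ(.gz) path.
#' @export
write_screen_fastq <- function(reads, r1) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- paste0(reads$read_id, " 1:N:0:", reads$i7, "+", reads$i5)
  qual <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n) {
    strrep("I", n)
  }, ""))
  Biostrings::writeXStringSet(dna, r1, format = "fastq", qualities = qual,
                              compress = endsWith(r1, ".gz"))
  invisible(r1)
}

#' Simulate a complete screen at the count level
#'
#' Runs one [simulate_sort()] per sorted sample of the design (seeded
#' per-replicate from `seed`) and draws each unsorted sample as a
#' multinomial read sample of the full cell population, returning a ready
#' count matrix plus the per-replicate true states.
#'
#' @param library library from [simulate_library()].
#' @param design a [screen_design()]; sorted samples' `tcrs` determine
#'   which cognates are boosted in each replicate.
#' @param cognate_map named list, TCR label -> cognate epitope id(s).
#' @param params a [sim_params()].
#' @param seed integer base seed.
#' @return list: `counts` (`sabr_counts` tibble), `states` (named list of
#'   `sabr_true_state` per sorted sample), `design`, `cognate_map`.
#' @export
simulate_screen <- function(library, design, cognate_map = list(),
                            params = sim_params(), seed = 1L) {
  # the pinned cognate frequency is a property of the cell pool, so it must
  # hold in the unsorted library samples as well as in each co-incubation
  if (!is.null(params$cognate_frequency) && length(cognate_map)) {
    library <- pin_abundance(library, unique(unlist(cognate_map)),
                             params$cognate_frequency)
  }
  samp <- design$samples
  cols <- list()
  states <- list()
  for (i in seq_len(nrow(samp))) {
    sid <- samp$sample_id[i]
    sub_seed <- (seed * 1000L + i) %% .Machine$integer.max
    if (samp$role[i] == "sorted") {
      st <- simulate_sort(library, params, tcr_set = samp$tcrs[[i]],
                          cognate_map = cognate_map, seed = sub_seed)
      states[[sid]] <- st
      cnt <- st$sorted_counts
    } else {
      cnt <- withr::with_seed(sub_seed, {
        as.integer(stats::rmultinom(1, params$reads_per_sample, library$abundance))
      })
      names(cnt) <- library$id
    }
    cols[[sid]] <- list(
      counts = tibble::tibble(epitope_id = library$id, count = unname(cnt)),
      assigned = sum(cnt), unmatched_insert = 0L
    )
  }
  list(counts = merge_counts(cols), states = states, design = design,
       cognate_map = cognate_map)
}
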