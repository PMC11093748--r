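#' Describe a screen design
#'
#' Ties count-matrix samples to their roles: which samples are unsorted
#' library references, which are sorted replicates, and which TCRs each
#' sorted co-incubation contained (one TCR for single screens, several for
#' multiplexed / dropout designs). The positive-control TCR and its known
#' cognate epitopes drive confidence-zone calibration.
#'
#' @param samples tibble with columns sample_id, role (`sorted` /
#'   `unsorted`), replicate, and tcrs (list-column of TCR labels, or a
#'   `tcr_label` character column with comma-separated labels).
#' @param control_tcr label of the positive-control TCR (optional until
#'   zones are calibrated).
#' @param control_cognates epitope ids known cognate to the control TCR.
#' @return list of class `screen_design`.
#' @export
screen_design <- function(samples, control_tcr = NULL, control_cognates = character()) {
  samples <- tibble::as_tibble(samples)
  if (!"tcrs" %in% names(samples)) {
    if ("tcr_label" %in% names(samples)) {
      samples$tcrs <- lapply(strsplit(samples$tcr_label, ","), trimws)
      samples$tcrs[samples$role == "unsorted"] <- list(character())
    } else {
      rlang::abort("samples need a `tcrs` list-column or `tcr_label` column")
    }
  }
  if (!any(samples$role == "unsorted")) {
    rlang::abort("design needs at least one unsorted sample")
  }
  sorted <- samples[samples$role == "sorted", , drop = FALSE]
  if (any(lengths(sorted$tcrs) == 0)) {
    rlang::abort("every sorted sample must list at least one TCR")
  }
  structure(
    list(samples = samples, control_tcr = control_tcr,
         control_cognates = control_cognates),
    class = "screen_design"
  )
}

#' Read / write a screen design as JSON
#'
#' @param path JSON path.
#' @param design a [screen_design()].
#' @export
read_screen_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  samples <- tibble::as_tibble(x$samples)
  if (is.character(samples$tcrs)) samples$tcrs <- strsplit(samples$tcrs, ",")
  samples$tcrs <- lapply(samples$tcrs, function(t) trimws(unlist(t)))
  screen_design(samples, control_tcr = x$control_tcr,
                control_cognates = unlist(x$control_cognates))
}

#' @rdname read_screen_design
#' @export
write_screen_design <- function(design, path) {
  out <- list(
    samples = dplyr::mutate(
      design$samples,
      tcrs = vapply(.data$tcrs, paste, "", collapse = ",")
    ),
    control_tcr = design$control_tcr,
    control_cognates = design$control_cognates
  )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Normalise counts to counts-per-million
#'
#' Adds a pseudocount to every cell and scales each sample column to one
#' million, taming zero counts before the abundance regression.
#'
#' @param counts `sabr_counts` tibble (column `epitope_id` plus one column
#'   per sample).
#' @param pseudocount added to every count before scaling (default 0.5).
#' @return tibble of the same shape with CPM abundances.
#' @export
normalize_cpm <- function(counts, pseudocount = 0.5) {
  counts <- tibble::as_tibble(counts)
  samp <- setdiff(names(counts), "epitope_id")
  for (s in samp) {
    col <- counts[[s]] + pseudocount
    if (sum(counts[[s]]) == 0 && pseudocount == 0) {
      rlang::abort(paste0("all-zero sample column: ", s))
    }
    counts[[s]] <- col / sum(col) * 1e6
  }
  counts
}

#' Fit the expected-abundance model for one sorted replicate
#'
#' Ordinary least squares (with intercept) of the sorted sample's
#' normalised abundance on the mean normalised unsorted abundance; its
#' fitted values are the expected abundance of each epitope absent any
#' TCR-driven enrichment, so the residual is the enrichment score.
#'
#' @param mean_unsorted numeric vector, mean unsorted CPM per epitope.
#' @param sorted numeric vector, sorted-sample CPM per epitope.
#' @return object of class `sabr_abundance_fit` wrapping the `lm`.
#' @export
fit_expected_abundance <- function(mean_unsorted, sorted) {
  if (length(mean_unsorted) < 3) rlang::abort("need >= 3 epitopes to fit")
  if (stats::var(mean_unsorted) == 0) {
    rlang::abort("zero variance in mean unsorted abundance; cannot fit")
  }
  fit <- stats::lm(sorted ~ mean_unsorted,
                   data = data.frame(sorted = sorted, mean_unsorted = mean_unsorted))
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         sigma = summary(fit)$sigma),
    class = "sabr_abundance_fit"
  )
}

#' @export
print.sabr_abundance_fit <- function(x, ...) {
  cat("Expected-abundance fit: expected =", format(x$intercept, digits = 4),
      "+", format(x$slope, digits = 4), "* mean_unsorted",
      " (R^2 =", format(x$r_squared, digits = 3), ")\n")
  invisible(x)
}

#' Tidy an expected-abundance fit
#'
#' @param x a `sabr_abundance_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per coefficient (term, estimate, std.error,
#'   statistic, p.value); `glance()`: one row of fit diagnostics.
#' @importFrom generics tidy glance
#' @exportS3Method generics::tidy
tidy.sabr_abundance_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @rdname tidy.sabr_abundance_fit
#' @exportS3Method generics::glance
glance.sabr_abundance_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, sigma = x$sigma,
    slope = x$slope, intercept = x$intercept,
    nobs = stats::nobs(x$fit)
  )
}

#' Compute per-replicate enrichment scores
#'
#' For every sorted replicate, fits the expected-abundance regression
#' against the mean unsorted abundance and scores each epitope by the
#' difference between measured and expected abundance (ES, in CPM units;
#' `studentize = TRUE` divides by the residual SD instead).
#'
#' @param design a [screen_design()].
#' @param counts `sabr_counts` tibble.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @param studentize divide residuals by the fit's residual SD.
#' @return tibble of class `sabr_es`, one row per sorted sample x epitope:
#'   sample_id, replicate, epitope_id, observed, expected, es; fitted
#'   models kept in `attr(, "fits")`, the design in `attr(, "design")`.
#' @export
compute_es <- function(design, counts, pseudocount = 0.5, studentize = FALSE) {
  stopifnot(inherits(design, "screen_design"))
  counts <- tibble::as_tibble(counts)
  samp <- design$samples
  missing <- setdiff(samp$sample_id, names(counts))
  if (length(missing)) {
    rlang::abort(paste0("design samples absent from counts: ",
                        paste(missing, collapse = ", ")))
  }
  cpm <- normalize_cpm(counts[c("epitope_id", samp$sample_id)], pseudocount)
  unsorted_ids <- samp$sample_id[samp$role == "unsorted"]
  mean_unsorted <- rowMeans(as.matrix(cpm[unsorted_ids]))
  sorted <- samp[samp$role == "sorted", , drop = FALSE]
  fits <- list()
  rows <- vector("list", nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    sid <- sorted$sample_id[i]
    obs <- cpm[[sid]]
    fit <- fit_expected_abundance(mean_unsorted, obs)
    fits[[sid]] <- fit
    expected <- unname(stats::fitted(fit$fit))
    es <- obs - expected
    if (studentize) es <- es / fit$sigma
    rows[[i]] <- tibble::tibble(
      sample_id = sid, replicate = sorted$replicate[i],
      epitope_id = cpm$epitope_id, observed = obs, expected = expected, es = es
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "design") <- design
  class(out) <- unique(c("sabr_es", class(out)))
  out
}

#' Aggregate enrichment scores per TCR
#'
#' A TCR's score for an epitope is the mean ES over the sorted replicates
#' whose co-incubation contained that TCR — the deconvolution rule for
#' dropout designs, which reduces to the plain replicate mean for
#' single-TCR screens. In contrast mode the mean ES over replicates
#' lacking the TCR is additionally subtracted, sharpening dropout designs.
#'
#' @param es `sabr_es` tibble from [compute_es()].
#' @param design the [screen_design()] (defaults to the one stored on
#'   `es`).
#' @param contrast subtract the mean ES of replicates lacking each TCR.
#' @return tibble of class `sabr_tcr_scores`: tcr, epitope_id, mean_es,
#'   n_replicates, and a `replicate_es` list-column of per-replicate ES
#'   values.
#' @export
score_by_tcr <- function(es, design = attr(es, "design"), contrast = FALSE) {
  samp <- design$samples[design$samples$role == "sorted", , drop = FALSE]
  tcrs <- sort(unique(unlist(samp$tcrs)))
  rows <- vector("list", length(tcrs))
  for (k in seq_along(tcrs)) {
    tcr <- tcrs[k]
    with_ids <- samp$sample_id[vapply(samp$tcrs, function(t) tcr %in% t, TRUE)]
    without_ids <- setdiff(samp$sample_id, with_ids)
    if (contrast && length(without_ids) == 0) {
      rlang::abort(paste0("TCR ", tcr,
                          " is present in every replicate; contrast mode impossible"))
    }
    sub <- es[es$sample_id %in% with_ids, c("sample_id", "epitope_id", "es")]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$epitope_id),
      mean_es = mean(.data$es),
      n_replicates = dplyr::n(),
      replicate_es = list(.data$es),
      .groups = "drop"
    )
    if (contrast) {
      ref <- es[es$sample_id %in% without_ids, c("epitope_id", "es")]
      ref <- dplyr::summarise(dplyr::group_by(ref, .data$epitope_id),
                              ref_es = mean(.data$es), .groups = "drop")
      agg <- dplyr::left_join(agg, ref, by = "epitope_id")
      agg$mean_es <- agg$mean_es - agg$ref_es
      agg$ref_es <- NULL
    }
    agg$tcr <- tcr
    rows[[k]] <- agg
  }
  out <- dplyr::bind_rows(rows)[, c("tcr", "epitope_id", "mean_es",
                                    "n_replicates", "replicate_es")]
  attr(out, "design") <- design
  class(out) <- unique(c("sabr_tcr_scores", class(out)))
  out
}

#' Calibrate two-tier confidence zones from the control TCR
#'
#' The weakest positive-control cognate anchors the zones: with `base` the
#' minimum mean ES over the control TCR's cognate epitopes, the
#' high-confidence threshold is `fractions[1] * base` and the
#' low-confidence threshold `fractions[2] * base`. A control cognate with
#' non-positive mean ES indicates a failed screen and aborts.
#'
#' @param scores `sabr_tcr_scores` tibble (must contain the control TCR).
#' @param control_tcr,cognates control TCR label and its cognate epitope
#'   ids (default from the stored design).
#' @param fractions length-2 numeric, high and low fractions of the base
#'   (default `c(0.5, 0.25)`).
#' @return list of class `sabr_zones`: high_threshold, low_threshold,
#'   provenance (control cognate ES values and fractions).
#' @export
calibrate_zones <- function(scores, control_tcr = NULL, cognates = NULL,
                            fractions = c(0.5, 0.25)) {
  design <- attr(scores, "design")
  control_tcr <- control_tcr %||% design$control_tcr
  cognates <- cognates %||% design$control_cognates
  if (is.null(control_tcr) || length(cognates) == 0) {
    rlang::abort("need a control TCR and at least one cognate epitope")
  }
  if (fractions[1] < fractions[2] || any(fractions <= 0)) {
    rlang::abort("fractions must be positive with fractions[1] >= fractions[2]")
  }
  ctl <- scores[scores$tcr == control_tcr & scores$epitope_id %in% cognates, ,
                drop = FALSE]
  if (nrow(ctl) < length(cognates)) {
    rlang::abort("some control cognates missing from the score table")
  }
  if (any(ctl$mean_es <= 0)) {
    rlang::abort(paste0(
      "control cognate(s) with non-positive mean ES (failed screen signal): ",
      paste(ctl$epitope_id[ctl$mean_es <= 0], collapse = ", ")
    ))
  }
  base <- min(ctl$mean_es)
  structure(
    list(high_threshold = fractions[1] * base,
         low_threshold = fractions[2] * base,
         provenance = list(control_tcr = control_tcr,
                           cognate_es = stats::setNames(ctl$mean_es, ctl$epitope_id),
                           fractions = fractions, base = base)),
    class = "sabr_zones"
  )
}

#' Read / write confidence zones as JSON
#'
#' @param zones a `sabr_zones` object.
#' @param path JSON path.
#' @export
write_zones <- function(zones, path) {
  jsonlite::write_json(unclass(zones), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_zones
#' @export
read_zones <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "sabr_zones")
}

#' Call putative hits against calibrated zones
#'
#' Tier `high` when mean ES >= the high threshold, `low` when it falls
#' between the two thresholds, `none` otherwise. Hits are ordered by
#' descending mean ES, ties broken by epitope id.
#'
#' @param scores `sabr_tcr_scores` tibble.
#' @param zones a [calibrate_zones()] result.
#' @param keep_all keep `none`-tier rows (default `FALSE`: hits only).
#' @return tibble with an added `tier` column, sorted by tcr then
#'   descending mean ES.
#' @export
call_hits <- function(scores, zones, keep_all = FALSE) {
  scores$tier <- dplyr::case_when(
    scores$mean_es >= zones$high_threshold ~ "high",
    scores$mean_es >= zones$low_threshold ~ "low",
    TRUE ~ "none"
  )
  out <- dplyr::arrange(scores, .data$tcr, dplyr::desc(.data$mean_es),
                        .data$epitope_id)
  if (!keep_all) out <- out[out$tier != "none", , drop = FALSE]
  attr(out, "zones") <- zones
  out
}

#' Deconvolute a multiplexed dropout screen
#'
#' Convenience wrapper for the leave-one-out design: computes
#' per-replicate ES, then scores each TCR by the mean ES over the
#' replicates that contained it (optionally contrasting against replicates
#' that did not). Requires each TCR to be absent from at least one
#' replicate and present in at least two.
#'
#' @inheritParams compute_es
#' @param contrast subtract the mean ES over TCR-lacking replicates.
#' @return `sabr_tcr_scores` tibble (see [score_by_tcr()]).
#' @export
dropout_deconvolute <- function(design, counts, pseudocount = 0.5,
                                contrast = FALSE, studentize = FALSE) {
  sorted <- design$samples[design$samples$role == "sorted", , drop = FALSE]
  tcrs <- unique(unlist(sorted$tcrs))
  n_with <- vapply(tcrs, function(tcr) {
    sum(vapply(sorted$tcrs, function(t) tcr %in% t, TRUE))
  }, 1L)
  thin <- tcrs[n_with < 2]
  if (length(thin)) {
    rlang::warn(paste0("TCR(s) present in fewer than 2 replicates: ",
                       paste(thin, collapse = ", ")))
  }
  es <- compute_es(design, counts, pseudocount = pseudocount,
                   studentize = studentize)
  score_by_tcr(es, design, contrast = contrast)
}

#' Write a per-TCR ES table
#'
#' TSV with one row per (tcr, epitope): mean ES, replicate count, per-
#' replicate ES values (comma-joined) and tier when present.
#'
#' @param scores `sabr_tcr_scores` tibble (optionally after
#'   [call_hits()]).
#' @param path TSV path.
#' @export
write_es_table <- function(scores, path) {
  flat <- tibble::as_tibble(scores)
  flat$replicate_es <- vapply(flat$replicate_es, function(v) {
    paste(format(v, trim = TRUE), collapse = ",")
  }, "")
  readr::write_tsv(flat, path)
  invisible(path)
}
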