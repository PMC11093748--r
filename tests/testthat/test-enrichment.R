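# small helper: a design with u unsorted and s sorted single-TCR replicates
single_design <- function(s = 3, u = 3, tcr = "TCRX", control = NULL,
                          cognates = character()) {
  samples <- tibble::tibble(
    sample_id = c(sprintf("sort%d", seq_len(s)), sprintf("uns%d", seq_len(u))),
    role = c(rep("sorted", s), rep("unsorted", u)),
    replicate = c(seq_len(s), seq_len(u)),
    tcrs = c(rep(list(tcr), s), rep(list(character()), u))
  )
  screen_design(samples, control_tcr = control, control_cognates = cognates)
}

test_that("CPM normalisation scales columns as specified", {
  m <- tibble::tibble(epitope_id = c("a", "b", "c"), S = c(1L, 1L, 2L))
  expect_equal(normalize_cpm(m, pseudocount = 0)$S, c(250000, 250000, 500000))
  # pseudocount 0.5 on [0, 10]: hand arithmetic 0.5/11 and 10.5/11 scaled
  m2 <- tibble::tibble(epitope_id = c("a", "b"), S = c(0L, 10L))
  expect_equal(normalize_cpm(m2, pseudocount = 0.5)$S,
               c(0.5 / 11, 10.5 / 11) * 1e6)
  m3 <- tibble::tibble(epitope_id = c("a", "b"), S = c(0L, 0L))
  expect_error(normalize_cpm(m3, pseudocount = 0), "all-zero.*S")
})

test_that("expected-abundance OLS matches the normal-equation oracle", {
  # identity fit
  x <- c(10, 20, 30, 40, 50)
  f <- suppressWarnings(fit_expected_abundance(x, x))  # perfect fit
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  expect_equal(unname(stats::residuals(f$fit)), rep(0, 5), tolerance = 1e-9)

  # exact linear data recovered to machine precision
  f2 <- suppressWarnings(fit_expected_abundance(x, 2 * x + 7))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 7, tolerance = 1e-9)

  # 5-epitope toy table vs closed-form normal equations
  y <- c(12, 18, 35, 38, 60)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope_hand <- sxy / sxx
  intercept_hand <- mean(y) - slope_hand * mean(x)
  f3 <- fit_expected_abundance(x, y)
  expect_equal(f3$slope, slope_hand, tolerance = 1e-12)
  expect_equal(f3$intercept, intercept_hand, tolerance = 1e-12)

  expect_error(fit_expected_abundance(rep(1, 5), x), "zero variance")
  expect_error(fit_expected_abundance(1:2, 1:2), ">= 3")

  # broom-style accessors
  td <- generics::tidy(f3)
  expect_equal(td$estimate, c(intercept_hand, slope_hand), tolerance = 1e-12)
  gl <- generics::glance(f3)
  expect_equal(gl$nobs, 5)
})

test_that("ES is observed minus expected, ~0 for a null screen", {
  set.seed(41)
  n <- 200
  base <- rpois(n, 400)
  counts <- tibble::tibble(
    epitope_id = sprintf("E%03d", 1:n),
    sort1 = rpois(n, base), sort2 = rpois(n, base), sort3 = rpois(n, base),
    uns1 = rpois(n, base), uns2 = rpois(n, base), uns3 = rpois(n, base)
  )
  des <- single_design()
  es <- compute_es(des, counts)
  # residuals of an OLS fit with intercept sum to ~0 per replicate
  sums <- tapply(es$es, es$sample_id, sum)
  expect_true(all(abs(sums) < 1e-6 * 1e6))
  # null screen: every |mean ES| small relative to mean abundance (5000 CPM)
  scores <- score_by_tcr(es)
  expect_lt(max(abs(scores$mean_es)), 0.2 * 1e6 / n)
  # residuals match brute-force least squares recomputation
  cpm <- normalize_cpm(counts)
  mu <- rowMeans(as.matrix(cpm[c("uns1", "uns2", "uns3")]))
  X <- cbind(1, mu)
  beta <- solve(t(X) %*% X, t(X) %*% cpm$sort1)
  res_hand <- cpm$sort1 - X %*% beta
  expect_equal(es$es[es$sample_id == "sort1"], as.numeric(res_hand),
               tolerance = 1e-8)
})

test_that("ES is invariant to epitope relabeling and replicate order", {
  set.seed(43)
  n <- 50
  counts <- tibble::tibble(
    epitope_id = sprintf("E%02d", 1:n),
    sort1 = rpois(n, 300), sort2 = rpois(n, 300),
    uns1 = rpois(n, 300), uns2 = rpois(n, 300)
  )
  des <- single_design(s = 2, u = 2)
  es1 <- compute_es(des, counts)
  # permute rows (relabeling): per-epitope ES identical
  perm <- sample(n)
  es2 <- compute_es(des, counts[perm, ])
  o1 <- order(es1$sample_id, es1$epitope_id)
  o2 <- order(es2$sample_id, es2$epitope_id)
  expect_equal(es1$es[o1], es2$es[o2])
  expect_equal(es1$epitope_id[o1], es2$epitope_id[o2])
  # swap replicate columns in the design: mean ES unchanged
  des_sw <- single_design(s = 2, u = 2)
  des_sw$samples <- des_sw$samples[c(2, 1, 4, 3), ]
  s1 <- score_by_tcr(compute_es(des, counts))
  s2 <- score_by_tcr(compute_es(des_sw, counts))
  expect_equal(s1$mean_es, s2$mean_es)
})

test_that("zones derive from the weakest control cognate and gate hit tiers", {
  scores <- tibble::tibble(
    tcr = "CTRL", epitope_id = c("cogA", "cogB", "bg"),
    mean_es = c(12, 8, 0.1), n_replicates = 3,
    replicate_es = list(0, 0, 0)
  )
  attr(scores, "design") <- screen_design(
    tibble::tibble(sample_id = c("s", "u"), role = c("sorted", "unsorted"),
                   replicate = 1, tcrs = list("CTRL", character())),
    control_tcr = "CTRL", control_cognates = c("cogA", "cogB")
  )
  z <- calibrate_zones(scores)
  expect_equal(z$high_threshold, 4)   # min(12, 8) * 0.5
  expect_equal(z$low_threshold, 2)
  z1 <- calibrate_zones(scores, cognates = "cogA")
  expect_equal(c(z1$high_threshold, z1$low_threshold), c(6, 3))

  bad <- scores
  bad$mean_es[1] <- -1
  expect_error(calibrate_zones(bad), "non-positive")

  # tier boundaries: >= high -> high; [low, high) -> low; else none
  test_scores <- tibble::tibble(
    tcr = "T", epitope_id = c("e1", "e2", "e3", "e4"),
    mean_es = c(6, 3, 2, 4), n_replicates = 1, replicate_es = list(0, 0, 0, 0)
  )
  zz <- structure(list(high_threshold = 5, low_threshold = 2.5),
                  class = "sabr_zones")
  hits <- call_hits(test_scores, zz)
  expect_equal(hits$epitope_id, c("e1", "e4", "e2"))
  expect_equal(hits$tier, c("high", "low", "low"))
  all_rows <- call_hits(test_scores, zz, keep_all = TRUE)
  expect_equal(all_rows$tier[all_rows$epitope_id == "e3"], "none")
  # ordering: descending mean ES, ties by id
  expect_equal(all_rows$epitope_id, c("e1", "e4", "e2", "e3"))

  # zones JSON round trip
  p <- withr::local_tempfile(fileext = ".json")
  write_zones(z, p)
  expect_equal(read_zones(p)$high_threshold, 4)
})

test_that("seeded cognates dominate ES in a simulated single-TCR screen", {
  lib <- simulate_library(sim_params(n_epitopes = 500, reads_per_sample = 50000L,
                                     n_cells = 50000L), seed = 5)
  cog <- lib$id[123]
  des <- single_design(s = 3, u = 3, tcr = "TCRX", control = "TCRX",
                       cognates = cog)
  sim <- simulate_screen(lib, des, cognate_map = list(TCRX = cog),
                         params = sim_params(n_epitopes = 500,
                                             reads_per_sample = 50000L,
                                             n_cells = 50000L),
                         seed = 5)
  scores <- score_by_tcr(compute_es(des, sim$counts))
  expect_equal(scores$epitope_id[which.max(scores$mean_es)], cog)
  # with zones calibrated on this screen's own control, the cognate is the
  # only high-confidence hit among 500 epitopes
  z <- calibrate_zones(scores)
  hits <- call_hits(scores, z)
  expect_true(cog %in% hits$epitope_id[hits$tier == "high"])
  expect_lte(sum(hits$tier == "high"), 3)
})

test_that("ES table writer flattens replicate scores", {
  scores <- tibble::tibble(
    tcr = "T", epitope_id = c("a", "b"), mean_es = c(1.5, 0.5),
    n_replicates = 2, replicate_es = list(c(1, 2), c(0, 1))
  )
  p <- withr::local_tempfile(fileext = ".tsv")
  write_es_table(scores, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(back$replicate_es, c("1,2", "0,1"))
})

test_that("screen designs round-trip through JSON", {
  des <- single_design(s = 2, u = 1, tcr = c("A"), control = "A",
                       cognates = c("e1", "e2"))
  des$samples$tcrs[[1]] <- c("A", "B")
  p <- withr::local_tempfile(fileext = ".json")
  write_screen_design(des, p)
  back <- read_screen_design(p)
  expect_equal(back$samples$tcrs, des$samples$tcrs)
  expect_equal(back$control_cognates, c("e1", "e2"))
  expect_equal(back$control_tcr, "A")
})

test_that("dropout deconvolution recovers cognates in a leave-one-out multiplex", {
  # 7 TCRs, 7 sorted leave-one-out replicates, 4 seeded cognate pairs
  p <- sim_params(n_epitopes = 300, reads_per_sample = 50000L,
                  n_cells = 50000L)
  lib <- simulate_library(p, seed = 17)
  tcrs <- sprintf("TCR%d", 1:7)
  cognate_map <- as.list(stats::setNames(lib$id[c(10, 60, 110, 160)], tcrs[1:4]))
  samples <- tibble::tibble(
    sample_id = c(sprintf("rep%d", 1:7), "uns1", "uns2", "uns3"),
    role = c(rep("sorted", 7), rep("unsorted", 3)),
    replicate = c(1:7, 1:3),
    tcrs = c(lapply(1:7, function(i) tcrs[-i]), rep(list(character()), 3))
  )
  des <- screen_design(samples)
  sim <- simulate_screen(lib, des, cognate_map = cognate_map, params = p,
                         seed = 17)
  scores <- dropout_deconvolute(des, sim$counts)
  for (tcr in tcrs[1:4]) {
    sub <- scores[scores$tcr == tcr, ]
    expect_equal(sub$epitope_id[which.max(sub$mean_es)], cognate_map[[tcr]])
  }
  # contrast mode pulls each cognate further from background
  ctr <- dropout_deconvolute(des, sim$counts, contrast = TRUE)
  for (tcr in tcrs[1:4]) {
    plain <- scores$mean_es[scores$tcr == tcr &
                              scores$epitope_id == cognate_map[[tcr]]]
    con <- ctr$mean_es[ctr$tcr == tcr & ctr$epitope_id == cognate_map[[tcr]]]
    expect_gt(con, plain)
  }
  # degenerate design: TCR in every replicate -> plain mean, contrast errors
  samples2 <- samples
  samples2$tcrs[1:7] <- lapply(1:7, function(i) unique(c(tcrs[-i], "TCR8")))
  des2 <- screen_design(samples2)
  es2 <- compute_es(des2, sim$counts)
  s_all <- score_by_tcr(es2)
  overall <- dplyr::summarise(dplyr::group_by(
    tibble::as_tibble(es2), .data$epitope_id), m = mean(.data$es))
  merged <- dplyr::left_join(s_all[s_all$tcr == "TCR8", ], overall,
                             by = "epitope_id")
  expect_equal(merged$mean_es, merged$m)
  expect_error(score_by_tcr(es2, contrast = TRUE), "every replicate")
})
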