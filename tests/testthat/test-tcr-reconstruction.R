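test_that("reference loading validates anchors and round-trips through FASTA", {
  ref <- fixture_reference()
  expect_setequal(ref$kind, c("V", "J", "C"))
  expect_true(all(translate_nt(ref$nt_seq) == ref$aa_seq))
  # V anchors point at a Cys, J anchors at the F/W of FGXG
  vs <- ref[ref$kind == "V", ]
  expect_true(all(substr(vs$aa_seq, vs$anchor, vs$anchor) == "C"))
  js <- ref[ref$kind == "J", ]
  expect_true(all(grepl("^[FW]G.G",
                        substr(js$aa_seq, js$anchor, nchar(js$aa_seq)))))
  # hand check on TRAV1*01: its only terminal-window Cys is the CDR3 start
  trav1 <- ref[ref$name == "TRAV1*01", ]
  expect_equal(trav1$anchor, nchar(trav1$aa_seq) - 3L)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_allele_reference(ref, fa)
  back <- load_allele_reference(fa)
  expect_equal(back[c("name", "chain", "kind", "nt_seq", "aa_seq", "anchor")],
               ref[c("name", "chain", "kind", "nt_seq", "aa_seq", "anchor")])
})

test_that("segments without their conserved motif are flagged unusable", {
  fa <- withr::local_tempfile(fileext = ".fa")
  dna <- Biostrings::DNAStringSet(c(
    back_translate("GYKLTAGTGTSLLVDP", seed = 1),  # no FGXG / WGXG
    back_translate("DSNYQLIWGSGTKLII", seed = 2)
  ))
  names(dna) <- c("X1|TRAJ90*01|toy|F|J-REGION", "X2|TRAJ33*01|toy|F|J-REGION")
  Biostrings::writeXStringSet(dna, fa)
  expect_warning(ref <- load_allele_reference(fa), "unusable")
  expect_false(ref$usable[ref$name == "TRAJ90*01"])
  expect_true(ref$usable[ref$name == "TRAJ33*01"])
  expect_error(
    reconstruct_chain("TRAJ90*01", "TRAJ33*01", "CAVS", ref = ref),
    "V segment|unusable|is a"
  )
})

test_that("germline-junction CDR3 reproduces straight germline concatenation", {
  ref <- fixture_reference()
  v <- ref[ref$name == "TRAV1*01", ]
  j <- ref[ref$name == "TRAJ12*01", ]
  cc <- ref[ref$name == "TRAC*01", ]
  cdr3 <- paste0(substr(v$aa_seq, v$anchor, nchar(v$aa_seq)),
                 substr(j$aa_seq, 1, j$anchor))
  ch <- reconstruct_chain("TRAV1*01", "TRAJ12*01", cdr3, ref = ref)
  expect_equal(ch$aa, paste0(v$aa_seq, j$aa_seq, cc$aa_seq))
  expect_equal(ch$nt, paste0(v$nt_seq, j$nt_seq, cc$nt_seq))
})

test_that("chains assemble as V-frame + CDR3 + J-tail + C with one CDR3 copy", {
  # hand-assembled toy: V framework 20 aa + Cys anchor, CDR3 11-mer,
  # J remainder 5 aa after the anchor, C 10 aa -> 46 aa chain, CDR3 at 21
  fa <- withr::local_tempfile(fileext = ".fa")
  v_aa <- "MDKILTASFLLGVHLAGVSGC"        # anchor C at 21
  j_aa <- "NTEVFGKGTKLTV"                # F anchor at 5, tail = GKGTKLTV
  j_aa <- "NTEVFGKGT"                    # tail after F = GKGT (4 aa) -- keep 5:
  j_aa <- "NTEVFGKGTL"                   # tail GKGTL (5 aa)
  c_aa <- "DIQNPEPAVY"
  dna <- Biostrings::DNAStringSet(c(
    back_translate(v_aa, seed = 1), back_translate(j_aa, seed = 2),
    back_translate(c_aa, seed = 3)
  ))
  names(dna) <- c("A|TRAV9*01|t|F|V-REGION", "B|TRAJ5*01|t|F|J-REGION",
                  "C|TRAC*01|t|F|C-REGION")
  Biostrings::writeXStringSet(dna, fa)
  ref <- load_allele_reference(fa)
  ch <- reconstruct_chain("TRAV9*01", "TRAJ5*01", "CASSLGGEQYF", ref = ref)
  expect_equal(ch$aa, paste0("MDKILTASFLLGVHLAGVSG", "CASSLGGEQYF", "GKGTL",
                             "DIQNPEPAVY"))
  expect_equal(nchar(ch$aa), 46)
  expect_equal(ch$provenance$cdr3_start, 21L)
  expect_equal(translate_nt(ch$nt), ch$aa)
  expect_equal(n_occurrences(ch$aa, "CASSLGGEQYF"), 1L)
})

test_that("unknown alleles and malformed CDR3s error usefully", {
  ref <- fixture_reference()
  expect_error(reconstruct_chain("TRAV1*01", "TRAJ99*01", "CAVSF", ref = ref),
               "nearest reference names.*TRAJ")
  expect_error(reconstruct_chain("TRAV1*01", "TRAJ12*01", "AVSF", ref = ref),
               "does not start with C")
  expect_warning(
    ch <- reconstruct_chain("TRAV1*01", "TRAJ12*01", "AVSGYKLTF", ref = ref,
                            lenient = TRUE),
    "does not start with C"
  )
  expect_equal(translate_nt(ch$nt), ch$aa)
  expect_error(reconstruct_chain("TRAV1*01", "TRAJ12*01", "", ref = ref),
               "non-empty")
})

test_that("reconstruction is deterministic and translation-consistent", {
  ref <- fixture_reference()
  a1 <- reconstruct_chain("TRAV2*01", "TRAJ33*01", "CTYQDSNYQLIW", ref = ref,
                          seed = 9)
  a2 <- reconstruct_chain("TRAV2*01", "TRAJ33*01", "CTYQDSNYQLIW", ref = ref,
                          seed = 9)
  expect_identical(a1$nt, a2$nt)
  expect_equal(translate_nt(a1$nt), a1$aa)
})

test_that("constructs are flank5 + alpha + 2A + truncated beta, additive in length", {
  ref <- fixture_reference()
  a <- reconstruct_chain("TRAV1*01", "TRAJ12*01", "CTYQGYKLTF", ref = ref)
  b <- reconstruct_chain("TRBV19*01", "TRBJ2-7*01", "CQQTSYEQYF", ref = ref)
  cons <- assemble_construct(a, b, tcr_id = "toy")
  blp <- regexpr("GCTCAGC", b$nt, fixed = TRUE)
  beta_trunc_len <- as.integer(blp) + 6L
  expect_equal(
    nchar(cons$construct_nt),
    6L + nchar(a$nt) + nchar(sabrscreen:::P2A_NT) + beta_trunc_len
  )
  expect_true(startsWith(cons$construct_nt, "GAATTC"))
  # alpha precedes 2A precedes beta
  p_alpha <- regexpr(a$nt, cons$construct_nt, fixed = TRUE)
  p_2a <- regexpr(sabrscreen:::P2A_NT, cons$construct_nt, fixed = TRUE)
  p_beta <- regexpr(substr(b$nt, 1, 30), cons$construct_nt, fixed = TRUE)
  expect_true(p_alpha < p_2a && p_2a < p_beta)
  # truncation motif ends the construct
  expect_true(endsWith(cons$construct_nt, "GCTCAGC"))
})

test_that("internal EcoRI sites are resampled away, leaving exactly one", {
  ref <- fixture_reference()
  a <- reconstruct_chain("TRAV1*01", "TRAJ12*01", "CTYQGYKLTF", ref = ref)
  b <- reconstruct_chain("TRBV19*01", "TRBJ2-7*01", "CQQTSYEQYF", ref = ref)
  # seed an internal GAATTC by direct codon surgery on an E-F dipeptide
  # (GAA = E, TTC = F) placed inside the CDR3
  ch <- reconstruct_chain("TRAV1*01", "TRAJ12*01", "CTYQEFGYKLTF", ref = ref,
                          seed = 2)
  p <- regexpr("EF", ch$aa, fixed = TRUE)
  nt <- ch$nt
  substr(nt, 3 * (p - 1) + 1, 3 * (p - 1) + 6) <- "GAATTC"
  stopifnot(translate_nt(nt) == ch$aa)
  ch$nt <- nt
  expect_equal(n_occurrences(ch$nt, "GAATTC"), 1L)
  cons <- assemble_construct(ch, b, tcr_id = "seeded")
  expect_equal(n_occurrences(cons$construct_nt, "GAATTC"), 1L)  # only the flank
  expect_true(startsWith(cons$construct_nt, "GAATTC"))
  # protein unchanged by synonymous resampling
  coding <- substr(cons$construct_nt, 7, nchar(cons$construct_nt))
  n3 <- (nchar(coding) %/% 3) * 3
  expect_equal(
    substr(translate_nt(substr(coding, 1, n3)), 1, nchar(ch$aa)),
    ch$aa
  )
})

test_that("missing truncation motif in the beta constant region errors", {
  ref <- fixture_reference()
  a <- reconstruct_chain("TRAV1*01", "TRAJ12*01", "CTYQGYKLTF", ref = ref)
  b <- reconstruct_chain("TRBV19*01", "TRBJ2-7*01", "CQQTSYEQYF", ref = ref)
  expect_error(assemble_construct(a, b, beta_trunc_motif = "GCTGAGC"),
               "absent")
})

test_that("clonotype tables reconstruct end to end and write outputs", {
  ref <- fixture_reference()
  clono <- tibble::tibble(
    tcr_id = c("TCR1", "TCR2"),
    va = "TRAV1*01", ja = "TRAJ12*01",
    cdr3a = c("CTYQGYKLTF", "CTYQAAGYKLTF"),
    vb = "TRBV19*01", jb = "TRBJ2-7*01",
    cdr3b = c("CQQTSYEQYF", "CQQTGGSYEQYF")
  )
  out <- reconstruct_tcrs(clono, ref)
  expect_equal(out$tcr_id, c("TCR1", "TCR2"))
  expect_true(all(startsWith(out$construct_nt, "GAATTC")))
  expect_true(all(vapply(seq_len(2), function(i) {
    count_motif_cdr3 <- sum(gregexpr(clono$cdr3a[i], out$alpha_aa[i],
                                     fixed = TRUE)[[1]] > 0)
    count_motif_cdr3 == 1
  }, TRUE)))

  dir <- withr::local_tempdir()
  paths <- write_constructs(out, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "constructs.fa"))
  expect_equal(as.character(fa), setNames(out$construct_nt, out$tcr_id))
  feats <- readr::read_tsv(file.path(dir, "features.tsv"), show_col_types = FALSE)
  expect_setequal(unique(feats$feature), c("flank5", "alpha", "2A", "beta"))
})
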