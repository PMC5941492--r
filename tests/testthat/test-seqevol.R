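# Pairwise alignment, back-translation and NG86 estimation.

test_that("identical proteins align to identity with the diagonal BLOSUM62 score", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  s <- "MKVLAWQHE"
  aln <- align_protein_pair(s, s, mode = "global")
  expect_identical(aln$a, s)
  expect_identical(aln$b, s)
  expected <- sum(BLOSUM62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expect_equal(aln$score, expected)
})

test_that("local alignment with toy scoring matches the textbook DP oracle", {
  a <- "HEAGAWGHEE"
  b <- "PAWHEAE"
  aln <- align_protein_pair(a, b, mode = "local", match = 2, mismatch = -1,
                            gap_open = 0, gap_extend = 1)
  expect_equal(aln$score, oracle_local_dp(a, b, 2, -1, -1))
})

test_that("backtranslation maps residues to codons and gaps to ---", {
  aln <- list(a = "MV", b = "MV", start_a = 1L, start_b = 1L)
  caln <- backtranslate(aln, "ATGGTT", "ATGGTA")
  expect_identical(caln$codons_a, c("ATG", "GTT"))
  expect_identical(caln$codons_b, c("ATG", "GTA"))
  r <- ng86(caln, n_boot = 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)

  gapped <- list(a = "MV-", b = "MVA", start_a = 1L, start_b = 1L)
  caln2 <- backtranslate(gapped, "ATGGTT", "ATGGTTGCA")
  expect_identical(caln2$codons_a[3], "---")
  expect_identical(caln2$codons_b[3], "GCA")
})

test_that("backtranslation rejects a CDS that does not translate to the protein", {
  aln <- list(a = "MV", b = "MV", start_a = 1L, start_b = 1L)
  expect_error(backtranslate(aln, "ATGGC", "ATGGTA"), "divisible")
  expect_error(backtranslate(aln, "ATGGCT", "ATGGTA"), "residue 2")
})

test_that("NG86 reproduces the hand-enumerated two-codon case", {
  # ATGAAA vs ATGAGA: ATG has no synonymous neighbor; AAA has 1/3 syn site
  # (AAG), AGA has 2/3 (CGA, AGG); the single A->G difference is
  # nonsynonymous (Lys -> Arg)
  r <- ng86(list(codons_a = c("ATG", "AAA"), codons_b = c("ATG", "AGA")),
            n_boot = 0)
  expect_equal(r$S, 0.5)
  expect_equal(r$N, 5.5)
  expect_equal(r$Nd, 1)
  expect_equal(r$Sd, 0)
  expect_equal(r$pN, 1 / 5.5)
})

test_that("NG86 on an identical alignment gives zero rates and undefined ratio", {
  cods <- c("ATG", "AAA", "GGC", "TTT")
  r <- ng86(list(codons_a = cods, codons_b = cods), n_boot = 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
})

test_that("NG86 matches the brute-force oracle on random alignments", {
  set.seed(401)
  for (i in 1:25) {
    anc <- oracle_random_codons(40)
    cb <- oracle_mutate(anc, 0.08)
    r <- ng86(list(codons_a = anc, codons_b = cb), n_boot = 0)
    o <- oracle_ng86(anc, cb)
    expect_equal(r$N, o$N, tolerance = 1e-12)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    if (!is.na(o$Ka)) expect_equal(r$Ka, o$Ka, tolerance = 1e-12)
    if (!is.na(o$Ks)) expect_equal(r$Ks, o$Ks, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric in sequence order and conserves N + S", {
  set.seed(402)
  for (i in 1:10) {
    a <- oracle_random_codons(30)
    b <- oracle_mutate(a, 0.1)
    r1 <- ng86(list(codons_a = a, codons_b = b), n_boot = 0)
    r2 <- ng86(list(codons_a = b, codons_b = a), n_boot = 0)
    expect_equal(r1$Ka, r2$Ka)
    expect_equal(r1$Ks, r2$Ks)
    expect_equal(r1$N + r1$S, 3 * 30)
  }
})

test_that("adding only synonymous differences never increases Ka", {
  # GGT/GGC/GGA/GGG all encode Gly: swap third positions freely
  a <- rep("GGT", 50)
  b <- a
  r0 <- ng86(list(codons_a = a, codons_b = b), n_boot = 0)
  b[1:10] <- "GGC"
  r1 <- ng86(list(codons_a = a, codons_b = b), n_boot = 0)
  expect_equal(r1$Ka, r0$Ka)
  expect_gt(r1$Ks, r0$Ks)
})

test_that("gapped codon columns are dropped pairwise before counting", {
  r <- ng86(list(codons_a = c("ATG", "---", "AAA"),
                 codons_b = c("ATG", "GGG", "AGA")), n_boot = 0)
  expect_equal(r$n_codons, 2L)
  expect_equal(r$N + r$S, 6)
})

test_that("constraint bootstrap flags strongly constrained pairs", {
  set.seed(403)
  # synonymous differences only (in a quarter of columns, so pS stays
  # correctable), no nonsynonymous ones -> c = 1 - Ka/Ks = 1
  a <- rep(c("GGT", "CCT", "ACT"), 40)
  b <- a
  syn_swap <- c(GGT = "GGC", CCT = "CCC", ACT = "ACC")
  idx <- seq(1, 120, by = 4)
  b[idx] <- unname(syn_swap[a[idx]])
  r <- ng86(list(codons_a = a, codons_b = b), n_boot = 500)
  expect_equal(r$c_value, 1)
  expect_true(r$under_constraint)
  expect_true(r$c_low > 0)
})

test_that("batch_kaks computes both regions and flags positive selection", {
  set.seed(404)
  p1 <- evolve_codon_pair(80, omega = 0.2, target_ks = 0.4, seed = 4041)
  prot <- function(cds) paste(Biostrings::GENETIC_CODE[
    substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))],
    collapse = "")
  proteins <- c(g1 = prot(p1$cds_a), g2 = prot(p1$cds_b))
  cds <- c(g1 = p1$cds_a, g2 = p1$cds_b)
  pairs <- data.frame(gene_a = "g1", gene_b = "g2")
  hits <- data.frame(gene_id = c("g1", "g2"), start = c(10L, 10L),
                     end = c(40L, 40L), score = c(5, 5))
  full <- batch_kaks(pairs, proteins, cds, region = "full_length")
  mot <- batch_kaks(pairs, proteins, cds, region = "motif_only",
                    motif_hits = hits)
  expect_equal(nrow(full), 1L)
  expect_equal(nrow(mot), 1L)
  expect_equal(mot$n_codons, 30L)
  expect_false(full$positive_selection)
  # missing hit -> pair skipped with a warning
  expect_warning(
    empty <- batch_kaks(pairs, proteins, cds, region = "motif_only",
                        motif_hits = hits[1, , drop = FALSE]),
    "skipped")
  expect_equal(nrow(empty), 0L)
})
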