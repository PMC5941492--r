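# Expansion-mechanism classification.

toy_genes <- function(starts, widths = 1000, chromosome = "chr1",
                      ids = NULL) {
  n <- length(starts)
  data.frame(
    gene_id = if (is.null(ids)) sprintf("g%03d", seq_len(n)) else ids,
    chromosome = chromosome, strand = "+",
    start = as.integer(starts),
    end = as.integer(starts + widths),
    intron_count = 2L, stringsAsFactors = FALSE)
}

test_that("tandem rule: close ranks and span within the class threshold", {
  # 10 genes spaced 10 kb apart; family at ranks 5 and 7 -> span ~60 kb
  genes <- rank_genes(toy_genes(seq(0, 9) * 10000, widths = 500))
  fam <- genes[genes$array_rank %in% c(5, 7), ]
  calls <- detect_tandem_clusters(fam, genes, species_class = "compact")
  expect_equal(sort(calls$gene_id), sort(fam$gene_id))
  expect_equal(length(unique(calls$cluster_id)), 1L)
})

test_that("tandem rule: adjacent ranks but span beyond 100 kb fail for compact", {
  genes <- rank_genes(toy_genes(c(0, 120000), widths = 500))
  fam <- genes
  compact <- detect_tandem_clusters(fam, genes, species_class = "compact")
  expect_equal(nrow(compact), 0L)
  # the same span passes under the large-genome 350 kb threshold
  large <- detect_tandem_clusters(fam, genes, species_class = "large")
  expect_equal(nrow(large), 2L)
})

test_that("tandem rule: more than 10 intervening array genes fail", {
  genes <- rank_genes(toy_genes(seq(0, 14) * 1000, widths = 500))
  fam <- genes[genes$array_rank %in% c(1, 13), ]
  calls <- detect_tandem_clusters(fam, genes, species_class = "compact")
  expect_equal(nrow(calls), 0L)
})

test_that("tandem clustering equals the brute-force union-find oracle", {
  set.seed(601)
  for (rep in 1:20) {
    n <- 120
    genes <- toy_genes(sort(sample.int(2e6, n)), widths = 800,
                       chromosome = sample(c("chr1", "chr2"), n, TRUE))
    genes$gene_id <- sprintf("g%03d", seq_len(n))
    genes <- rank_genes(genes)
    fam <- genes[sort(sample.int(n, 25)), ]
    cls <- if (rep %% 2 == 0) "compact" else "large"
    span <- if (cls == "compact") 100000 else 350000
    calls <- detect_tandem_clusters(fam, genes, species_class = cls)
    got <- unname(lapply(split(calls$gene_id, calls$cluster_id), sort))
    want <- oracle_tandem(fam, 10, span)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("tandem calls are invariant to input row order (ranks recomputed)", {
  set.seed(602)
  genes <- toy_genes(sort(sample.int(5e5, 60)), widths = 700)
  genes$gene_id <- sprintf("g%03d", 1:60)
  fam_ids <- genes$gene_id[c(5, 6, 7, 30, 50)]
  shuffled <- genes[sample.int(60), ]
  a <- detect_tandem_clusters(genes[genes$gene_id %in% fam_ids, ],
                              rank_genes(genes), "compact")
  b <- detect_tandem_clusters(shuffled[shuffled$gene_id %in% fam_ids, ],
                              rank_genes(shuffled), "compact")
  expect_equal(sort(a$gene_id), sort(b$gene_id))
})

test_that("segmental calls need min_anchors flanking homolog pairs within 50 kb", {
  # family pair on chr1/chr2, three anchor pairs just beside each
  g <- rbind(
    toy_genes(c(0, 2000, 4000, 6000), chromosome = "chr1",
              ids = c("a1", "a2", "f1", "a3")),
    toy_genes(c(0, 2000, 4000, 6000), chromosome = "chr2",
              ids = c("b1", "b2", "f2", "b3")))
  fam <- g[g$gene_id %in% c("f1", "f2"), ]
  anchors <- data.frame(gene_a = c("a1", "a2", "a3"),
                        gene_b = c("b1", "b2", "b3"))
  calls <- detect_segmental(fam, g, anchors)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_anchors, 3L)

  # move the anchors to 60 kb away: no call at the default 50 kb flank
  far <- g
  far$start[far$gene_id %in% c("a1", "a2", "a3")] <-
    far$start[far$gene_id %in% c("a1", "a2", "a3")] + 64000L
  far$end[far$gene_id %in% c("a1", "a2", "a3")] <-
    far$end[far$gene_id %in% c("a1", "a2", "a3")] + 64000L
  expect_equal(nrow(detect_segmental(fam, far, anchors)), 0L)

  # min_anchors = 0: every family pair is called (degenerate control)
  degen <- detect_segmental(fam, g, anchors, min_anchors = 0)
  expect_equal(nrow(degen), 1L)
})

test_that("anchors with missing coordinates are skipped with a warning", {
  g <- rbind(toy_genes(c(0, 2000), chromosome = "chr1", ids = c("a1", "f1")),
             toy_genes(c(0, 2000), chromosome = "chr2", ids = c("b1", "f2")))
  fam <- g[g$gene_id %in% c("f1", "f2"), ]
  anchors <- data.frame(gene_a = c("a1", "missing"), gene_b = c("b1", "b9"))
  expect_warning(calls <- detect_segmental(fam, g, anchors, min_anchors = 1),
                 "missing")
  expect_equal(calls$n_anchors, 1L)
})

test_that("element attribution uses any >= 1 bp overlap, largest overlap wins", {
  fam <- toy_genes(c(1000, 5000, 9000), ids = c("g1", "g2", "g3"))
  elements <- data.frame(
    chromosome = "chr1",
    start = c(500L, 1500L, 8000L),
    end = c(2500L, 1900L, 9001L),
    family = c("MULE", "LTR", "hAT"),
    element_id = c("e1", "e2", "e3"), stringsAsFactors = FALSE)
  calls <- attribute_mobile_elements(fam, elements)
  # g1 overlaps e1 (1500 bp) and e2 (400 bp): MULE wins
  expect_equal(calls$mechanism[calls$gene_id == "g1"], "MULE")
  # g3 overlaps e3 by exactly 1 bp (gene start 9000 0-based = base 9000)
  expect_true("g3" %in% calls$gene_id)
  expect_equal(calls$overlap_bp[calls$gene_id == "g3"], 1L)
  # g2 overlaps nothing
  expect_false("g2" %in% calls$gene_id)
})

test_that("unknown element labels are rejected", {
  fam <- toy_genes(1000, ids = "g1")
  bad <- data.frame(chromosome = "chr1", start = 0L, end = 5000L,
                    family = "SINE", element_id = "e1")
  expect_error(attribute_mobile_elements(fam, bad), "unknown element")
})

test_that("retrogene rule: intron-poor copy of a multi-intron parent at high identity", {
  set.seed(603)
  prot <- paste(sample(AA20_test(), 120, TRUE), collapse = "")
  other <- paste(sample(AA20_test(), 120, TRUE), collapse = "")
  fam <- data.frame(
    gene_id = c("copy", "parent", "far", "multi"),
    chromosome = "chr1", strand = "+",
    start = c(0L, 10000L, 20000L, 30000L),
    end = c(400L, 10400L, 20400L, 30400L),
    intron_count = c(0L, 4L, 1L, 3L),
    protein = c(prot, prot, other, other), stringsAsFactors = FALSE)
  calls <- detect_retrogenes(fam)
  expect_equal(calls$gene_id, c("copy", "far"))
  expect_equal(calls$evidence[calls$gene_id == "copy"], "parent")
  # low identity fails the default 0.70 threshold
  strict <- detect_retrogenes(fam, identity_threshold = 1.01)
  expect_equal(nrow(strict), 0L)
  # multi-intron genes are never called
  expect_false("multi" %in% calls$gene_id)
  expect_false("parent" %in% calls$gene_id)
})

test_that("mechanism summary reports counts as percentages of family size", {
  seg <- data.frame(gene_a = sprintf("s%d", 1:10),
                    gene_b = sprintf("t%d", 1:10), mechanism = "segmental")
  out <- summarize_mechanisms(segmental = seg, family_size = 40)
  expect_equal(out$percent[out$mechanism == "segmental"], 50)
  empty <- summarize_mechanisms(family_size = 0)
  expect_true(all(empty$percent == 0))
})

test_that("planted mechanisms are recovered exactly from synthetic genomes", {
  cfg <- sim_config(seed = 3)
  g <- simulate_genome(cfg)
  genes <- rank_genes(g$genes)
  fam_ids <- g$ground_truth$motif_genes$gene_id
  fam <- genes[genes$gene_id %in% fam_ids, ]
  truth <- g$ground_truth

  tand <- detect_tandem_clusters(fam, genes,
                                 species_class = truth$species_class)
  got <- lapply(split(tand$gene_id, tand$cluster_id), sort)
  want <- lapply(truth$tandem_members, sort)
  expect_setequal(unname(vapply(got, paste, character(1), collapse = ",")),
                  unname(vapply(want, paste, character(1), collapse = ",")))

  seg <- detect_segmental(fam, genes, g$homolog_pairs)
  expect_setequal(pair_key(seg$gene_a, seg$gene_b),
                  pair_key(truth$segmental_pairs$gene_a,
                           truth$segmental_pairs$gene_b))

  el <- attribute_mobile_elements(fam, g$elements)
  expect_setequal(paste(el$gene_id, el$mechanism),
                  paste(truth$element_genes$gene_id,
                        truth$element_genes$family))

  rt <- detect_retrogenes(fam)
  expect_setequal(paste(rt$gene_id, rt$evidence),
                  paste(truth$retrogenes$gene_id, truth$retrogenes$parent))
})
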