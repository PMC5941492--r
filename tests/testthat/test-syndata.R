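# Synthetic-data generator: determinism, planted-feature consistency,
# codon-pair evolution.

test_that("config validation enforces counts and omega positivity", {
  expect_error(sim_config(n_chromosomes = 0), "n_chromosomes")
  expect_error(sim_config(omega_values = c(0.5, -1)), "omega_values")
  expect_error(sim_config(n_tissues = 1), "n_tissues")
  expect_s3_class(sim_config(n_tandem_arrays = 0), "sim_config")
})

test_that("genome simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  write_genome_files(simulate_genome(cfg), d1)
  write_genome_files(simulate_genome(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("no planted arrays means empty tandem ground truth", {
  cfg <- sim_config(seed = 2, n_tandem_arrays = 0)
  g <- simulate_genome(cfg)
  expect_length(g$ground_truth$tandem_members, 0L)
})

test_that("ground truth is consistent with the emitted files", {
  cfg <- sim_config(seed = 4)
  dir <- file.path(tempdir(), "sim_rt")
  write_genome_files(simulate_genome(cfg), dir)
  bundle <- read_genome_files(dir)
  expect_true(check_ground_truth(bundle))
  # round trip preserves coordinates and intron structure
  orig <- simulate_genome(cfg)$genes
  back <- bundle$genes[match(orig$gene_id, bundle$genes$gene_id), ]
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$intron_count, orig$intron_count)
  expect_equal(back$protein, orig$protein)
  unlink(dir, recursive = TRUE)
})

test_that("impossible layouts raise a configuration error", {
  cfg <- sim_config(seed = 1, genes_per_chromosome = 10, n_chromosomes = 1,
                    n_tandem_arrays = 5, tandem_array_size = 3)
  expect_error(simulate_genome(cfg), "impossible layout")
})

test_that("codon-pair evolution respects omega limits and determinism", {
  # omega = 0: no nonsynonymous change, proteins identical
  p0 <- evolve_codon_pair(150, omega = 0, target_ks = 0.3, seed = 12)
  expect_equal(p0$n_nonsyn, 0L)
  prot <- function(cds) paste(Biostrings::GENETIC_CODE[
    substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))],
    collapse = "")
  expect_identical(prot(p0$cds_a), prot(p0$cds_b))

  # target_ks = 0: descendants equal the ancestor
  pid <- evolve_codon_pair(60, omega = 1, target_ks = 0, seed = 13)
  expect_identical(pid$cds_a, pid$ancestor)
  expect_identical(pid$cds_b, pid$ancestor)

  # determinism
  pa <- evolve_codon_pair(80, omega = 0.5, target_ks = 0.2, seed = 14)
  pb <- evolve_codon_pair(80, omega = 0.5, target_ks = 0.2, seed = 14)
  expect_identical(pa, pb)
})

test_that("evolved sequences never contain internal stop codons", {
  for (i in 1:5) {
    p <- evolve_codon_pair(100, omega = 2, target_ks = 0.5, seed = 20 + i)
    for (cds in c(p$cds_a, p$cds_b)) {
      aas <- Biostrings::GENETIC_CODE[
        substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))]
      expect_false(any(aas == "*"))
    }
  }
})

test_that("neutral evolution realizes a ratio near 1 (law of large numbers)", {
  p <- evolve_codon_pair(10000, omega = 1, target_ks = 0.3, seed = 99)
  expect_lt(abs(p$realized_ratio - 1), 0.1)
})

test_that("conversion-alignment tracts make the planted pair identical in the tract", {
  sim <- simulate_conversion_alignment(
    5, 100, 0.12, seed = 8, tract = list(pair = c(2, 4), start = 90,
                                         length = 90))
  tr <- sim$truth
  a <- substring(sim$alignment[[tr$pair[1]]], tr$start + 1, tr$end)
  b <- substring(sim$alignment[[tr$pair[2]]], tr$start + 1, tr$end)
  expect_identical(a, b)
  # sequences stay stop-free coding
  for (s in sim$alignment) {
    aas <- Biostrings::GENETIC_CODE[
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))]
    expect_false(any(aas == "*"))
  }
})

test_that("expression generator plants detectable signals", {
  cfg <- sim_config(seed = 6, noise_sd = 0)
  ex <- simulate_expression(cfg)
  atlas <- ex$datasets$tissues
  truth <- ex$truth$preferred_genes
  # noiseless planted genes pass the 2x rule in their recorded tissue
  for (k in seq_len(nrow(truth))) {
    g <- truth$gene[k]
    m <- atlas$mat[g, ]
    by_t <- tapply(m, atlas$sample_map$group[
      match(names(m), atlas$sample_map$sample)], mean)
    focal <- by_t[truth$tissue[k]]
    expect_gte(focal, 2 * max(by_t[names(by_t) != truth$tissue[k]]))
  }
  # shared latent with vanishing noise gives |r| near 1
  co <- ex$datasets$coexpr1$mat
  pairs <- ex$truth$coexpressed_pairs
  r <- cor(log2(co[pairs$gene_a[1], ] + 1), log2(co[pairs$gene_b[1], ] + 1))
  expect_gt(abs(r), 0.99)
  expect_equal(sign(r), pairs$sign[1])
})
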