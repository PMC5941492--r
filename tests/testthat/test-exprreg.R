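# Tissue preference, treatment regulation, co-expression calling.

atlas_fixture <- function(means, tissues = paste0("T", seq_along(means))) {
  mat <- matrix(means, nrow = 1, dimnames = list("g1", tissues))
  list(mat = mat,
       map = data.frame(sample = tissues, group = tissues,
                        stringsAsFactors = FALSE))
}

test_that("vegetative-preferred call follows the forced 2x arithmetic", {
  # T1-T4 means (10, 12, 8, 10), T5-T11 all <= 4: mean(focal) = 10 >= 2 * 4
  fx <- atlas_fixture(c(10, 12, 8, 10, 4, 3, 2, 4, 1, 2, 3))
  out <- classify_tissue(fx$mat, fx$map, focal = paste0("T", 1:4))
  expect_equal(out$call, "preferred")
  expect_equal(out$fold, 10 / 4)
})

test_that("an all-zero gene is undetected and uncalled", {
  fx <- atlas_fixture(rep(0, 5))
  out <- classify_tissue(fx$mat, fx$map)
  expect_false(out$detected)
  expect_equal(out$call, "none")
})

test_that("specific means detected only in the focal tissues", {
  fx <- atlas_fixture(c(8, 6, 0.2, 0.1, 0.3))
  out <- classify_tissue(fx$mat, fx$map, focal = c("T1", "T2"))
  expect_equal(out$call, "specific")
  broader <- atlas_fixture(c(8, 6, 2, 0.1, 0.3))
  out2 <- classify_tissue(broader$mat, broader$map, focal = c("T1", "T2"))
  expect_equal(out2$call, "preferred")
})

test_that("the preference fold boundary is inclusive at exactly 2", {
  exact <- atlas_fixture(c(8, 4, 3, 2))
  out <- classify_tissue(exact$mat, exact$map, focal = "T1")
  expect_equal(out$fold, 2)
  expect_equal(out$call, "preferred")
  below <- atlas_fixture(c(7.999, 4, 3, 2))
  expect_equal(classify_tissue(below$mat, below$map, focal = "T1")$call,
               "none")
})

test_that("tissue calls are invariant to sample column order", {
  set.seed(901)
  mat <- matrix(runif(3 * 6, 0, 10), 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  map <- data.frame(sample = paste0("s", 1:6),
                    group = rep(c("T1", "T2", "T3"), each = 2))
  a <- classify_tissue(mat, map)
  b <- classify_tissue(mat[, sample(6)], map)
  expect_equal(a, b)
})

test_that("treatment regulation applies the inclusive 2x rule both ways", {
  mat <- matrix(c(5, 12,   # up: 12 >= 2*5 is false -> none? 12 < 10? no: up
                  5, 9,    # none: 9 < 10
                  8, 4,    # down: 8 >= 2*4
                  0.2, 0.4), # undetected
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), c("c1", "t1")))
  out <- classify_treatment(mat, control = "c1", treated = "t1")
  expect_equal(out$call, c("up", "none", "down", "none"))
  expect_false(out$detected[4])
  exact <- matrix(c(5, 10), 1, dimnames = list("g", c("c1", "t1")))
  expect_equal(classify_treatment(exact, control = "c1",
                                  treated = "t1")$call, "up")
})

test_that("co-expression threshold is inclusive at |r| = 0.8 with sign consistency", {
  # construct matrices with exact correlations via shared/independent parts
  base <- c(1, 2, 3, 4, 5, 6, 7, 8)
  make <- function(r) {
    # two genes with empirical Pearson correlation exactly r: mix the
    # standardized profile with its orthogonalized complement
    x <- scale(base)[, 1]
    z <- stats::resid(stats::lm(c(5, 2, 7, 1, 8, 3, 6, 4) ~ x))
    z <- z / stats::sd(z)
    rbind(gA = x, gB = r * x + sqrt(1 - r^2) * z)
  }
  mats <- list(make(0.80), make(0.85), make(0.9), make(0.1))
  out <- coexpression_pairs(mats, min_datasets = 3, log_transform = FALSE,
                            all_pairs = TRUE)
  expect_equal(out$n_supporting, 3)
  expect_equal(out$sign, "+")
  expect_true(out$called)
  # just below threshold in one dataset drops support to 2
  mats2 <- list(make(0.7999), make(0.85), make(0.9), make(0.1))
  out2 <- coexpression_pairs(mats2, min_datasets = 3, log_transform = FALSE,
                             all_pairs = TRUE)
  expect_equal(out2$n_supporting, 2)
  expect_false(out2$called)
  # mixed signs are not called under the default, called when disabled
  mats3 <- list(make(0.85), make(-0.9), make(0.82), make(0.83))
  out3 <- coexpression_pairs(mats3, min_datasets = 3, log_transform = FALSE,
                             all_pairs = TRUE)
  expect_equal(out3$sign, "mixed")
  expect_false(out3$called)
  out4 <- coexpression_pairs(mats3, min_datasets = 3, log_transform = FALSE,
                             require_sign_consistency = FALSE,
                             all_pairs = TRUE)
  expect_true(out4$called)
})

test_that("co-expression is symmetric and skips constant genes", {
  set.seed(902)
  mats <- lapply(1:3, function(i) {
    m <- matrix(rnorm(4 * 10), 4, dimnames = list(paste0("g", 1:4), NULL))
    m["g4", ] <- 1  # constant
    m
  })
  out <- coexpression_pairs(mats, min_datasets = 3, log_transform = FALSE,
                            all_pairs = TRUE)
  expect_equal(out$gene_a, pmin(out$gene_a, out$gene_b))
  g4 <- out[out$gene_a == "g4" | out$gene_b == "g4", ]
  expect_true(all(g4$n_supporting == 0))
})

test_that("planted expression signals are recovered with the documented rules", {
  cfg <- sim_config(seed = 7)
  ex <- simulate_expression(cfg)
  atlas <- ex$datasets$tissues
  tis <- classify_tissue(atlas$mat, atlas$sample_map)
  truth <- ex$truth$preferred_genes
  called <- tis$gene[tis$call %in% c("preferred", "specific")]
  expect_gte(mean(truth$gene %in% called), 0.9)
  expect_gte(mean(called %in% truth$gene), 0.9)
  # calls name the planted tissue
  sub <- tis[match(truth$gene, tis$gene), ]
  expect_true(all(sub$focal == truth$tissue))

  reg_truth <- ex$truth$regulated_genes
  for (tr in unique(reg_truth$treatment)) {
    d <- ex$datasets[[tr]]
    out <- classify_treatment(d$mat, d$sample_map)
    want <- reg_truth[reg_truth$treatment == tr, ]
    got <- out[match(want$gene, out$gene), ]
    expect_equal(got$call, want$direction)
    expect_gte(mean(out$gene[out$call != "none"] %in% want$gene), 0.9)
  }

  co <- coexpression_pairs(ex$datasets[grep("^coexpr",
                                            names(ex$datasets))])
  tp <- ex$truth$coexpressed_pairs
  expect_gte(mean(pair_key(tp$gene_a, tp$gene_b) %in%
                    pair_key(co$gene_a, co$gene_b)), 0.9)
  expect_gte(mean(pair_key(co$gene_a, co$gene_b) %in%
                    pair_key(tp$gene_a, tp$gene_b)), 0.9)
  # recovered signs agree with the planted ones
  m <- match(pair_key(co$gene_a, co$gene_b), pair_key(tp$gene_a, tp$gene_b))
  ok <- !is.na(m)
  expect_true(all(co$sign[ok] == ifelse(tp$sign[m[ok]] > 0, "+", "-")))
  mods <- coexpression_modules(co)
  expect_true(all(c(co$gene_a, co$gene_b) %in% mods$gene))
})
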