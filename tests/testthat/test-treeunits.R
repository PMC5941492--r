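# Ancestral-unit counting on species-labeled gene trees.

ab_species <- function(tree) {
  tips <- tree$tip.label
  stats::setNames(substr(tips, 1, 1), tips)
}

test_that("hand-enumerated toy trees give the expected unit counts", {
  # ((A1,(B1,A2)),(B2,A3)): minimal mixed clades are (B1,A2) and (B2,A3)
  tr <- ape::read.tree(text = "((A1,(B1,A2)),(B2,A3));")
  u <- count_ancestral_units(tr, ab_species(tr),
                             list(a = "A", b = "B"))
  expect_equal(u$n_units, 2L)
  clades <- lapply(u$member_clades, sort)
  expect_setequal(vapply(clades, paste, character(1), collapse = ","),
                  c("A2,B1", "A3,B2"))

  tr2 <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  expect_equal(count_ancestral_units(tr2, ab_species(tr2),
                                     list(a = "A", b = "B"))$n_units, 2L)

  # single mixed cherry deep in an otherwise pure tree
  tr3 <- ape::read.tree(text = "(((A1,A2),A3),(A4,B1));")
  expect_equal(count_ancestral_units(tr3, ab_species(tr3),
                                     list(a = "A", b = "B"))$n_units, 1L)
})

test_that("a lineage-pure tree yields zero units with a warning", {
  tr <- ape::read.tree(text = "((A1,A2),(A3,A4));")
  expect_warning(u <- count_ancestral_units(tr, ab_species(tr),
                                            list(a = "A", b = "B")),
                 "no leaves")
  expect_equal(u$n_units, 0L)
})

test_that("unmapped leaves and unrooted trees are rejected", {
  tr <- ape::read.tree(text = "((A1,B1),(A2,B2));")
  expect_error(count_ancestral_units(tr, c(A1 = "A", B1 = "B", A2 = "A"),
                                     list(a = "A", b = "B")),
               "without a species")
  unrooted <- ape::read.tree(text = "(A1,B1,(A2,B2));")
  expect_false(ape::is.rooted(unrooted))
  expect_error(count_ancestral_units(unrooted, ab_species(unrooted),
                                     list(a = "A", b = "B")), "unrooted")
  rooted <- root_gene_tree(unrooted, "A1")
  expect_true(ape::is.rooted(rooted))
})

test_that("counts are invariant under leaf rotation of the Newick string", {
  tr <- ape::read.tree(text = "((A1,(B1,A2)),(B2,A3));")
  rot <- ape::read.tree(text = "((A3,B2),((A2,B1),A1));")
  sp <- ab_species(tr)
  split <- list(a = "A", b = "B")
  expect_equal(count_ancestral_units(tr, sp, split)$n_units,
               count_ancestral_units(rot, sp, split)$n_units)
})

test_that("multifurcating mixed nodes can be minimal units", {
  tr <- ape::read.tree(text = "((A1,A2,B1),(B2,B3));")
  u <- count_ancestral_units(tr, ab_species(tr), list(a = "A", b = "B"))
  expect_equal(u$n_units, 1L)
})

test_that("unit counts are bounded by the smaller lineage leaf count", {
  set.seed(801)
  for (i in 1:15) {
    sim <- simulate_duplication_tree(
      n_at_splits = sample(1:6, 1),
      lineage_species = list("X", "Y"), seed = 900 + i)
    u <- count_ancestral_units(sim$tree, sim$leaf_species, sim$splits[[1]])
    sp <- sim$leaf_species
    expect_lte(u$n_units, min(sum(sp == "X"), sum(sp == "Y")))
  }
})

test_that("recorded duplication histories are recovered exactly along a backbone", {
  for (i in 1:10) {
    n1 <- sample(1:5, 1)
    n2 <- n1 + sample(0:5, 1)
    sim <- simulate_duplication_tree(
      n_at_splits = c(n1, n2),
      lineage_species = list("moss", "gym", c("dic", "mon")),
      seed = 1700 + i)
    ub <- units_along_backbone(sim$tree, sim$leaf_species, sim$splits)
    expect_equal(ub$n_units, c(n1, n2))
    # duplication-only histories: deeper counts never exceed shallower
    expect_true(all(diff(ub$n_units) >= 0))
  }
})

test_that("single-gene families give one unit at every split", {
  sim <- simulate_duplication_tree(
    n_at_splits = c(1, 1),
    lineage_species = list("moss", "gym", c("dic", "mon")),
    seed = 77, mean_extra_leaves = 0)
  ub <- units_along_backbone(sim$tree, sim$leaf_species, sim$splits)
  expect_equal(ub$n_units, c(1L, 1L))
})

test_that("inconsistent split nesting is rejected", {
  tr <- ape::read.tree(text = "((A1,B1),(C1,C2));")
  sp <- c(A1 = "A", B1 = "B", C1 = "C", C2 = "C")
  expect_error(units_along_backbone(
    tr, sp, list(list(a = "A", b = c("B", "C")),
                 list(a = "A", b = "B"))), "not nested")
})
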