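# Ancestral units: minimal mixed clades of a species-labeled rooted gene
# tree at a lineage split. Each minimal mixed clade implies one gene in the
# most recent common ancestor of the two lineages, so the count is a
# parsimony lower bound on the MRCA gene content (gene losses are not
# reconciled and lineage-pure clades outside mixed clades are not counted).

#' Count ancestral units at a lineage split
#'
#' A node of the rooted gene tree is a *minimal mixed clade* for a split
#' when its subtree contains at least one leaf from each side of the split
#' and no single child subtree does. The number of such nodes is the
#' ancestral-unit count: the minimum number of genes the common ancestor of
#' the two lineages must have carried.
#'
#' @param tree A rooted `phylo` tree (or a Newick string / file path).
#'   Multifurcating nodes are accepted and may themselves be minimal mixed.
#' @param leaf_species Named character vector mapping every leaf label to
#'   its species.
#' @param split List with elements `a` and `b`: character vectors of species
#'   on each side of the lineage split. Leaves from species on neither side
#'   are ignored.
#' @return A list with class `"unit_count"`: `n_units`, `member_clades`
#'   (list of leaf-label sets, pairwise disjoint), `split`.
#' @export
count_ancestral_units <- function(tree, leaf_species, split) {
  tree <- as_rooted_phylo(tree)
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(leaf_species))
  if (length(unmapped) > 0L)
    stop("leaves without a species mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  side <- rep(0L, length(tips)) # 1 = side a, 2 = side b, 0 = ignored
  side[leaf_species[tips] %in% split$a] <- 1L
  side[leaf_species[tips] %in% split$b] <- 2L
  if (!any(side == 1L) || !any(side == 2L)) {
    warning("one side of the split has no leaves; 0 units", call. = FALSE)
    return(structure(list(n_units = 0L, member_clades = list(),
                          split = split), class = "unit_count"))
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  # per-node counts of side-a and side-b leaves, computed tips-first
  cnt_a <- c(as.integer(side == 1L), integer(nnode))
  cnt_b <- c(as.integer(side == 2L), integer(nnode))
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]
    child <- edges[k, 2]
    cnt_a[par] <- cnt_a[par] + cnt_a[child]
    cnt_b[par] <- cnt_b[par] + cnt_b[child]
  }
  mixed <- cnt_a > 0L & cnt_b > 0L
  units <- integer(0)
  for (v in (ntip + 1L):(ntip + nnode)) {
    if (!mixed[v]) next
    children <- edges[edges[, 1] == v, 2]
    if (!any(mixed[children])) units <- c(units, v)
  }
  clades <- lapply(units, function(v) {
    tips[intersect(subtree_tips(edges, ntip, v), seq_len(ntip))]
  })
  structure(list(n_units = length(units), member_clades = clades,
                 split = split), class = "unit_count")
}

subtree_tips <- function(edges, ntip, node) {
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= ntip) {
      out <- c(out, v)
    } else {
      stack <- c(stack, edges[edges[, 1] == v, 2])
    }
  }
  out
}

#' @export
print.unit_count <- function(x, ...) {
  cat(sprintf("%d ancestral unit(s) at split {%s} | {%s}\n", x$n_units,
              paste(x$split$a, collapse = ","),
              paste(x$split$b, collapse = ",")))
  for (cl in x$member_clades)
    cat("  -", paste(cl, collapse = ", "), "\n")
  invisible(x)
}

#' Ancestral units along a backbone of nested splits
#'
#' Applies [count_ancestral_units()] to an ordered series of lineage splits
#' (deepest first). Each successive split must be nested inside one side of
#' the previous one (its species union contained in that side), as along a
#' species-phylogeny backbone.
#'
#' @inheritParams count_ancestral_units
#' @param ordered_splits List of splits (each a list with `a`, `b`),
#'   deepest first.
#' @return Data frame with one row per split: `split`, `n_units`, plus the
#'   full `"unit_count"` objects as the `units` attribute.
#' @export
units_along_backbone <- function(tree, leaf_species, ordered_splits) {
  if (length(ordered_splits) > 1L) {
    for (k in seq_len(length(ordered_splits) - 1L)) {
      prev <- ordered_splits[[k]]
      cur <- unique(c(ordered_splits[[k + 1L]]$a, ordered_splits[[k + 1L]]$b))
      if (!(all(cur %in% prev$a) || all(cur %in% prev$b)))
        stop(sprintf("split %d is not nested inside a side of split %d",
                     k + 1L, k), call. = FALSE)
    }
  }
  counts <- lapply(ordered_splits, function(sp)
    count_ancestral_units(tree, leaf_species, sp))
  out <- data.frame(
    split = vapply(ordered_splits, function(sp)
      paste0("{", paste(sp$a, collapse = ","), "}|{",
             paste(sp$b, collapse = ","), "}"), character(1)),
    n_units = vapply(counts, `[[`, integer(1), "n_units"),
    stringsAsFactors = FALSE)
  attr(out, "units") <- counts
  out
}

#' Root a gene tree on an outgroup
#'
#' Thin wrapper over [ape::root()] with `resolve.root = TRUE`. Unrooted
#' trees are rejected by the unit-counting functions because the rooting
#' changes the counts; this utility makes the rooting step explicit.
#'
#' @param tree `phylo`, Newick string or file path.
#' @param outgroup Leaf label(s) to root on.
#' @return A rooted `phylo`.
#' @export
root_gene_tree <- function(tree, outgroup) {
  tree <- as_phylo(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("cannot interpret tree input", call. = FALSE)
}

as_rooted_phylo <- function(tree) {
  tree <- as_phylo(tree)
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it explicitly (see root_gene_tree)",
         call. = FALSE)
  tree
}
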