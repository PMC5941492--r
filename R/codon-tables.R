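# Codon machinery shared by the NG86 estimator and the codon-pair simulator.
#
# All tables use the standard nuclear genetic code. Mutations that create a
# stop codon count as nonsynonymous when sites are classified; mutational
# pathways that pass through a stop are excluded when differences are counted
# (with a fall-back to all pathways in the rare case every pathway is blocked).

NUCS <- c("A", "C", "G", "T")

.codon_env <- new.env(parent = emptyenv())

#' All 64 codons in fixed lexicographic order
#' @noRd
all_codons <- function() {
  if (is.null(.codon_env$codons)) {
    g <- expand.grid(n3 = NUCS, n2 = NUCS, n1 = NUCS, stringsAsFactors = FALSE)
    .codon_env$codons <- paste0(g$n1, g$n2, g$n3)
  }
  .codon_env$codons
}

#' Translate one codon to its amino acid (stop = "*")
#' @noRd
codon_aa <- function(codon) {
  tab <- codon_table()
  unname(tab[codon])
}

codon_table <- function() {
  if (is.null(.codon_env$aa)) {
    codons <- all_codons()
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(codons),
      no.init.codon = TRUE
    ))
    names(aa) <- codons
    .codon_env$aa <- aa
  }
  .codon_env$aa
}

is_stop_codon <- function(codon) codon_table()[codon] == "*"

#' Single-nucleotide neighbors of a codon (9 per codon)
#' @noRd
codon_neighbors <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- character(9)
  k <- 0L
  for (pos in 1:3) {
    for (n in NUCS[NUCS != s[pos]]) {
      k <- k + 1L
      t <- s
      t[pos] <- n
      out[k] <- paste(t, collapse = "")
    }
  }
  out
}

#' Per-codon synonymous site count (NG86)
#'
#' For each position, the fraction of the three possible single-nucleotide
#' changes that are synonymous; changes to stop codons are nonsynonymous.
#' Stop codons themselves get NA (they never occur in valid CDS input).
#' @noRd
syn_sites_table <- function() {
  if (is.null(.codon_env$syn_sites)) {
    codons <- all_codons()
    aa <- codon_table()
    s <- vapply(codons, function(cd) {
      if (aa[cd] == "*") return(NA_real_)
      cs <- strsplit(cd, "")[[1]]
      total <- 0
      for (pos in 1:3) {
        nsyn <- 0L
        for (n in NUCS[NUCS != cs[pos]]) {
          t <- cs
          t[pos] <- n
          mut <- paste(t, collapse = "")
          if (aa[mut] != "*" && aa[mut] == aa[cd]) nsyn <- nsyn + 1L
        }
        total <- total + nsyn / 3
      }
      total
    }, numeric(1))
    names(s) <- codons
    .codon_env$syn_sites <- s
  }
  .codon_env$syn_sites
}

#' Per-codon stop-neighbor site count
#'
#' For each codon, the fraction of single-nucleotide changes that create a
#' stop codon, expressed on the same per-site scale as syn_sites_table
#' (each position contributes #stop-neighbors / 3). These sites count as
#' nonsynonymous in NG86 but can never realize a substitution in viable
#' coding sequence.
#' @noRd
stop_sites_table <- function() {
  if (is.null(.codon_env$stop_sites)) {
    codons <- all_codons()
    aa <- codon_table()
    s <- vapply(codons, function(cd) {
      if (aa[cd] == "*") return(NA_real_)
      sum(aa[codon_neighbors(cd)] == "*") / 3
    }, numeric(1))
    names(s) <- codons
    .codon_env$stop_sites <- s
  }
  .codon_env$stop_sites
}

#' Pathway-averaged synonymous/nonsynonymous difference counts
#'
#' 64 x 64 matrices sd_mat / nd_mat giving, for each ordered codon pair, the
#' number of synonymous and nonsynonymous differences averaged over all
#' minimal mutational pathways that avoid stop codons (all pathways if every
#' one is blocked). Entries involving stop codons are NA.
#' @noRd
diff_tables <- function() {
  if (is.null(.codon_env$sd_mat)) {
    codons <- all_codons()
    aa <- codon_table()
    n <- length(codons)
    sd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
    nd_mat <- matrix(0, n, n, dimnames = list(codons, codons))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (aa[codons[i]] == "*" || aa[codons[j]] == "*") {
          sd_mat[i, j] <- NA_real_
          nd_mat[i, j] <- NA_real_
        } else if (i != j) {
          d <- codon_path_diffs(codons[i], codons[j], aa)
          sd_mat[i, j] <- d[["sd"]]
          nd_mat[i, j] <- d[["nd"]]
        }
      }
    }
    .codon_env$sd_mat <- sd_mat
    .codon_env$nd_mat <- nd_mat
  }
  list(sd = .codon_env$sd_mat, nd = .codon_env$nd_mat)
}

#' Average syn/nonsyn step counts over minimal pathways between two codons
#' @noRd
codon_path_diffs <- function(a, b, aa = codon_table()) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  pos <- which(sa != sb)
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- perms(pos)
  keep_sd <- numeric(0)
  keep_nd <- numeric(0)
  all_sd <- numeric(0)
  all_nd <- numeric(0)
  for (k in seq_len(nrow(paths))) {
    cur <- sa
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (p in paths[k, ]) {
      nxt <- cur
      nxt[p] <- sb[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (aa[to] == "*") blocked <- TRUE
      if (aa[from] == aa[to]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    all_sd <- c(all_sd, sd)
    all_nd <- c(all_nd, nd)
    if (!blocked) {
      keep_sd <- c(keep_sd, sd)
      keep_nd <- c(keep_nd, nd)
    }
  }
  if (length(keep_sd) > 0L) {
    c(sd = mean(keep_sd), nd = mean(keep_nd))
  } else {
    c(sd = mean(all_sd), nd = mean(all_nd))
  }
}

#' All permutations of a small vector (n <= 3 here)
#' @noRd
perms <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- perms(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  out
}

#' Split a CDS string into codons
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Random CDS with no internal stop codons
#' @noRd
random_cds <- function(n_codons) {
  codons <- all_codons()
  sense <- codons[codon_table() != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
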