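# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (string manipulation, explicit
# enumeration, brute force) and share no tables or code paths with the
# package internals.

ORACLE_CODE <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) ORACLE_CODE[[codon]]

oracle_neighbors <- function(codon) {
  nts <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in 1:3) {
    for (n in setdiff(nts, substr(codon, i, i))) {
      x <- codon
      substr(x, i, i) <- n
      out <- c(out, x)
    }
  }
  out
}

# Synonymous site count of one codon (changes to stops are nonsynonymous).
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  nb <- oracle_neighbors(codon)
  sum(vapply(nb, function(x) {
    oracle_translate(x) != "*" && oracle_translate(x) == aa
  }, logical(1))) / 3
}

# All orderings of the differing positions between two codons.
oracle_orderings <- function(pos) {
  if (length(pos) <= 1L) return(list(pos))
  out <- list()
  for (i in seq_along(pos))
    for (rest in oracle_orderings(pos[-i]))
      out[[length(out) + 1L]] <- c(pos[i], rest)
  out
}

# Pathway-averaged syn/nonsyn differences between two codons, skipping
# pathways that visit a stop codon (all pathways if every one does).
oracle_codon_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  ok <- list()
  all <- list()
  for (ord in oracle_orderings(pos)) {
    cur <- a
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_translate(nxt) == "*") blocked <- TRUE
      if (oracle_translate(nxt) == oracle_translate(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    all[[length(all) + 1L]] <- c(sd, nd)
    if (!blocked) ok[[length(ok) + 1L]] <- c(sd, nd)
  }
  use <- if (length(ok)) ok else all
  m <- colMeans(do.call(rbind, use))
  c(sd = m[1], nd = m[2])
}

# Full NG86 recomputation for a gap-free codon alignment.
oracle_ng86 <- function(codons_a, codons_b) {
  Sa <- sum(vapply(codons_a, oracle_syn_sites, numeric(1)))
  Sb <- sum(vapply(codons_b, oracle_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(codons_a) - S
  d <- mapply(function(a, b) oracle_codon_diffs(a, b), codons_a, codons_b)
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       Ka = jc(pN), Ks = jc(pS))
}

# Random stop-free codon vector (independent generation path).
oracle_random_codons <- function(n) {
  all64 <- names(ORACLE_CODE)
  sense <- all64[ORACLE_CODE != "*"]
  sample(sense, n, replace = TRUE)
}

# Mutate a codon vector per-nucleotide at the given rate, suppressing stops.
oracle_mutate <- function(codons, rate) {
  nts <- c("A", "C", "G", "T")
  for (i in seq_along(codons)) {
    for (p in 1:3) {
      if (runif(1) < rate) {
        x <- codons[i]
        substr(x, p, p) <- sample(setdiff(nts, substr(x, p, p)), 1)
        if (oracle_translate(x) != "*") codons[i] <- x
      }
    }
  }
  codons
}

# Brute-force tandem clustering: all-pairs rule check + union-find.
oracle_tandem <- function(family, max_rank_diff, max_span) {
  n <- nrow(family)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same_chr <- family$chromosome[i] == family$chromosome[j]
      rank_ok <- abs(family$array_rank[i] - family$array_rank[j]) <=
        max_rank_diff
      span <- max(family$end[i], family$end[j]) -
        min(family$start[i], family$start[j])
      if (same_chr && rank_ok && span <= max_span) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(family$gene_id, roots)
  comp <- comp[vapply(comp, length, integer(1)) >= 2L]
  unname(lapply(comp, sort))
}

# Brute-force best window score over a protein for a motif profile.
oracle_best_window <- function(seq, profile) {
  L <- profile$length
  aa <- strsplit(seq, "")[[1]]
  if (length(aa) < L) return(NULL)
  best <- -Inf
  best_start <- NA
  for (s in 1:(length(aa) - L + 1)) {
    sc <- 0
    for (j in 1:L) {
      r <- aa[s + j - 1]
      sc <- sc + if (r %in% rownames(profile$scores))
        profile$scores[r, j] else 0
    }
    if (sc > best) {
      best <- sc
      best_start <- s
    }
  }
  list(score = unname(best), start = best_start)
}

# Brute-force maximum-scoring subarray (all O(n^2) spans).
oracle_max_subarray <- function(x) {
  best <- 0
  for (i in seq_along(x)) {
    for (j in i:length(x)) {
      s <- sum(x[i:j])
      if (s > best) best <- s
    }
  }
  best
}

# Textbook O(nm) local-alignment DP score with linear gaps.
oracle_local_dp <- function(a, b, match, mismatch, gap) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  H <- matrix(0, length(A) + 1, length(B) + 1)
  best <- 0
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      sub <- if (A[i] == B[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + sub, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Convenience: codon alignment from an evolved pair.
as_codon_alignment <- function(pair) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  list(codons_a = split3(pair$cds_a), codons_b = split3(pair$cds_b))
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

AA20_test <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}
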