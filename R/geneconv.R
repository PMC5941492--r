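# Gene-conversion detection: Sawyer-style maximal-fragment statistic over
# polymorphic sites, with significance from joint column permutation.
#
# Alignment columns are reported 0-based half-open, consistent with the
# package's internal coordinate policy.

#' Polymorphic sites of a multiple alignment
#'
#' Columns with at least two distinct non-gap characters; columns containing
#' any gap are excluded.
#'
#' @param alignment Character vector of >= 3 equal-length aligned sequences
#'   (named or not), or a character matrix (rows = sequences).
#' @return Integer vector of 0-based column indices.
#' @export
polymorphic_sites <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 3L)
    stop("need at least 3 sequences to detect conversion against the group",
         call. = FALSE)
  poly <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (any(col == "-")) next
    poly[j] <- length(unique(col)) >= 2L
  }
  which(poly) - 1L
}

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (inherits(alignment, "DNAStringSet") || inherits(alignment, "XStringSet"))
    alignment <- as.character(alignment)
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences have unequal lengths", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Best-scoring fragment of a sequence pair over polymorphic sites
#'
#' Over the pair's match/mismatch string at the polymorphic sites, finds the
#' maximal-scoring contiguous run (match +1, mismatch -`mismatch_penalty`).
#' The default infinite penalty makes fragments pure match runs.
#'
#' @param seq_a,seq_b Aligned sequences (equal length).
#' @param sites 0-based polymorphic column indices (from
#'   [polymorphic_sites()]).
#' @param mismatch_penalty Penalty per mismatching polymorphic site
#'   (default `Inf`: pure-match fragments).
#' @return List: `score`, `fragment_start`, `fragment_end` (0-based
#'   half-open alignment columns spanning the fragment; both 0 when no
#'   positive-scoring fragment exists), `n_polymorphic_in_fragment`.
#' @export
score_fragments <- function(seq_a, seq_b, sites, mismatch_penalty = Inf) {
  if (length(sites) == 0L)
    stop("no polymorphic sites supplied", call. = FALSE)
  a <- strsplit(seq_a, "")[[1]][sites + 1L]
  b <- strsplit(seq_b, "")[[1]][sites + 1L]
  match_vec <- a == b
  best <- kadane(ifelse(match_vec, 1,
                        if (is.finite(mismatch_penalty)) -mismatch_penalty
                        else -1e18))
  if (best$score <= 0) {
    return(list(score = 0, fragment_start = 0L, fragment_end = 0L,
                n_polymorphic_in_fragment = 0L))
  }
  list(score = best$score,
       fragment_start = sites[best$from],
       fragment_end = sites[best$to] + 1L,
       n_polymorphic_in_fragment = best$to - best$from + 1L)
}

# Maximum-scoring contiguous subarray with its span (ties: first found).
kadane <- function(x) {
  best <- 0
  best_from <- 0L
  best_to <- 0L
  cur <- 0
  cur_from <- 1L
  for (i in seq_along(x)) {
    if (cur <= 0) {
      cur <- x[i]
      cur_from <- i
    } else {
      cur <- cur + x[i]
    }
    if (cur > best) {
      best <- cur
      best_from <- cur_from
      best_to <- i
    }
  }
  list(score = best, from = best_from, to = best_to)
}

#' Permutation test for gene-conversion fragments
#'
#' For every sequence pair, the observed statistic is the best fragment
#' score over polymorphic sites ([score_fragments()]). The null permutes
#' polymorphic-site columns jointly across all sequences; the per-pair
#' `sim_pvalue` is `(1 + #null best-scores >= observed) / (1 + n)`, and
#' `global_pvalue` is the Bonferroni correction over all ordered pairs.
#' Pairs with `global_pvalue` at or below `alpha` are reported (all pairs
#' with `all_pairs = TRUE`).
#'
#' Under the default pure-match scoring the best fragment of a pair after a
#' joint column permutation depends only on where that pair's mismatching
#' sites land, so each permutation is evaluated directly from the permuted
#' mismatch positions rather than by rebuilding the alignment.
#'
#' @param alignment Aligned sequences (>= 3), as for [polymorphic_sites()].
#' @param n_permutations Number of permutations (>= 1000).
#' @param seed Random seed (required; the test is Monte Carlo).
#' @param mismatch_penalty Fragment mismatch penalty (default `Inf`).
#' @param alpha Global significance threshold for reporting (default 0.05).
#' @param all_pairs Report every pair regardless of significance.
#' @return Data frame of conversion events: `seq_a`, `seq_b`,
#'   `fragment_start`, `fragment_end` (0-based half-open alignment
#'   columns), `n_polymorphic_in_fragment`, `score`, `sim_pvalue`,
#'   `global_pvalue`.
#' @export
permutation_test <- function(alignment, n_permutations = 10000, seed,
                             mismatch_penalty = Inf, alpha = 0.05,
                             all_pairs = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_permutations < 1000)
    stop("n_permutations must be at least 1000", call. = FALSE)
  m <- alignment_matrix(alignment)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(m)))
  sites0 <- polymorphic_sites(m)
  if (length(sites0) == 0L) {
    warning("no polymorphic sites; nothing to test", call. = FALSE)
    return(empty_conversion_events())
  }
  s <- length(sites0)
  nseq <- nrow(m)
  pairs <- utils::combn(nseq, 2)
  n_pairs <- ncol(pairs)
  n_ordered <- nseq * (nseq - 1L)

  obs <- vector("list", n_pairs)
  mism <- vector("list", n_pairs) # 1-based indices into `sites0`
  for (p in seq_len(n_pairs)) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    a <- m[i, sites0 + 1L]
    b <- m[j, sites0 + 1L]
    mism[[p]] <- which(a != b)
    obs[[p]] <- score_fragments(paste(m[i, ], collapse = ""),
                                paste(m[j, ], collapse = ""),
                                sites0, mismatch_penalty)
  }
  obs_score <- vapply(obs, `[[`, numeric(1), "score")

  pure <- !is.finite(mismatch_penalty)
  exceed <- with_local_seed(seed, {
    if (pure) {
      perm_exceed_counts(s, mism, obs_score, n_permutations)
    } else {
      ex <- integer(n_pairs)
      for (r in seq_len(n_permutations)) {
        o <- sample.int(s)
        for (p in seq_len(n_pairs)) {
          mvec <- rep(1, s)
          mvec[o %in% mism[[p]]] <- -mismatch_penalty
          if (kadane(mvec)$score >= obs_score[p]) ex[p] <- ex[p] + 1L
        }
      }
      ex
    }
  })

  sim_p <- (1 + exceed) / (1 + n_permutations)
  global_p <- pmin(1, sim_p * n_ordered)
  out <- data.frame(
    seq_a = ids[pairs[1, ]], seq_b = ids[pairs[2, ]],
    fragment_start = vapply(obs, `[[`, integer(1), "fragment_start"),
    fragment_end = vapply(obs, `[[`, integer(1), "fragment_end"),
    n_polymorphic_in_fragment =
      vapply(obs, `[[`, integer(1), "n_polymorphic_in_fragment"),
    score = obs_score, sim_pvalue = sim_p, global_pvalue = global_p,
    stringsAsFactors = FALSE)
  if (!all_pairs) out <- out[out$global_pvalue <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest run of matching polymorphic sites when the mismatches of a pair
# sit at (1-based) positions `pos` among `s` sites.
max_match_run <- function(pos, s) {
  k <- length(pos)
  if (k == 0L) return(s)
  pos <- sort.int(pos, method = "radix")
  max(pos[1] - 1L, s - pos[k], if (k > 1L) max(diff(pos)) - 1L else 0L)
}

empty_conversion_events <- function() {
  data.frame(seq_a = character(0), seq_b = character(0),
             fragment_start = integer(0), fragment_end = integer(0),
             n_polymorphic_in_fragment = integer(0), score = numeric(0),
             sim_pvalue = numeric(0), global_pvalue = numeric(0),
             stringsAsFactors = FALSE)
}
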