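# Motif identification: position-specific scoring profile built from a seed
# alignment, scanned over a proteome with empirical E-values calibrated on
# shuffled decoy proteomes. Self-contained replacement for a profile-HMM +
# BLASTP search chain.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Build a position-specific scoring profile from a seed motif alignment
#'
#' Alignment columns with more than `max_gap_frac` gaps are dropped; each
#' remaining column is converted to per-residue log-odds scores against a
#' background frequency vector:
#' `score = log2(((count + pseudocount * bg) / (total + pseudocount)) / bg)`.
#'
#' @param seed_alignment Aligned seed sequences: an `AAStringSet`, a named
#'   character vector, or a path to an aligned FASTA file.
#' @param pseudocount Total pseudocount weight distributed by background
#'   frequency (default 1).
#' @param background Named vector of 20 background frequencies summing to 1
#'   (default uniform).
#' @param max_gap_frac Columns with a gap fraction above this are dropped
#'   (default 0.5).
#' @return A list with class `"motif_profile"`: `scores` (20 x L log-odds
#'   matrix, rows named by residue), `length`, `consensus`, `core_pos`
#'   (profile columns holding the V,Q core, or `NULL` if the consensus has
#'   no VQ dipeptide), `background`, `pseudocount`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL, max_gap_frac = 0.5) {
  seqs <- as_aa_character(seed_alignment)
  if (length(seqs) < 2L)
    stop("need at least 2 seed sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("seed sequences are not aligned (unequal lengths)", call. = FALSE)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  background <- background[AA20]
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1", call. = FALSE)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- gap_frac <= max_gap_frac
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  if (L < 5L)
    stop("profile has fewer than 5 columns after gap filtering", call. = FALSE)
  scores <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    total <- length(col)
    counts <- table(factor(col, levels = AA20))
    freq <- (as.numeric(counts) + pseudocount * background) /
      (total + pseudocount)
    scores[, j] <- log2(freq / background)
  }
  consensus <- paste(AA20[apply(scores, 2, which.max)], collapse = "")
  core <- regexpr("VQ", consensus, fixed = TRUE)
  core_pos <- if (core[1] > 0) c(core[1], core[1] + 1L) else NULL
  structure(list(scores = scores, length = L, consensus = consensus,
                 core_pos = core_pos, background = background,
                 pseudocount = pseudocount),
            class = "motif_profile")
}

as_aa_character <- function(x) {
  if (inherits(x, "AAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(as.character(Biostrings::readAAStringSet(x)))
  if (is.character(x)) return(x)
  stop("cannot interpret seed alignment input", call. = FALSE)
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("Motif profile: %d columns, consensus %s\n", x$length,
              x$consensus))
  if (!is.null(x$core_pos))
    cat(sprintf("  V,Q core at columns %d-%d\n", x$core_pos[1], x$core_pos[2]))
  invisible(x)
}

# Scores of every window of `seq` under the profile; unknown letters (X etc.)
# contribute 0. Returns numeric(0) if the protein is shorter than the profile.
score_windows <- function(seq, profile) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  L <- profile$length
  if (n < L) return(numeric(0))
  idx <- match(aa, AA20)
  nw <- n - L + 1L
  total <- numeric(nw)
  for (j in seq_len(L)) {
    sj <- unname(profile$scores[, j][idx[j:(nw + j - 1L)]])
    sj[is.na(sj)] <- 0
    total <- total + sj
  }
  total
}

#' Scan a proteome for motif hits
#'
#' Slides the profile over every window of every protein and assigns each
#' window score an empirical E-value: the number of windows at or above that
#' score in `n_shuffles` within-protein shuffled copies of the whole
#' proteome, divided by `n_shuffles` (the expected count of hits at that
#' score in a same-sized random database of the same composition).
#' Windows with E-value at or below the cutoff are reported; overlapping
#' hits within a gene are merged to the best-scoring one (ties broken by
#' leftmost start), and the best hit per gene is flagged `primary`.
#'
#' @param proteome Named character vector, `AAStringSet`, or FASTA path.
#' @param profile A `"motif_profile"` from [build_profile()].
#' @param evalue_cutoff Empirical E-value threshold (default 0.01).
#' @param n_shuffles Number of shuffled decoy proteomes (default 10).
#' @param shuffle_seed Seed for decoy shuffling (default 1), so scans are
#'   reproducible.
#' @return Data frame of hits: `gene_id`, `start`, `end` (0-based half-open
#'   protein coordinates), `score`, `empirical_evalue`, `motif_seq`,
#'   `has_core_vq`, `core_variant`, `primary`, `status` (regex confirmation
#'   from [regex_confirm()]).
#' @export
scan_proteome <- function(proteome, profile, evalue_cutoff = 0.01,
                          n_shuffles = 10, shuffle_seed = 1) {
  seqs <- toupper(as_aa_character(proteome))
  if (is.null(names(seqs)))
    stop("proteome sequences must be named", call. = FALSE)
  L <- profile$length
  if (all(nchar(seqs) < L)) {
    warning("profile longer than every protein; no windows scanned",
            call. = FALSE)
    return(empty_hits())
  }
  decoy <- decoy_scores(seqs, profile, n_shuffles, shuffle_seed)
  n_decoy <- length(decoy)
  evalue_of <- function(s) {
    # count of decoy scores >= s, averaged over shuffles
    (n_decoy - findInterval(s, decoy, left.open = TRUE)) / n_shuffles
  }
  rows <- list()
  for (g in names(seqs)) {
    w <- score_windows(seqs[[g]], profile)
    if (length(w) == 0L) next
    ev <- evalue_of(w)
    keep <- which(ev <= evalue_cutoff)
    if (length(keep) == 0L) next
    kept <- merge_overlapping(keep, w[keep], L)
    for (k in kept) {
      st <- k - 1L
      motif_seq <- substring(seqs[[g]], k, k + L - 1L)
      core <- core_residues(motif_seq, profile)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, start = st, end = st + L,
        score = w[k], empirical_evalue = evalue_of(w[k]),
        motif_seq = motif_seq,
        has_core_vq = identical(core, "VQ"),
        core_variant = if (is.null(core)) NA_character_ else core,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits$primary <- FALSE
  for (g in unique(hits$gene_id)) {
    i <- which(hits$gene_id == g)
    best <- i[order(-hits$score[i], hits$start[i])][1]
    hits$primary[best] <- TRUE
  }
  hits$status <- regex_confirm(hits$motif_seq)
  rownames(hits) <- NULL
  hits
}

decoy_scores <- function(seqs, profile, n_shuffles, shuffle_seed) {
  scores <- with_local_seed(shuffle_seed, {
    out <- vector("list", n_shuffles)
    for (r in seq_len(n_shuffles)) {
      shuf <- vapply(seqs, function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, character(1))
      out[[r]] <- unlist(lapply(shuf, score_windows, profile = profile),
                         use.names = FALSE)
    }
    out
  })
  sort(unlist(scores, use.names = FALSE))
}

# Run code under a temporary RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Greedy merge of overlapping candidate windows: repeatedly keep the
# best-scoring window (ties -> leftmost) and drop windows overlapping it.
merge_overlapping <- function(starts, scores, L) {
  ord <- order(-scores, starts)
  starts <- starts[ord]
  kept <- integer(0)
  for (s in starts) {
    if (!any(abs(kept - s) < L)) kept <- c(kept, s)
  }
  sort(kept)
}

core_residues <- function(motif_seq, profile) {
  if (is.null(profile$core_pos)) return(NULL)
  substring(motif_seq, profile$core_pos[1], profile$core_pos[2])
}

empty_hits <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             score = numeric(0), empirical_evalue = numeric(0),
             motif_seq = character(0), has_core_vq = logical(0),
             core_variant = character(0), primary = logical(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Confirm motif hits against the canonical VQ motif pattern
#'
#' The canonical motif structure is `FxxhVQxhTG`, where `x` is any residue
#' and `h` a hydrophobic residue (A, V, L, I, M, F, W or C); a V,H core is
#' accepted in place of V,Q. Returns `"full"` when the full pattern is
#' found in the sequence, `"partial"` when only the V,Q (or V,H) core is
#' present, `"none"` otherwise.
#'
#' @param motif_seq Character vector of motif-window sequences (or a hits
#'   data frame with a `motif_seq` column).
#' @return Character vector of statuses.
#' @export
regex_confirm <- function(motif_seq) {
  if (is.data.frame(motif_seq)) motif_seq <- motif_seq$motif_seq
  h <- paste0("[", paste(HYDROPHOBIC, collapse = ""), "]")
  full <- paste0("F..", h, "V[QH].", h, "TG")
  ifelse(grepl(full, motif_seq),
         "full",
         ifelse(grepl("V[QH]", motif_seq), "partial", "none"))
}

#' Write motif hits as TSV
#'
#' @param hits Data frame from [scan_proteome()].
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
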