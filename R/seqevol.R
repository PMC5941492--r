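# Pairwise protein alignment, codon back-translation and NG86 Ka/Ks.

#' Align two protein sequences
#'
#' Smith-Waterman (local) or Needleman-Wunsch (global) alignment with affine
#' gap penalties. Defaults are BLOSUM62 with gap open 10 and gap extend 1.
#' A simple match/mismatch scheme can be supplied instead of a substitution
#' matrix (useful for toy examples and cross-checks).
#'
#' @param a,b Protein sequences (character strings).
#' @param mode `"local"` or `"global"`.
#' @param substitution Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`), or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param match,mismatch If both are given they override `substitution` with
#'   a uniform match/mismatch scoring scheme.
#' @return A list with class `"protein_alignment"`: `a`, `b` (aligned strings
#'   with `-` gaps), `score`, `start_a`, `start_b` (1-based offsets of the
#'   aligned region within the input sequences) and `mode`.
#' @export
align_protein_pair <- function(a, b, mode = c("local", "global"),
                               substitution = "BLOSUM62",
                               gap_open = 10, gap_extend = 1,
                               match = NULL, mismatch = NULL) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence", call. = FALSE)
  if (!is.null(match) && !is.null(mismatch)) {
    letters_ab <- unique(strsplit(paste0(a, b), "")[[1]])
    substitution <- matrix(mismatch, length(letters_ab), length(letters_ab),
                           dimnames = list(letters_ab, letters_ab))
    diag(substitution) <- match
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = if (mode == "local") "local" else "global",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- Biostrings::alignedPattern(pa)
  sub <- Biostrings::alignedSubject(pa)
  # alignedPattern covers the full sequence in global mode, so the offsets
  # only matter for local alignments
  structure(list(
    a = as.character(pat)[[1]],
    b = as.character(sub)[[1]],
    score = Biostrings::score(pa),
    start_a = if (mode == "local")
      Biostrings::start(Biostrings::pattern(pa)) else 1L,
    start_b = if (mode == "local")
      Biostrings::start(Biostrings::subject(pa)) else 1L,
    mode = mode
  ), class = "protein_alignment")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every aligned residue by its source codon and every gap by
#' `---`. The CDS must translate exactly to the protein it is paired with
#' (terminal stop codons are stripped first).
#'
#' @param alignment A `"protein_alignment"` (or a list with aligned strings
#'   `a`, `b` and offsets `start_a`, `start_b`; offsets default to 1).
#' @param cds_a,cds_b Coding sequences for the two proteins.
#' @param id_a,id_b Optional sequence identifiers carried into the result.
#' @param region Label for the aligned region, `"full_length"` or
#'   `"motif_only"`.
#' @return A list with class `"codon_alignment"`: `id_a`, `id_b`,
#'   `codons_a`, `codons_b` (codon vectors, `---` for gaps) and `region`.
#' @export
backtranslate <- function(alignment, cds_a, cds_b, id_a = "a", id_b = "b",
                          region = c("full_length", "motif_only")) {
  region <- match.arg(region)
  cds_a <- strip_terminal_stop(toupper(cds_a))
  cds_b <- strip_terminal_stop(toupper(cds_b))
  prot_a <- gsub("-", "", alignment$a, fixed = TRUE)
  prot_b <- gsub("-", "", alignment$b, fixed = TRUE)
  off_a <- if (is.null(alignment$start_a)) 1L else alignment$start_a
  off_b <- if (is.null(alignment$start_b)) 1L else alignment$start_b
  codons_a <- codons_for_row(alignment$a, prot_a, cds_a, off_a, "a")
  codons_b <- codons_for_row(alignment$b, prot_b, cds_b, off_b, "b")
  structure(list(id_a = id_a, id_b = id_b,
                 codons_a = codons_a, codons_b = codons_b,
                 region = region), class = "codon_alignment")
}

strip_terminal_stop <- function(cds) {
  if (nchar(cds) %% 3 != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  last <- substring(cds, nchar(cds) - 2L, nchar(cds))
  if (!is_stop_codon(last)) cds else substring(cds, 1L, nchar(cds) - 3L)
}

codons_for_row <- function(aligned, prot, cds, offset, label) {
  n_aa <- nchar(cds) / 3
  # the aligned region may be a local slice; the CDS must cover it
  if (offset + nchar(prot) - 1L > n_aa)
    stop(sprintf("CDS %s too short for aligned protein region", label),
         call. = FALSE)
  codons <- split_codons(cds)
  trans <- codon_table()[codons]
  chars <- strsplit(aligned, "")[[1]]
  out <- character(length(chars))
  k <- offset - 1L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      out[i] <- "---"
    } else {
      k <- k + 1L
      if (trans[k] != chars[i])
        stop(sprintf(
          "CDS %s does not translate to the aligned protein at residue %d (%s vs %s)",
          label, k, trans[k], chars[i]), call. = FALSE)
      out[i] <- codons[k]
    }
  }
  out
}

#' Nei-Gojobori (1986) Ka/Ks for a pairwise codon alignment
#'
#' Counts synonymous and nonsynonymous sites per codon (fraction of
#' single-nucleotide neighbors that are synonymous; changes to stop codons
#' are nonsynonymous), averages sites over the two sequences, counts observed
#' differences by averaging over all minimal mutational pathways that avoid
#' stop codons, and applies the Jukes-Cantor correction
#' `K = -3/4 log(1 - 4p/3)`. Columns containing a gap are dropped pairwise.
#'
#' The functional-constraint statistic is `c = 1 - Ka/Ks` with a percentile
#' confidence interval from a codon-column bootstrap; the pair is flagged as
#' under constraint when the whole interval lies above 0. This constraint
#' statistic is a reconstruction from first principles, not a published
#' formula, and is labelled as such in output.
#'
#' @param alignment A `"codon_alignment"` from [backtranslate()], or a list
#'   with codon vectors `codons_a`, `codons_b`.
#' @param n_boot Bootstrap replicates for the constraint interval (0 skips
#'   the bootstrap; default 1000).
#' @param conf Confidence level for the bootstrap interval.
#' @return A list with class `"kaks_result"`: site counts `N`, `S`, observed
#'   differences `Nd`, `Sd`, proportions `pN`, `pS`, corrected rates `Ka`,
#'   `Ks`, `ratio` (NA when undefined: Ks = 0, or a proportion >= 3/4),
#'   `c_value`, `c_low`, `c_high`, `under_constraint`, `n_codons` (ungapped
#'   columns), `region` and `estimator`.
#' @export
ng86 <- function(alignment, n_boot = 1000, conf = 0.95) {
  con <- ng86_contributions(alignment)
  if (length(con$sa) == 0L)
    stop("no ungapped codon columns in alignment", call. = FALSE)
  res <- ng86_from_sums(sum(con$sa), sum(con$sb), sum(con$sd), sum(con$nd),
                        3 * length(con$sa))
  res$n_codons <- length(con$sa)
  res$region <- if (is.null(alignment$region)) "full_length" else alignment$region
  res$id_a <- alignment$id_a
  res$id_b <- alignment$id_b
  res$estimator <- "NG86"
  res$c_low <- NA_real_
  res$c_high <- NA_real_
  res$under_constraint <- NA
  if (n_boot > 0L && length(con$sa) > 1L) {
    ci <- c_bootstrap(con, n_boot, conf)
    res$c_low <- ci[1]
    res$c_high <- ci[2]
    if (!any(is.na(ci))) res$under_constraint <- ci[1] > 0
  }
  class(res) <- "kaks_result"
  res
}

# Per-ungapped-column contributions: syn sites of each row, pathway-averaged
# syn/nonsyn differences. The bootstrap resamples these vectors.
ng86_contributions <- function(alignment) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  if (length(ca) != length(cb))
    stop("codon rows differ in length", call. = FALSE)
  keep <- ca != "---" & cb != "---" & !grepl("-", ca, fixed = TRUE) &
    !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]
  cb <- cb[keep]
  if (any(is_stop_codon(ca)) || any(is_stop_codon(cb)))
    stop("internal stop codon in alignment", call. = FALSE)
  syn <- syn_sites_table()
  dt <- diff_tables()
  list(sa = unname(syn[ca]), sb = unname(syn[cb]),
       sd = dt$sd[cbind(ca, cb)], nd = dt$nd[cbind(ca, cb)])
}

ng86_from_sums <- function(sum_sa, sum_sb, sum_sd, sum_nd, total_sites) {
  S <- (sum_sa + sum_sb) / 2
  N <- total_sites - S
  pS <- if (S > 0) sum_sd / S else NA_real_
  pN <- if (N > 0) sum_nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  list(N = N, S = S, Nd = sum_nd, Sd = sum_sd, pN = pN, pS = pS,
       Ka = Ka, Ks = Ks, ratio = ratio,
       c_value = if (is.na(ratio)) NA_real_ else 1 - ratio)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

c_bootstrap <- function(con, n_boot, conf) {
  m <- length(con$sa)
  idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = m)
  sa <- matrix(con$sa[idx], nrow = m)
  sb <- matrix(con$sb[idx], nrow = m)
  sd <- matrix(con$sd[idx], nrow = m)
  nd <- matrix(con$nd[idx], nrow = m)
  S <- (colSums(sa) + colSums(sb)) / 2
  N <- 3 * m - S
  pS <- colSums(sd) / S
  pN <- colSums(nd) / N
  ok <- pS < 0.75 & pN < 0.75 & pS > 0
  if (sum(ok) < n_boot / 2) return(c(NA_real_, NA_real_))
  Ks <- -0.75 * log(1 - 4 * pS[ok] / 3)
  Ka <- -0.75 * log(1 - 4 * pN[ok] / 3)
  cvals <- 1 - Ka / Ks
  alpha <- (1 - conf) / 2
  unname(stats::quantile(cvals, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 Ka/Ks (%s region, %d codons)\n", x$region, x$n_codons))
  cat(sprintf("  N = %.2f, S = %.2f, Nd = %.2f, Sd = %.2f\n",
              x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("  Ka = %s, Ks = %s, Ka/Ks = %s\n",
              fmt_na(x$Ka), fmt_na(x$Ks), fmt_na(x$ratio)))
  if (!is.na(x$c_value))
    cat(sprintf("  constraint c = 1 - Ka/Ks = %s [%s, %s]%s\n",
                fmt_na(x$c_value), fmt_na(x$c_low), fmt_na(x$c_high),
                if (isTRUE(x$under_constraint)) " (under constraint)" else ""))
  invisible(x)
}

fmt_na <- function(x) if (is.na(x)) "NA" else sprintf("%.4f", x)

#' Batch Ka/Ks over gene pairs
#'
#' Aligns each pair of proteins (global by default, so full-length rates are
#' comparable across pairs), back-translates against the CDS, and runs
#' [ng86()]. With `region = "motif_only"` the motif window of each gene
#' (from `motif_hits`) is extracted first and only those windows are aligned;
#' pairs missing a motif hit for either gene are skipped.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b` (and optionally
#'   `species`).
#' @param proteins,cds Named character vectors of protein and CDS sequences.
#' @param region `"full_length"` or `"motif_only"`.
#' @param motif_hits Data frame of motif hits (columns `gene_id`, `start`,
#'   `end`, 0-based half-open protein coordinates), required for
#'   `"motif_only"`.
#' @param n_boot Bootstrap replicates passed to [ng86()].
#' @param mode Alignment mode passed to [align_protein_pair()].
#' @return Data frame, one row per computed pair: ids, region, site and
#'   difference counts, `Ka`, `Ks`, `ratio`, constraint columns, and
#'   `positive_selection` (`ratio > 1`). Skipped pairs are dropped with a
#'   warning naming them.
#' @export
batch_kaks <- function(pairs, proteins, cds,
                       region = c("full_length", "motif_only"),
                       motif_hits = NULL, n_boot = 0, mode = "global") {
  region <- match.arg(region)
  if (region == "motif_only" && is.null(motif_hits))
    stop("motif_only region requires motif_hits", call. = FALSE)
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    if (is.na(proteins[ga]) || is.na(proteins[gb]) ||
        is.na(cds[ga]) || is.na(cds[gb])) {
      skipped <- c(skipped, paste(ga, gb))
      next
    }
    pa <- proteins[[ga]]; pb <- proteins[[gb]]
    ca <- cds[[ga]]; cb <- cds[[gb]]
    if (region == "motif_only") {
      ha <- best_hit(motif_hits, ga)
      hb <- best_hit(motif_hits, gb)
      if (is.null(ha) || is.null(hb)) {
        skipped <- c(skipped, paste(ga, gb))
        next
      }
      pa <- substring(pa, ha$start + 1L, ha$end)
      pb <- substring(pb, hb$start + 1L, hb$end)
      ca <- substring(ca, 3L * ha$start + 1L, 3L * ha$end)
      cb <- substring(cb, 3L * hb$start + 1L, 3L * hb$end)
    }
    aln <- align_protein_pair(pa, pb, mode = mode)
    caln <- backtranslate(aln, ca, cb, id_a = ga, id_b = gb, region = region)
    r <- ng86(caln, n_boot = n_boot)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb,
      species = if ("species" %in% names(pairs)) pairs$species[i] else NA_character_,
      region = region, n_codons = r$n_codons,
      N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
      Ka = r$Ka, Ks = r$Ks, ratio = r$ratio,
      c_value = r$c_value, c_low = r$c_low, c_high = r$c_high,
      under_constraint = if (is.na(r$under_constraint)) NA else r$under_constraint,
      positive_selection = !is.na(r$ratio) && r$ratio > 1,
      estimator = "NG86",
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0L)
    warning("skipped pairs with missing sequence or motif hit: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (length(rows) == 0L) return(empty_kaks_table())
  do.call(rbind, rows)
}

best_hit <- function(hits, gene) {
  h <- hits[hits$gene_id == gene, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(-h$score, h$start), , drop = FALSE]
  as.list(h[1L, ])
}

empty_kaks_table <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             species = character(0), region = character(0),
             n_codons = integer(0), N = numeric(0), S = numeric(0),
             Nd = numeric(0), Sd = numeric(0), Ka = numeric(0),
             Ks = numeric(0), ratio = numeric(0), c_value = numeric(0),
             c_low = numeric(0), c_high = numeric(0),
             under_constraint = logical(0), positive_selection = logical(0),
             estimator = character(0), stringsAsFactors = FALSE)
}

#' Per-species mean Ka/Ks summary of a batch table
#'
#' @param kaks Output of [batch_kaks()].
#' @return Data frame of per-species (and region) means and pair counts.
#' @export
summarize_kaks <- function(kaks) {
  if (nrow(kaks) == 0L) {
    return(data.frame(species = character(0), region = character(0),
                      n_pairs = integer(0), mean_ka = numeric(0),
                      mean_ks = numeric(0), mean_ratio = numeric(0)))
  }
  sp <- if (all(is.na(kaks$species))) "all" else kaks$species
  agg <- split(kaks, list(sp, kaks$region), drop = TRUE)
  out <- lapply(agg, function(d) data.frame(
    species = if (all(is.na(d$species))) "all" else d$species[1],
    region = d$region[1], n_pairs = nrow(d),
    mean_ka = mean(d$Ka, na.rm = TRUE), mean_ks = mean(d$Ks, na.rm = TRUE),
    mean_ratio = mean(d$ratio, na.rm = TRUE), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
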