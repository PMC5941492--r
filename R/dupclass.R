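# Expansion-mechanism classification: tandem arrays, segmental duplications,
# mobile-element capture, retrogenes.
#
# Gene tables use 0-based half-open coordinates internally (see read_gff3
# for the GFF conversion). `array_rank` is the ordinal position of a gene
# among ALL annotated genes on its chromosome, ordered by start.

ELEMENT_FAMILIES <- c("MULE", "hAT", "CACTA", "LTR", "helitron")

#' Assign chromosome-wise gene ranks
#'
#' Ranks every gene by start coordinate within its chromosome (ties broken
#' by end, then gene_id, so ranks are reproducible under input reordering).
#'
#' @param genes Gene table with `gene_id`, `chromosome`, `start`, `end`.
#' @return The table with an `array_rank` column added (1-based, per
#'   chromosome), rows in the original order.
#' @export
rank_genes <- function(genes) {
  genes$array_rank <- NA_integer_
  for (chr in unique(genes$chromosome)) {
    i <- which(genes$chromosome == chr)
    ord <- order(genes$start[i], genes$end[i], genes$gene_id[i])
    genes$array_rank[i[ord]] <- seq_along(i)
  }
  genes
}

#' Detect tandem arrays among family genes
#'
#' Two family genes are tandem-linked iff they lie on the same chromosome,
#' their chromosome-wide ranks differ by at most `max_rank_diff` genes, and
#' the genomic span from the leftmost start to the rightmost end of the two
#' genes is at most the species-class distance (100 kb for compact genomes
#' such as Arabidopsis and moss, 350 kb otherwise). Tandem arrays are the
#' connected components of this relation with at least two members.
#'
#' @param family Gene table for the family members (subset of `all_genes`).
#' @param all_genes Full gene annotation used to compute ranks; if it lacks
#'   an `array_rank` column, [rank_genes()] is applied.
#' @param species_class `"compact"` (100 kb) or `"large"` (350 kb; default).
#' @param max_rank_diff Maximum number of intervening array positions
#'   (default 10).
#' @param max_span Override for the distance threshold in bp (otherwise set
#'   by `species_class`).
#' @return Data frame of calls: `gene_id`, `mechanism` (`"tandem"`),
#'   `cluster_id`, `evidence`. Genes in no array are absent.
#' @export
detect_tandem_clusters <- function(family, all_genes,
                                   species_class = c("large", "compact"),
                                   max_rank_diff = 10, max_span = NULL) {
  species_class <- match.arg(species_class)
  if (is.null(max_span))
    max_span <- if (species_class == "compact") 100000 else 350000
  if (!"array_rank" %in% names(all_genes))
    all_genes <- rank_genes(all_genes)
  fam <- merge(family[, setdiff(names(family), "array_rank"), drop = FALSE],
               all_genes[, c("gene_id", "array_rank")], by = "gene_id")
  if (nrow(fam) < nrow(family))
    stop("family genes missing from the ranked annotation: ",
         paste(setdiff(family$gene_id, fam$gene_id), collapse = ", "),
         call. = FALSE)
  n <- nrow(fam)
  if (n < 2L) return(empty_dup_calls())
  linked <- outer(fam$chromosome, fam$chromosome, "==") &
    abs(outer(fam$array_rank, fam$array_rank, "-")) <= max_rank_diff &
    (outer(fam$end, fam$end, pmax) -
       outer(fam$start, fam$start, pmin)) <= max_span
  linked[lower.tri(linked, diag = TRUE)] <- FALSE
  idx <- which(linked, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_dup_calls())
  edges <- cbind(fam$gene_id[idx[, 1]], fam$gene_id[idx[, 2]])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  out <- data.frame(gene_id = igraph::V(g)$name,
                    mechanism = "tandem",
                    cluster_id = paste0("tandem_", comp$membership),
                    evidence = NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Detect segmentally duplicated family pairs from flanking anchors
#'
#' A family pair (g1, g2) is called segmental when at least `min_anchors`
#' homologous gene pairs (a, b), with a != g1 and b != g2, lie within
#' `flank` bp of g1 and g2 respectively (either orientation of the anchor
#' pair counts). Distance is the genomic gap between gene intervals (0 when
#' they overlap).
#'
#' @param family Gene table of family members.
#' @param all_genes Full gene annotation (anchor coordinates come from
#'   here).
#' @param homolog_pairs Data frame `gene_a`, `gene_b` (and optionally
#'   `identity`) of genome-wide homologous gene pairs.
#' @param flank Flank size in bp (default 50,000).
#' @param min_anchors Minimum supporting anchor pairs (default 2).
#' @return Data frame of pair calls: `gene_a`, `gene_b`, `mechanism`
#'   (`"segmental"`), `n_anchors`, `evidence` (anchor list).
#' @export
detect_segmental <- function(family, all_genes, homolog_pairs,
                             flank = 50000, min_anchors = 2) {
  coords <- all_genes[, c("gene_id", "chromosome", "start", "end")]
  rownames(coords) <- coords$gene_id
  missing <- setdiff(unique(c(homolog_pairs$gene_a, homolog_pairs$gene_b)),
                     coords$gene_id)
  if (length(missing) > 0L) {
    warning("anchors with missing coordinates skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    homolog_pairs <- homolog_pairs[
      !(homolog_pairs$gene_a %in% missing | homolog_pairs$gene_b %in% missing), ,
      drop = FALSE]
  }
  fam_ids <- family$gene_id
  out <- NULL
  if (length(fam_ids) >= 2L) {
    for (i in seq_len(length(fam_ids) - 1L)) {
      for (j in (i + 1L):length(fam_ids)) {
        g1 <- fam_ids[i]
        g2 <- fam_ids[j]
        sup <- anchor_support(g1, g2, coords, homolog_pairs, flank)
        if (length(sup) >= min_anchors || min_anchors == 0) {
          out <- rbind(out, data.frame(
            gene_a = g1, gene_b = g2, mechanism = "segmental",
            n_anchors = length(sup),
            evidence = paste(sup, collapse = ";"),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      mechanism = character(0), n_anchors = integer(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

anchor_support <- function(g1, g2, coords, pairs, flank) {
  sup <- character(0)
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[k]
    b <- pairs$gene_b[k]
    fwd <- a != g1 && b != g2 &&
      gene_gap(coords[a, ], coords[g1, ]) <= flank &&
      gene_gap(coords[b, ], coords[g2, ]) <= flank
    rev <- a != g2 && b != g1 &&
      gene_gap(coords[a, ], coords[g2, ]) <= flank &&
      gene_gap(coords[b, ], coords[g1, ]) <= flank
    if (fwd || rev) sup <- c(sup, paste0(a, "~", b))
  }
  sup
}

# Genomic gap between two gene intervals; Inf across chromosomes, 0 if they
# overlap or touch.
gene_gap <- function(x, y) {
  if (x$chromosome != y$chromosome) return(Inf)
  max(0, max(x$start, y$start) - min(x$end, y$end))
}

#' Attribute family genes to mobile elements
#'
#' A gene overlapping an annotated element span by at least 1 bp is
#' attributed to that element's family; with several overlapping elements
#' the largest overlap wins (ties broken by element order in the input).
#'
#' @param family Gene table of family members.
#' @param elements Data frame of element spans: `chromosome`, `start`,
#'   `end` (0-based half-open), `family` (one of MULE, hAT, CACTA, LTR,
#'   helitron), and optionally `element_id`.
#' @return Data frame of calls: `gene_id`, `mechanism` (element family),
#'   `evidence` (element id), `overlap_bp`.
#' @export
attribute_mobile_elements <- function(family, elements) {
  bad <- setdiff(unique(elements$family), ELEMENT_FAMILIES)
  if (length(bad) > 0L)
    stop("unknown element family label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!"element_id" %in% names(elements))
    elements$element_id <- paste0("elem_", seq_len(nrow(elements)))
  gr_genes <- GenomicRanges::GRanges(
    family$chromosome,
    IRanges::IRanges(start = family$start + 1L, end = family$end))
  gr_elem <- GenomicRanges::GRanges(
    elements$chromosome,
    IRanges::IRanges(start = elements$start + 1L, end = elements$end))
  ov <- GenomicRanges::findOverlaps(gr_genes, gr_elem)
  if (length(ov) == 0L) {
    return(data.frame(gene_id = character(0), mechanism = character(0),
                      evidence = character(0), overlap_bp = integer(0),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  wid <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_genes)[qh], IRanges::ranges(gr_elem)[sh]))
  out <- NULL
  for (q in unique(qh)) {
    i <- which(qh == q)
    best <- i[which.max(wid[i])]
    out <- rbind(out, data.frame(
      gene_id = family$gene_id[q],
      mechanism = elements$family[sh[best]],
      evidence = elements$element_id[sh[best]],
      overlap_bp = wid[best],
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect retrogenes within a family
#'
#' A family gene with at most one intron is called a retrogene when its best
#' protein match among multi-intron (>= 2) family members reaches the global
#' identity threshold; the matched gene is recorded as the parent.
#'
#' @param family Gene table with `intron_count` and `protein` columns.
#' @param identity_threshold Minimum global protein identity (default 0.70).
#' @return Data frame of calls: `gene_id`, `mechanism` (`"retrogene"`),
#'   `evidence` (parent gene id), `identity`.
#' @export
detect_retrogenes <- function(family, identity_threshold = 0.70) {
  if (!"intron_count" %in% names(family))
    stop("intron_count column required for retrogene detection",
         call. = FALSE)
  candidates <- family$gene_id[family$intron_count <= 1L]
  parents <- family$gene_id[family$intron_count >= 2L]
  out <- NULL
  for (g in candidates) {
    best_id <- NA_character_
    best_pid <- -Inf
    for (p in parents) {
      pid <- global_identity(family$protein[family$gene_id == g],
                             family$protein[family$gene_id == p])
      if (pid > best_pid) {
        best_pid <- pid
        best_id <- p
      }
    }
    if (!is.na(best_id) && best_pid >= identity_threshold) {
      out <- rbind(out, data.frame(
        gene_id = g, mechanism = "retrogene", evidence = best_id,
        identity = best_pid, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), mechanism = character(0),
                      evidence = character(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# Global protein identity: matches / alignment length under the package's
# default global alignment.
global_identity <- function(a, b) {
  aln <- align_protein_pair(a, b, mode = "global")
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Summarize expansion mechanisms over a family
#'
#' Counts genes carrying each mechanism and expresses them as percentages of
#' the family size. A gene may carry several mechanisms (e.g. both tandem
#' and segmental); each is counted under its own row, so percentages need
#' not sum to 100.
#'
#' @param tandem,segmental,elements,retro Call tables from the four
#'   detectors (any may be empty or NULL).
#' @param family_size Number of genes in the family.
#' @return Data frame `mechanism`, `n_genes`, `percent`.
#' @export
summarize_mechanisms <- function(tandem = NULL, segmental = NULL,
                                 elements = NULL, retro = NULL,
                                 family_size) {
  mech_genes <- list(
    tandem = if (!is.null(tandem) && nrow(tandem)) unique(tandem$gene_id)
             else character(0),
    segmental = if (!is.null(segmental) && nrow(segmental))
      unique(c(segmental$gene_a, segmental$gene_b)) else character(0),
    retrogene = if (!is.null(retro) && nrow(retro)) unique(retro$gene_id)
                else character(0))
  for (fam in ELEMENT_FAMILIES) {
    mech_genes[[fam]] <-
      if (!is.null(elements) && nrow(elements))
        unique(elements$gene_id[elements$mechanism == fam])
      else character(0)
  }
  classified <- unique(unlist(mech_genes))
  mechs <- c("tandem", "segmental", ELEMENT_FAMILIES, "retrogene")
  out <- data.frame(
    mechanism = c(mechs, "unclassified"),
    n_genes = c(vapply(mech_genes[mechs], length, integer(1)),
                max(0L, family_size - length(classified))),
    stringsAsFactors = FALSE)
  out$percent <- if (family_size > 0) 100 * out$n_genes / family_size else 0
  rownames(out) <- NULL
  out
}

empty_dup_calls <- function() {
  data.frame(gene_id = character(0), mechanism = character(0),
             cluster_id = character(0), evidence = character(0),
             stringsAsFactors = FALSE)
}
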