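# Synthetic-data generator: genomes with planted tandem arrays, segmental
# blocks, element-captured genes and retrogenes; codon pairs evolved at a
# known dN/dS; alignments with planted conversion tracts; gene trees with
# recorded duplication histories; expression matrices with planted tissue
# preference, stress regulation and co-expression.
#
# One global seed; each component derives its own stream from it so
# components can be regenerated independently.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the generator emulates: compact
#' plant-like chromosomes with geometric intergenic gaps, tandem arrays
#' within the species-class distance threshold, segmental blocks with
#' collinear flanking anchors, strong (fourfold) planted expression
#' signals, and moderate log-normal expression noise.
#'
#' @param seed Global seed; all component streams derive from it.
#' @param n_chromosomes,genes_per_chromosome Genome layout counts.
#' @param intergenic_mean Mean intergenic gap in bp (geometric draw).
#' @param n_tandem_arrays,tandem_array_size Planted tandem arrays.
#' @param n_segmental_blocks,block_anchor_genes Planted segmental pairs and
#'   the number of flanking anchor pairs supporting each.
#' @param n_element_genes Family genes planted on mobile elements.
#' @param n_retrogenes Planted retrogene (parent, intronless copy) pairs.
#' @param n_singletons Additional unlinked family genes.
#' @param n_vh_variants Family genes whose motif core is VH instead of VQ.
#' @param omega_values dN/dS ratios used when codon pairs are evolved.
#' @param target_ks Expected synonymous divergence of evolved pairs.
#' @param tract_length Planted conversion tract length in bp.
#' @param n_tissues,n_datasets,n_replicates Expression design counts.
#' @param fold_planted Fold-change of planted expression signals.
#' @param noise_sd Expression noise sd on the log2 scale.
#' @param n_expr_genes,n_preferred,n_regulated,n_coexpr_pairs Expression
#'   gene counts and planted signal counts.
#' @param species_class `"compact"` (100 kb tandem span) or `"large"`
#'   (350 kb).
#' @return A validated list with class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2, genes_per_chromosome = 150,
                       intergenic_mean = 3000,
                       n_tandem_arrays = 3, tandem_array_size = 3,
                       n_segmental_blocks = 2, block_anchor_genes = 3,
                       n_element_genes = 2, n_retrogenes = 1,
                       n_singletons = 3, n_vh_variants = 1,
                       omega_values = c(0.2, 0.5, 1, 2), target_ks = 0.3,
                       tract_length = 600,
                       n_tissues = 11, n_datasets = 5, n_replicates = 3,
                       fold_planted = 4, noise_sd = 0.25,
                       n_expr_genes = 60, n_preferred = 8, n_regulated = 8,
                       n_coexpr_pairs = 10,
                       species_class = c("large", "compact")) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = n_chromosomes,
              genes_per_chromosome = genes_per_chromosome,
              intergenic_mean = intergenic_mean,
              n_tandem_arrays = n_tandem_arrays,
              tandem_array_size = tandem_array_size,
              n_segmental_blocks = n_segmental_blocks,
              block_anchor_genes = block_anchor_genes,
              n_element_genes = n_element_genes,
              n_retrogenes = n_retrogenes,
              n_singletons = n_singletons,
              n_vh_variants = n_vh_variants,
              omega_values = omega_values, target_ks = target_ks,
              tract_length = tract_length,
              n_tissues = n_tissues, n_datasets = n_datasets,
              n_replicates = n_replicates,
              fold_planted = fold_planted, noise_sd = noise_sd,
              n_expr_genes = n_expr_genes, n_preferred = n_preferred,
              n_regulated = n_regulated, n_coexpr_pairs = n_coexpr_pairs,
              species_class = match.arg(species_class))
  structural <- c("n_chromosomes", "genes_per_chromosome", "intergenic_mean",
                  "tandem_array_size", "n_tissues", "n_datasets",
                  "n_replicates", "n_expr_genes")
  for (f in structural)
    if (cfg[[f]] < 1) stop(f, " must be >= 1", call. = FALSE)
  planted <- c("n_tandem_arrays", "n_segmental_blocks", "block_anchor_genes",
               "n_element_genes", "n_retrogenes", "n_singletons",
               "n_vh_variants", "n_preferred", "n_regulated",
               "n_coexpr_pairs")
  for (f in planted)
    if (cfg[[f]] < 0) stop(f, " must be >= 0", call. = FALSE)
  if (any(cfg$omega_values <= 0))
    stop("omega_values must be > 0", call. = FALSE)
  if (cfg$n_tissues < 2) stop("n_tissues must be >= 2", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# ---------------------------------------------------------------------------
# Genome simulation

#' Simulate a genome with planted expansion mechanisms
#'
#' Lays out genes on chromosomes with geometric intergenic gaps and plants,
#' with recorded ground truth: tandem arrays (consecutive ranks, intra-array
#' gaps forced small so the array sits well inside the species-class span
#' threshold; all other family genes kept more than 10 ranks from each
#' other), segmental pairs supported by collinear flanking anchor pairs
#' within the 50 kb flank, family genes overlapping labeled mobile
#' elements, and retrogene (multi-intron parent, intronless identical-
#' protein copy) pairs. Family genes carry an intact VQ motif in their
#' protein; everything else is background.
#'
#' @param config A [sim_config()].
#' @return A genome bundle: `genes` (gene table with `protein`, `cds`,
#'   `intron_count`), `elements`, `homolog_pairs`, `ground_truth`,
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed + 11L, simulate_genome_impl(config))
}

simulate_genome_impl <- function(cfg) {
  C <- cfg$n_chromosomes
  G <- cfg$genes_per_chromosome
  claimed <- lapply(seq_len(C), function(i) integer(0))
  buffer <- 12L

  claim_block <- function(k) {
    for (try in seq_len(500L)) {
      chr <- sample.int(C, 1L)
      if (G < k) next
      start <- sample.int(G - k + 1L, 1L)
      ranks <- start:(start + k - 1L)
      if (length(claimed[[chr]]) == 0L ||
          min(abs(outer(ranks, claimed[[chr]], "-"))) >= buffer) {
        claimed[[chr]] <<- c(claimed[[chr]], ranks)
        return(list(chr = chr, ranks = ranks))
      }
    }
    stop("impossible layout: cannot place planted features with the ",
         "required separation; increase genes_per_chromosome",
         call. = FALSE)
  }

  arrays <- lapply(seq_len(cfg$n_tandem_arrays), function(i)
    claim_block(cfg$tandem_array_size))
  seg <- lapply(seq_len(cfg$n_segmental_blocks), function(i)
    list(g1 = claim_block(1L), g2 = claim_block(1L)))
  elem <- lapply(seq_len(cfg$n_element_genes), function(i) claim_block(1L))
  retro <- lapply(seq_len(cfg$n_retrogenes), function(i)
    list(parent = claim_block(1L), copy = claim_block(1L)))
  singles <- lapply(seq_len(cfg$n_singletons), function(i) claim_block(1L))

  # per-chromosome gene geometry
  n_codons <- lapply(seq_len(C), function(chr) sample(120:300, G, TRUE))
  introns <- lapply(seq_len(C), function(chr) sample(2:5, G, TRUE))
  gaps <- lapply(seq_len(C), function(chr)
    stats::rgeom(G, 1 / (cfg$intergenic_mean + 1)) + 1L)
  # force small gaps inside planted arrays and around segmental genes
  for (a in arrays)
    gaps[[a$chr]][a$ranks[-1]] <- 500L
  for (s in seg) {
    for (side in s) {
      r <- side$ranks
      bag <- cfg$block_anchor_genes
      w <- max(1L, r - bag):min(G, r + bag + 1L)
      gaps[[side$chr]][setdiff(w, 1L)] <- 500L
      # 60 kb moat on both sides of the anchor window, so anchors are
      # within the 50 kb flank of their own family gene only
      for (m in c(r - bag - 1L, r + bag + 2L))
        if (m >= 2L && m <= G) gaps[[side$chr]][m] <- 60000L
    }
  }

  gene_rows <- list()
  for (chr in seq_len(C)) {
    span <- 3L * n_codons[[chr]] + 30L * introns[[chr]] + 50L
    starts <- cumsum(as.numeric(gaps[[chr]])) +
      cumsum(c(0, span[-G]))
    for (r in seq_len(G)) {
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = sprintf("chr%d_g%04d", chr, r),
        chromosome = paste0("chr", chr),
        strand = sample(c("+", "-"), 1L),
        start = as.integer(starts[r]),
        end = as.integer(starts[r] + span[r]),
        intron_count = introns[[chr]][r],
        n_codons = n_codons[[chr]][r],
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- genes$gene_id
  gid <- function(slot) sprintf("chr%d_g%04d", slot$chr, slot$ranks)

  family <- c(unlist(lapply(arrays, gid)),
              unlist(lapply(seg, function(s) c(gid(s$g1), gid(s$g2)))),
              unlist(lapply(elem, gid)),
              unlist(lapply(retro, function(s) c(gid(s$parent), gid(s$copy)))),
              unlist(lapply(singles, gid)))
  family <- unique(family)

  vh_genes <- if (cfg$n_vh_variants > 0 && length(family) > 0)
    sample(family, min(cfg$n_vh_variants, length(family))) else character(0)

  # sequences: family genes carry a planted intact motif
  genes$protein <- NA_character_
  genes$cds <- NA_character_
  motif_rows <- list()
  for (i in seq_len(nrow(genes))) {
    nc <- genes$n_codons[i]
    prot <- paste(sample(AA20, nc, TRUE), collapse = "")
    id <- genes$gene_id[i]
    if (id %in% family) {
      core <- if (id %in% vh_genes) "VH" else "VQ"
      inst <- motif_instance(core)
      len <- nchar(inst)
      pos <- sample(10:(nc - len - 10L), 1L)
      substr(prot, pos, pos + len - 1L) <- inst
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        gene_id = id, start = pos - 1L, end = pos + len - 1L, core = core,
        stringsAsFactors = FALSE)
    }
    genes$protein[i] <- prot
    genes$cds[i] <- reverse_translate(prot)
  }

  # retrogenes: copy is an intronless synonymous re-encoding of the parent
  for (rt in retro) {
    p <- gid(rt$parent)
    cpy <- gid(rt$copy)
    genes[cpy, "protein"] <- genes[p, "protein"]
    genes[cpy, "cds"] <- reverse_translate(genes[p, "protein"])
    genes[cpy, "intron_count"] <- 0L
    genes[p, "intron_count"] <- 4L
    mi <- which(vapply(motif_rows, function(m) m$gene_id == cpy, logical(1)))
    mp <- which(vapply(motif_rows, function(m) m$gene_id == p, logical(1)))
    motif_rows[[mi]] <- motif_rows[[mp]]
    motif_rows[[mi]]$gene_id <- cpy
  }

  # elements overlapping the planted element genes
  elements <- do.call(rbind, lapply(seq_along(elem), function(k) {
    g <- genes[gid(elem[[k]]), ]
    data.frame(chromosome = g$chromosome,
               start = max(0L, g$start - 150L), end = g$end + 150L,
               family = ELEMENT_FAMILIES[(k - 1L) %% 5L + 1L],
               element_id = sprintf("elem_%d", k),
               stringsAsFactors = FALSE)
  }))
  if (is.null(elements))
    elements <- data.frame(chromosome = character(0), start = integer(0),
                           end = integer(0), family = character(0),
                           element_id = character(0),
                           stringsAsFactors = FALSE)

  # homolog anchors flanking each segmental pair, plus the pair itself
  pair_rows <- list()
  for (s in seg) {
    g1 <- gid(s$g1)
    g2 <- gid(s$g2)
    pair_rows[[length(pair_rows) + 1L]] <- data.frame(
      gene_a = g1, gene_b = g2, identity = round(stats::runif(1, .75, .95), 3),
      stringsAsFactors = FALSE)
    offs <- utils::head(c(1L, -1L, 2L, -2L, 3L, -3L, 4L, -4L),
                        cfg$block_anchor_genes)
    for (o in offs) {
      r1 <- s$g1$ranks + o
      r2 <- s$g2$ranks + o
      if (r1 < 1L || r1 > G || r2 < 1L || r2 > G) next
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        gene_a = sprintf("chr%d_g%04d", s$g1$chr, r1),
        gene_b = sprintf("chr%d_g%04d", s$g2$chr, r2),
        identity = round(stats::runif(1, .75, .95), 3),
        stringsAsFactors = FALSE)
    }
  }
  homolog_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)

  truth <- list(
    species_class = cfg$species_class,
    family_genes = family,
    tandem_members = stats::setNames(
      lapply(arrays, gid),
      if (length(arrays)) sprintf("array_%d", seq_along(arrays))
      else character(0)),
    segmental_pairs = if (length(seg)) do.call(rbind, lapply(seg, function(s)
      data.frame(gene_a = gid(s$g1), gene_b = gid(s$g2),
                 stringsAsFactors = FALSE)))
      else data.frame(gene_a = character(0), gene_b = character(0)),
    element_genes = if (length(elem)) data.frame(
      gene_id = vapply(elem, gid, character(1)),
      family = elements$family, stringsAsFactors = FALSE)
      else data.frame(gene_id = character(0), family = character(0)),
    retrogenes = if (length(retro)) do.call(rbind, lapply(retro, function(s)
      data.frame(gene_id = gid(s$copy), parent = gid(s$parent),
                 stringsAsFactors = FALSE)))
      else data.frame(gene_id = character(0), parent = character(0)),
    motif_genes = if (length(motif_rows)) do.call(rbind, motif_rows)
      else data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), core = character(0)))

  genes$n_codons <- NULL
  rownames(genes) <- NULL
  list(genes = genes, elements = elements, homolog_pairs = homolog_pairs,
       ground_truth = truth, config = cfg)
}

#' Simulate a seed motif alignment
#'
#' Generates `n` intact motif-domain instances (the canonical core
#' `FxxhVQxhTG` with random `x` and hydrophobic `h` positions, inside
#' semi-conserved domain flanks), already aligned (equal length, no
#' gaps), as a stand-in seed set for profile building. The default of 119
#' sequences
#' matches the size of the Pfam VQ seed alignment; at that depth the
#' variable columns of the profile are close to background, so intact
#' motifs are not penalized for residues absent from the seeds. A fraction
#' of seeds (`vh_fraction`, default 10%) carries the VH core variant found
#' in monocot family members, so that VH-core genes remain detectable.
#'
#' @param n Number of seed sequences.
#' @param seed Random seed.
#' @param vh_fraction Fraction of seeds with a V,H core.
#' @return Named character vector of aligned motif sequences.
#' @export
simulate_seed_alignment <- function(n = 119, seed = 1, vh_fraction = 0.1) {
  with_local_seed(seed, {
    n_vh <- round(vh_fraction * n)
    cores <- sample(c(rep("VH", n_vh), rep("VQ", n - n_vh)))
    out <- vapply(cores, motif_instance, character(1))
    stats::setNames(out, sprintf("seed%03d", seq_len(n)))
  })
}

# One intact motif-domain instance: the canonical 10-residue core
# FxxhVQxhTG (or its VH variant) inside semi-conserved flanks, 30 residues
# in all. Real motif domains are much longer than the core decapeptide;
# the flanks carry the extra information a proteome-scale scan needs to
# separate true instances from the best shuffled-decoy windows.
DOMAIN_FLANK5 <- strsplit("EDLISKLYKN", "")[[1]]
DOMAIN_FLANK3 <- strsplit("WRPLDEYSAK", "")[[1]]
DOMAIN_CONSERVATION <- 0.9

motif_instance <- function(core = "VQ") {
  flank <- function(template) {
    keep <- stats::runif(length(template)) < DOMAIN_CONSERVATION
    out <- template
    out[!keep] <- sample(AA20, sum(!keep), TRUE)
    paste(out, collapse = "")
  }
  paste0(flank(DOMAIN_FLANK5),
         "F", paste(sample(AA20, 2, TRUE), collapse = ""),
         sample(HYDROPHOBIC, 1), core, sample(AA20, 1),
         sample(HYDROPHOBIC, 1), "TG",
         flank(DOMAIN_FLANK3))
}

# Random synonymous encoding of a protein (no stop codons by construction).
reverse_translate <- function(protein) {
  tab <- codon_table()
  by_aa <- split(names(tab), tab)
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(x) {
    opts <- by_aa[[x]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Validate a genome bundle against its recorded ground truth
#'
#' Checks that every planted feature names genes that exist, that all CDS
#' are in frame, stop-free and translate to their proteins, and that each
#' recorded motif window contains at least the motif core.
#'
#' @param genome Genome bundle from [simulate_genome()] (or read back with
#'   [read_genome_files()]).
#' @return `TRUE` (invisibly); stops with a message on any inconsistency.
#' @export
check_ground_truth <- function(genome) {
  genes <- genome$genes
  gt <- genome$ground_truth
  ids <- genes$gene_id
  ref <- c(unlist(gt$tandem_members), gt$segmental_pairs$gene_a,
           gt$segmental_pairs$gene_b, gt$element_genes$gene_id,
           gt$retrogenes$gene_id, gt$retrogenes$parent,
           gt$motif_genes$gene_id, gt$family_genes)
  missing <- setdiff(ref, ids)
  if (length(missing) > 0L)
    stop("ground truth references unknown genes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab <- codon_table()
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[i]
    if (nchar(cds) %% 3 != 0L)
      stop("CDS not in frame: ", genes$gene_id[i], call. = FALSE)
    codons <- split_codons(cds)
    if (any(tab[codons] == "*"))
      stop("internal stop codon in CDS: ", genes$gene_id[i], call. = FALSE)
    if (paste(tab[codons], collapse = "") != genes$protein[i])
      stop("CDS does not translate to protein: ", genes$gene_id[i],
           call. = FALSE)
  }
  mg <- gt$motif_genes
  for (k in seq_len(nrow(mg))) {
    prot <- genes$protein[genes$gene_id == mg$gene_id[k]]
    win <- substring(prot, mg$start[k] + 1L, mg$end[k])
    if (regex_confirm(win) == "none")
      stop("recorded motif window lacks the motif core: ", mg$gene_id[k],
           call. = FALSE)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Codon-pair evolution

#' Evolve a codon sequence pair at a known dN/dS
#'
#' Starting from a stop-free ancestor, substitutions are proposed uniformly
#' over nucleotide sites and alternative bases on a randomly chosen lineage.
#' Proposals creating a stop codon are rejected; synonymous and
#' nonsynonymous proposals are accepted with relative probability `omega`
#' (nonsynonymous : synonymous). Because NG86 counts mutations to stop
#' codons as nonsynonymous sites while the simulator never realizes them,
#' the nonsynonymous acceptance is inflated by the ancestor's stop-neighbor
#' site fraction, so that the realized rate per NG86 nonsynonymous site is
#' `omega` times the synonymous rate and the true dN/dS of the process (as
#' the estimator defines sites) equals `omega`.
#' Evolution stops when the accepted synonymous substitution count reaches
#' `round(target_ks * S)` with `S` the ancestor's synonymous site count
#' (NG86 counting), giving an expected pairwise Ks near `target_ks`.
#'
#' @param ancestor_len Ancestor length in codons (ignored when `ancestor`
#'   is given).
#' @param omega True dN/dS (>= 0; 0 forbids nonsynonymous change).
#' @param target_ks Target synonymous divergence per synonymous site.
#' @param seed Random seed.
#' @param ancestor Optional ancestor CDS (stop-free, in frame).
#' @return List: `cds_a`, `cds_b`, `ancestor`, realized counts `n_syn`,
#'   `n_nonsyn`, ancestral site counts `S`, `N`, and `realized_ratio`
#'   (`(n_nonsyn/N) / (n_syn/S)`, NA when no synonymous change).
#' @export
evolve_codon_pair <- function(ancestor_len, omega, target_ks, seed,
                              ancestor = NULL) {
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  with_local_seed(seed, {
    if (is.null(ancestor)) ancestor <- random_cds(ancestor_len)
    anc <- split_codons(ancestor)
    tab <- codon_table()
    if (any(tab[anc] == "*"))
      stop("ancestor contains an internal stop codon", call. = FALSE)
    syn_tab <- syn_sites_table()
    S <- sum(syn_tab[anc])
    N <- 3 * length(anc) - S
    target_syn <- round(target_ks * S)
    # stop-neighbor compensation: keep the realized per-NG86-site ratio at
    # omega even though stop-creating proposals never realize
    stop_sites <- sum(stop_sites_table()[anc])
    g <- N / (N - stop_sites)
    w <- omega * g
    p_syn <- if (w > 1) 1 / w else 1
    p_nonsyn <- min(1, w)
    seqs <- list(a = anc, b = anc)
    n_syn <- 0L
    n_nonsyn <- 0L
    guard <- 0L
    while (n_syn < target_syn) {
      guard <- guard + 1L
      if (guard > 1e7) stop("codon evolution failed to converge",
                            call. = FALSE)
      lin <- if (stats::runif(1) < 0.5) "a" else "b"
      ci <- sample.int(length(anc), 1L)
      pos <- sample.int(3L, 1L)
      cur <- seqs[[lin]][ci]
      nt <- sample(NUCS[NUCS != substr(cur, pos, pos)], 1L)
      new <- cur
      substr(new, pos, pos) <- nt
      if (tab[new] == "*") next
      if (tab[new] == tab[cur]) {
        if (stats::runif(1) <= p_syn) {
          seqs[[lin]][ci] <- new
          n_syn <- n_syn + 1L
        }
      } else if (p_nonsyn > 0 && stats::runif(1) <= p_nonsyn) {
        seqs[[lin]][ci] <- new
        n_nonsyn <- n_nonsyn + 1L
      }
    }
    ratio <- if (n_syn > 0) (n_nonsyn / N) / (n_syn / S) else NA_real_
    list(cds_a = paste(seqs$a, collapse = ""),
         cds_b = paste(seqs$b, collapse = ""),
         ancestor = ancestor, n_syn = n_syn, n_nonsyn = n_nonsyn,
         S = S, N = N, realized_ratio = ratio)
  })
}

#' Simulate a coding multiple alignment with an optional conversion tract
#'
#' Each sequence diverges independently from a stop-free common ancestor by
#' per-nucleotide substitution at the given rate (stop-creating changes are
#' suppressed). A planted tract copies a codon-aligned window from one
#' sequence of a pair into the other, making them identical there — the
#' signature a gene-conversion scan looks for.
#'
#' @param n_seq Number of sequences (>= 3).
#' @param n_codons Alignment length in codons.
#' @param divergence Per-nucleotide substitution probability from the
#'   ancestor.
#' @param seed Random seed.
#' @param tract `NULL`, or a list with `pair` (two sequence indices),
#'   `start` (0-based alignment column, rounded down to a codon boundary)
#'   and `length` (bp, rounded to whole codons).
#' @return List: `alignment` (named character vector), `truth` (`NULL` or
#'   the planted tract as `pair`, `start`, `end` in 0-based half-open
#'   columns).
#' @export
simulate_conversion_alignment <- function(n_seq = 6, n_codons = 100,
                                          divergence = 0.1, seed,
                                          tract = NULL) {
  if (n_seq < 3L) stop("need at least 3 sequences", call. = FALSE)
  with_local_seed(seed, {
    tab <- codon_table()
    anc <- split_codons(random_cds(n_codons))
    seqs <- vapply(seq_len(n_seq), function(i) {
      cod <- anc
      for (ci in seq_along(cod)) {
        for (pos in 1:3) {
          if (stats::runif(1) < divergence) {
            new <- cod[ci]
            substr(new, pos, pos) <-
              sample(NUCS[NUCS != substr(new, pos, pos)], 1L)
            if (tab[new] != "*") cod[ci] <- new
          }
        }
      }
      paste(cod, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("seq%d", seq_len(n_seq))
    truth <- NULL
    if (!is.null(tract)) {
      start <- (tract$start %/% 3L) * 3L
      len <- max(3L, (tract$length %/% 3L) * 3L)
      end <- min(start + len, 3L * n_codons)
      donor <- tract$pair[1]
      recip <- tract$pair[2]
      substr(seqs[recip], start + 1L, end) <-
        substring(seqs[donor], start + 1L, end)
      truth <- list(pair = c(names(seqs)[donor], names(seqs)[recip]),
                    start = start, end = end)
    }
    list(alignment = seqs, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Gene trees with recorded duplication histories

#' Simulate a gene tree by recorded duplications along a species backbone
#'
#' Lineages split off the backbone in order: split k separates lineage k
#' from all later lineages. `n_at_splits[k]` genes exist when split k
#' happens; every gene leaves at least one descendant on both sides of
#' every split it spans (duplication-only history, no loss), so the
#' ancestral-unit count at split k is exactly `n_at_splits[k]`.
#'
#' @param n_at_splits Integer vector of gene counts at each successive
#'   split (non-decreasing; length = number of splits).
#' @param lineage_species List of character vectors of species per lineage
#'   (length = number of splits + 1).
#' @param seed Random seed.
#' @param mean_extra_leaves Mean extra within-lineage duplications per
#'   terminal clade (Poisson).
#' @return List: `tree` (rooted `phylo`), `leaf_species`, `splits`
#'   (deepest first, each a list with `a`, `b`), `n_at_splits`.
#' @export
simulate_duplication_tree <- function(n_at_splits, lineage_species, seed,
                                      mean_extra_leaves = 0.7) {
  m <- length(n_at_splits)
  if (length(lineage_species) != m + 1L)
    stop("need one more lineage than splits", call. = FALSE)
  if (m > 1L && any(diff(n_at_splits) < 0))
    stop("n_at_splits must be non-decreasing (duplication-only history)",
         call. = FALSE)
  with_local_seed(seed, {
    env <- new.env()
    env$counter <- 0L
    env$species <- character(0)

    clade_of <- function(lineage) {
      k <- 1L + stats::rpois(1, mean_extra_leaves)
      labs <- vapply(seq_len(k), function(i) {
        env$counter <- env$counter + 1L
        sp <- lineage[sample.int(length(lineage), 1L)]
        lab <- sprintf("t%d_%s", env$counter, sp)
        env$species[lab] <- sp
        lab
      }, character(1))
      join_random(labs)
    }

    grow <- function(k) {
      if (k == m) {
        sprintf("(%s,%s)", clade_of(lineage_species[[k]]),
                clade_of(lineage_species[[k + 1L]]))
      } else {
        n_child <- env$assign[[k]][env$next_child[k]]
        env$next_child[k] <- env$next_child[k] + 1L
        kids <- vapply(seq_len(n_child), function(i) grow(k + 1L),
                       character(1))
        sprintf("(%s,%s)", clade_of(lineage_species[[k]]),
                join_random(kids))
      }
    }

    # how many split-(k+1) genes descend from each split-k gene
    env$assign <- lapply(seq_len(max(0L, m - 1L)), function(k) {
      counts <- rep(1L, n_at_splits[k])
      extra <- n_at_splits[k + 1L] - n_at_splits[k]
      if (extra > 0L) {
        idx <- sample.int(n_at_splits[k], extra, replace = TRUE)
        counts <- counts + tabulate(idx, n_at_splits[k])
      }
      counts
    })
    env$next_child <- rep(1L, max(1L, m - 1L))

    roots <- vapply(seq_len(n_at_splits[1]), function(i) grow(1L),
                    character(1))
    newick <- paste0(join_random(roots), ";")
    tree <- ape::read.tree(text = newick)
    splits <- lapply(seq_len(m), function(k) list(
      a = lineage_species[[k]],
      b = unique(unlist(lineage_species[(k + 1L):(m + 1L)]))))
    list(tree = tree, leaf_species = env$species, splits = splits,
         n_at_splits = n_at_splits)
  })
}

join_random <- function(items) {
  while (length(items) > 1L) {
    i <- sample.int(length(items), 2L)
    merged <- sprintf("(%s,%s)", items[i[1]], items[i[2]])
    items <- c(items[-i], merged)
  }
  items
}

# ---------------------------------------------------------------------------
# Expression simulation

#' Simulate expression matrices with planted regulation and co-expression
#'
#' Generates, on the log2 scale with i.i.d. normal noise (`noise_sd`),
#' exponentiated to FPKM-like abundances:
#' a tissue atlas in which planted genes are expressed `fold_planted`-fold
#' (with margin) above every non-focal tissue; treatment datasets
#' (control/treated) with planted up- and down-regulated genes; and
#' `n_datasets` unstructured co-expression datasets in which each planted
#' pair shares a latent per-sample profile, with the recorded sign, in
#' `min(4, n_datasets)` of them.
#'
#' @param config A [sim_config()].
#' @param gene_ids Optional gene id vector (defaults to
#'   `config$n_expr_genes` generated ids).
#' @return List: `datasets` (named list of `mat` + `sample_map` + `type`),
#'   `truth` (`preferred_genes`, `regulated_genes`, `coexpressed_pairs`).
#' @export
simulate_expression <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed + 29L, {
    genes <- if (is.null(gene_ids))
      sprintf("g%03d", seq_len(cfg$n_expr_genes)) else gene_ids
    ng <- length(genes)
    pool <- sample(genes)
    take <- function(n) {
      n <- min(n, length(pool))
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    preferred <- take(cfg$n_preferred)
    regulated <- take(cfg$n_regulated)
    coex <- take(2L * cfg$n_coexpr_pairs)
    tissues <- sprintf("T%d", seq_len(cfg$n_tissues))
    fold <- cfg$fold_planted
    noise <- cfg$noise_sd
    reps <- cfg$n_replicates

    # tissue atlas
    pref_tissue <- stats::setNames(sample(tissues, length(preferred), TRUE),
                                   preferred)
    mu <- matrix(stats::runif(ng * cfg$n_tissues, 0, 2), ng,
                 dimnames = list(genes, tissues))
    for (g in preferred) {
      others <- setdiff(tissues, pref_tissue[g])
      mu[g, others] <- stats::runif(length(others), 0, 2)
      mu[g, pref_tissue[g]] <- log2(1.5 * fold) + max(mu[g, others])
    }
    atlas <- expr_matrix(mu, reps, noise)

    # treatment datasets
    treatments <- c("drought", "salt")
    reg_rows <- data.frame(gene = regulated,
                           treatment = rep(treatments,
                                           length.out = length(regulated)),
                           direction = rep(c("up", "down"),
                                           length.out = length(regulated)),
                           stringsAsFactors = FALSE)
    treat_sets <- list()
    for (tr in treatments) {
      mu_t <- matrix(stats::runif(ng * 2, 1, 3), ng,
                     dimnames = list(genes, c("control", "treated")))
      mu_t[, "treated"] <- mu_t[, "control"] +
        stats::rnorm(ng, 0, 0.05)
      sel <- reg_rows[reg_rows$treatment == tr, ]
      for (k in seq_len(nrow(sel))) {
        g <- sel$gene[k]
        if (sel$direction[k] == "up")
          mu_t[g, "treated"] <- mu_t[g, "control"] + log2(1.5 * fold)
        else
          mu_t[g, "treated"] <- mu_t[g, "control"] - log2(1.5 * fold)
      }
      treat_sets[[tr]] <- expr_matrix(mu_t, reps, noise, type = "treatment")
    }

    # co-expression datasets
    pairs <- data.frame(
      gene_a = coex[seq_len(length(coex) / 2)],
      gene_b = coex[seq_len(length(coex) / 2) + length(coex) / 2],
      sign = sample(c(1, -1), length(coex) / 2, TRUE),
      stringsAsFactors = FALSE)
    n_samples <- 20L
    planted_in <- seq_len(min(4L, cfg$n_datasets))
    coex_sets <- list()
    for (d in seq_len(cfg$n_datasets)) {
      base <- stats::runif(ng, 1, 4)
      m <- matrix(stats::rnorm(ng * n_samples, 0, 1), ng) + base
      rownames(m) <- genes
      colnames(m) <- sprintf("s%02d", seq_len(n_samples))
      if (d %in% planted_in) {
        for (k in seq_len(nrow(pairs))) {
          z <- stats::rnorm(n_samples, 0, 1)
          m[pairs$gene_a[k], ] <- base[match(pairs$gene_a[k], genes)] + z +
            stats::rnorm(n_samples, 0, noise)
          m[pairs$gene_b[k], ] <- base[match(pairs$gene_b[k], genes)] +
            pairs$sign[k] * z + stats::rnorm(n_samples, 0, noise)
        }
      }
      coex_sets[[sprintf("coexpr%d", d)]] <- list(
        mat = 2^m,
        sample_map = data.frame(sample = colnames(m), group = "sample",
                                replicate = seq_len(n_samples),
                                stringsAsFactors = FALSE),
        type = "coexpression")
    }

    datasets <- c(list(tissues = atlas), treat_sets, coex_sets)
    truth <- list(
      preferred_genes = data.frame(gene = preferred,
                                   tissue = unname(pref_tissue[preferred]),
                                   stringsAsFactors = FALSE),
      regulated_genes = reg_rows,
      coexpressed_pairs = pairs)
    list(datasets = datasets, truth = truth)
  })
}

# Expand a genes x groups mean matrix (log2) into a replicated noisy
# abundance matrix with its sample map.
expr_matrix <- function(mu, reps, noise_sd, type = "tissues") {
  groups <- colnames(mu)
  samples <- as.vector(outer(groups, seq_len(reps),
                             function(g, r) sprintf("%s.r%d", g, r)))
  m <- matrix(NA_real_, nrow(mu), length(samples),
              dimnames = list(rownames(mu), samples))
  for (j in seq_along(groups)) {
    for (r in seq_len(reps)) {
      m[, sprintf("%s.r%d", groups[j], r)] <-
        2^(mu[, j] + stats::rnorm(nrow(mu), 0, noise_sd))
    }
  }
  list(mat = m,
       sample_map = data.frame(
         sample = samples,
         group = rep(groups, times = reps),
         replicate = rep(seq_len(reps), each = length(groups)),
         stringsAsFactors = FALSE),
       type = type)
}
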