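# End-to-end orchestration: build a complete synthetic input bundle and run
# every analysis stage over it, writing per-stage TSVs and a summary JSON.

#' Write a complete synthetic input bundle
#'
#' Generates and writes every input the pipeline consumes: the genome
#' bundle (GFF3, protein/CDS FASTA, element BED, homolog-pair TSV), a seed
#' motif alignment, an aligned coding sequence set with a planted
#' conversion tract, a species-labeled gene tree with its lineage map, the
#' expression datasets, and a combined ground-truth JSON sidecar.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  write_genome_files(genome, dir)

  seed_aln <- simulate_seed_alignment(n = 119, seed = config$seed + 41L)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seed_aln),
                              file.path(dir, "seed_motifs.faa"))

  conv <- simulate_conversion_alignment(
    n_seq = 6, n_codons = 300, divergence = 0.1,
    seed = config$seed + 43L,
    tract = list(pair = c(1, 2), start = 150, length = config$tract_length))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(conv$alignment),
                              file.path(dir, "conversion_alignment.fna"))

  sim_tree <- simulate_duplication_tree(
    n_at_splits = c(5, 9),
    lineage_species = list("moss", "gymnosperm", c("dicot", "monocot")),
    seed = config$seed + 47L)
  ape::write.tree(sim_tree$tree, file.path(dir, "gene_tree.nwk"))
  utils::write.table(
    data.frame(leaf = names(sim_tree$leaf_species),
               species = unname(sim_tree$leaf_species),
               stringsAsFactors = FALSE),
    file.path(dir, "leaf_species.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  filler_n <- max(0L, config$n_expr_genes -
                    length(genome$ground_truth$family_genes))
  expr_ids <- c(genome$ground_truth$family_genes,
                sprintf("bg%03d", seq_len(filler_n)))
  expr <- simulate_expression(config, gene_ids = expr_ids)
  for (nm in names(expr$datasets)) {
    write_expression_tsv(expr$datasets[[nm]]$mat,
                         expr$datasets[[nm]]$sample_map,
                         file.path(dir, paste0("expr_", nm)))
  }

  truth <- genome$ground_truth
  truth$conversion_tract <- conv$truth
  truth$tree_units <- list(
    n_at_splits = sim_tree$n_at_splits,
    splits = sim_tree$splits)
  truth$expression <- expr$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(species_class = config$species_class, seed = config$seed,
         n_tissues = config$n_tissues,
         expr_datasets = names(expr$datasets),
         treatments = unique(expr$truth$regulated_genes$treatment)),
    file.path(dir, "fixture_config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline over an input bundle
#'
#' Stages run in order: motif identification, duplication classification,
#' Ka/Ks estimation, gene-conversion detection, ancestral-unit counting,
#' expression classification. Each stage writes its TSV into `out_dir` and
#' contributes to `summary.json`; disabled stages are marked `"skipped"`.
#' All stochastic stages derive their streams from `seed`, so a rerun with
#' the same inputs and seed reproduces `summary.json` byte for byte.
#'
#' @param dir Input bundle directory (see [make_fixture()]).
#' @param out_dir Output directory.
#' @param seed Integer seed for the stochastic stages.
#' @param stages Character vector of stages to run (default all of
#'   `identify`, `dupclass`, `kaks`, `geneconv`, `treeunits`, `expression`).
#' @param params Optional overrides: `evalue_cutoff`, `species_class`,
#'   `flank`, `min_anchors`, `n_boot`, `n_permutations`, `fold`,
#'   `r_threshold`, `min_datasets`.
#' @return The summary list, invisibly; `summary.json` and per-stage TSVs
#'   are written to `out_dir`.
#' @export
run_pipeline <- function(dir, out_dir, seed = 1,
                         stages = c("identify", "dupclass", "kaks",
                                    "geneconv", "treeunits", "expression"),
                         params = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- utils::modifyList(list(
    evalue_cutoff = 0.01, species_class = NULL, flank = 50000,
    min_anchors = 2, n_boot = 200, n_permutations = 2000, fold = 2,
    r_threshold = 0.8, min_datasets = 3), params)
  fixture_cfg <- read_if_exists(file.path(dir, "fixture_config.json"))
  if (is.null(p$species_class))
    p$species_class <- if (!is.null(fixture_cfg$species_class))
      fixture_cfg$species_class else "large"
  summary <- list(seed = seed, parameters = p[order(names(p))])
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("pipeline run: seed=%d species_class=%s\n", seed,
              p$species_class), file = log_path)
  logmsg <- function(...) cat(sprintf(...), "\n", file = log_path,
                              append = TRUE, sep = "")

  genome <- run_stage("input", logmsg, read_genome_files(dir))
  genes <- rank_genes(genome$genes)
  proteins <- stats::setNames(genes$protein, genes$gene_id)
  cds <- stats::setNames(genes$cds, genes$gene_id)

  hits <- NULL
  family <- NULL
  if ("identify" %in% stages) {
    hits <- run_stage("identify", logmsg, {
      profile <- build_profile(file.path(dir, "seed_motifs.faa"))
      scan_proteome(proteins, profile, evalue_cutoff = p$evalue_cutoff,
                    shuffle_seed = seed + 1L)
    })
    write_hits_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
    # confirmation step: scan candidates must carry the motif core
    family <- unique(hits$gene_id[hits$primary &
                                    hits$status %in% c("full", "partial")])
    summary$identify <- list(
      n_hits = nrow(hits), family_size = length(family),
      n_full_motif = sum(hits$status == "full" & hits$primary),
      n_vh_core = sum(hits$core_variant == "VH" & hits$primary,
                      na.rm = TRUE))
  } else summary$identify <- "skipped"

  fam_genes <- if (!is.null(family))
    genes[genes$gene_id %in% family, , drop = FALSE] else NULL
  if ("dupclass" %in% stages && !is.null(fam_genes)) {
    dup <- run_stage("dupclass", logmsg, {
      tandem <- detect_tandem_clusters(fam_genes, genes,
                                       species_class = p$species_class)
      segmental <- detect_segmental(fam_genes, genes,
                                    genome$homolog_pairs,
                                    flank = p$flank,
                                    min_anchors = p$min_anchors)
      elem <- attribute_mobile_elements(fam_genes, genome$elements)
      retro <- detect_retrogenes(fam_genes)
      list(tandem = tandem, segmental = segmental, elem = elem,
           retro = retro)
    })
    for (nm in names(dup))
      utils::write.table(dup[[nm]],
                         file.path(out_dir, paste0("dup_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    mech <- summarize_mechanisms(dup$tandem, dup$segmental, dup$elem,
                                 dup$retro, family_size = nrow(fam_genes))
    utils::write.table(mech, file.path(out_dir, "mechanism_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$dupclass <- list(
      mechanisms = mech,
      n_tandem_clusters = length(unique(dup$tandem$cluster_id)))
  } else {
    dup <- NULL
    summary$dupclass <- "skipped"
  }

  if ("kaks" %in% stages && !is.null(dup)) {
    kaks <- run_stage("kaks", logmsg, with_local_seed(seed + 5L, {
      pairs <- rbind(tandem_pairs(dup$tandem),
                     dup$segmental[dup$segmental$mechanism == "segmental",
                                   c("gene_a", "gene_b")])
      pairs <- unique(pairs)
      if (nrow(pairs) == 0L) empty_kaks_table() else rbind(
        batch_kaks(pairs, proteins, cds, region = "full_length",
                   n_boot = p$n_boot),
        batch_kaks(pairs, proteins, cds, region = "motif_only",
                   motif_hits = hits, n_boot = p$n_boot))
    }))
    utils::write.table(kaks, file.path(out_dir, "kaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$kaks <- list(
      n_pairs = nrow(kaks),
      mean_ratio_full = mean_or_na(kaks$ratio[kaks$region == "full_length"]),
      mean_ratio_motif = mean_or_na(kaks$ratio[kaks$region == "motif_only"]),
      positive_selection_pairs = kaks_pair_ids(
        kaks[kaks$positive_selection, , drop = FALSE]))
  } else summary$kaks <- "skipped"

  if ("geneconv" %in% stages) {
    conv <- run_stage("geneconv", logmsg, {
      aln <- Biostrings::readDNAStringSet(
        file.path(dir, "conversion_alignment.fna"))
      permutation_test(as.character(aln),
                       n_permutations = p$n_permutations,
                       seed = seed + 7L)
    })
    utils::write.table(conv, file.path(out_dir, "conversion_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$geneconv <- list(
      n_events = nrow(conv),
      pairs = if (nrow(conv)) paste(conv$seq_a, conv$seq_b, sep = "~")
              else character(0))
  } else summary$geneconv <- "skipped"

  if ("treeunits" %in% stages) {
    units <- run_stage("treeunits", logmsg, {
      tree <- ape::read.tree(file.path(dir, "gene_tree.nwk"))
      lmap <- utils::read.delim(file.path(dir, "leaf_species.tsv"),
                                stringsAsFactors = FALSE)
      leaf_species <- stats::setNames(lmap$species, lmap$leaf)
      # unsimplified read: splits are ragged lists of species vectors
      gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
      splits <- lapply(gt$tree_units$splits, function(s)
        list(a = unlist(s$a), b = unlist(s$b)))
      units_along_backbone(tree, leaf_species, splits)
    })
    utils::write.table(units, file.path(out_dir, "ancestral_units.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$treeunits <- list(splits = units$split, n_units = units$n_units)
  } else summary$treeunits <- "skipped"

  if ("expression" %in% stages) {
    expr <- run_stage("expression", logmsg, {
      ds_names <- fixture_cfg$expr_datasets
      datasets <- lapply(ds_names, function(nm)
        read_expression_tsv(file.path(dir, paste0("expr_", nm))))
      names(datasets) <- ds_names
      atlas <- datasets$tissues
      tis <- classify_tissue(atlas$mat, atlas$sample_map, fold = p$fold)
      treats <- list()
      for (tr in fixture_cfg$treatments) {
        d <- datasets[[tr]]
        treats[[tr]] <- classify_treatment(d$mat, d$sample_map,
                                           fold = p$fold)
      }
      coexpr <- coexpression_pairs(
        datasets[grep("^coexpr", ds_names, value = TRUE)],
        r_threshold = p$r_threshold, min_datasets = p$min_datasets)
      list(tissue = tis, treatments = treats, coexpr = coexpr)
    })
    utils::write.table(expr$tissue,
                       file.path(out_dir, "tissue_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (tr in names(expr$treatments))
      utils::write.table(expr$treatments[[tr]],
                         file.path(out_dir,
                                   paste0("regulation_", tr, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expr$coexpr,
                       file.path(out_dir, "coexpression_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    modules <- coexpression_modules(expr$coexpr)
    utils::write.table(modules, file.path(out_dir, "coexpr_modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n <- nrow(expr$tissue)
    summary$expression <- list(
      pct_preferred = round(100 * sum(expr$tissue$call != "none") / n, 2),
      pct_undetected = round(100 * sum(!expr$tissue$detected) / n, 2),
      pct_regulated = stats::setNames(lapply(expr$treatments, function(d)
        round(100 * sum(d$call != "none") / nrow(d), 2)),
        names(expr$treatments)),
      n_coexpressed_pairs = nrow(expr$coexpr),
      n_modules = length(unique(modules$module)))
  } else summary$expression <- "skipped"

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  logmsg("pipeline complete")
  invisible(summary)
}

run_stage <- function(name, logmsg, expr) {
  logmsg("stage %s: start", name)
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  logmsg("stage %s: done", name)
  out
}

read_if_exists <- function(path) {
  if (!file.exists(path)) return(NULL)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# All within-cluster pairs of a tandem call table.
tandem_pairs <- function(tandem) {
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(tandem) || nrow(tandem) == 0L) return(out)
  for (cl in unique(tandem$cluster_id)) {
    members <- sort(tandem$gene_id[tandem$cluster_id == cl])
    if (length(members) < 2L) next
    cmb <- utils::combn(members, 2)
    out <- rbind(out, data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                                 stringsAsFactors = FALSE))
  }
  out
}

kaks_pair_ids <- function(kaks) {
  if (nrow(kaks) == 0L) return(character(0))
  unique(paste(kaks$gene_a, kaks$gene_b, sep = "~"))
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA else mean(x)
}
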