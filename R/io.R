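# File formats. Internal gene tables are 0-based half-open; GFF3 is written
# and read 1-based inclusive, BED 0-based half-open (rtracklayer performs
# the BED shift; conversions are pinned by round-trip tests).

#' Write a simulated genome bundle to a directory
#'
#' Emits `genes.gff3` (gene + exon features; intron counts are encoded as
#' exon structure), `proteins.faa`, `cds.fna`, `elements.bed`,
#' `homolog_pairs.tsv` and `ground_truth.json`.
#'
#' @param genome A genome bundle from [simulate_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(genome$genes, file.path(dir, "genes.gff3"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(stats::setNames(genome$genes$protein,
                                            genome$genes$gene_id)),
    file.path(dir, "proteins.faa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(genome$genes$cds,
                                             genome$genes$gene_id)),
    file.path(dir, "cds.fna"))
  write_elements_bed(genome$elements, file.path(dir, "elements.bed"))
  utils::write.table(genome$homolog_pairs,
                     file.path(dir, "homolog_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(genome$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a gene table as GFF3
#'
#' One `gene` feature per gene plus `intron_count + 1` evenly split `exon`
#' features. Internal 0-based half-open coordinates become 1-based
#' inclusive.
#'
#' @param genes Gene table (`gene_id`, `chromosome`, `strand`, `start`,
#'   `end`, `intron_count`).
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  feats <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    feats[[length(feats) + 1L]] <- data.frame(
      chromosome = g$chromosome, start = g$start + 1L, end = g$end,
      strand = g$strand, type = "gene", ID = g$gene_id,
      Parent = NA_character_, stringsAsFactors = FALSE)
    ex <- exon_breaks(g$start, g$end, g$intron_count)
    for (k in seq_len(nrow(ex))) {
      feats[[length(feats) + 1L]] <- data.frame(
        chromosome = g$chromosome, start = ex$start[k] + 1L, end = ex$end[k],
        strand = g$strand, type = "exon",
        ID = sprintf("%s.exon%d", g$gene_id, k), Parent = g$gene_id,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    tab$chromosome, IRanges::IRanges(tab$start, tab$end),
    strand = tab$strand, type = tab$type, ID = tab$ID)
  parent <- as(ifelse(is.na(tab$Parent), list(character(0)),
                      as.list(tab$Parent)), "CharacterList")
  S4Vectors::mcols(gr)$Parent <- parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Split a gene span into n_introns + 1 exons separated by short introns.
exon_breaks <- function(start, end, n_introns) {
  len <- end - start
  n_ex <- n_introns + 1L
  if (n_introns == 0L)
    return(data.frame(start = start, end = end))
  intron_len <- max(10L, min(50L, (len - 20L * n_ex) %/% max(1L, n_introns)))
  ex_total <- len - n_introns * intron_len
  sizes <- rep(ex_total %/% n_ex, n_ex)
  sizes[n_ex] <- sizes[n_ex] + ex_total %% n_ex
  starts <- start + cumsum(c(0L, sizes[-n_ex] + intron_len))
  data.frame(start = starts, end = starts + sizes)
}

#' Read a GFF3 gene annotation into a gene table
#'
#' Genes come from `gene` features; `intron_count` is the number of `exon`
#' features parented on each gene minus one (0 when no exons are
#' annotated). Coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return Gene table: `gene_id`, `chromosome`, `strand`, `start`, `end`,
#'   `intron_count`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  parents <- unlist(lapply(S4Vectors::mcols(exons)$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_))
  exon_n <- table(parents)
  out <- data.frame(
    gene_id = genes$ID,
    chromosome = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = GenomicRanges::start(genes) - 1L,
    end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE)
  out$intron_count <- ifelse(out$gene_id %in% names(exon_n),
                             as.integer(exon_n[out$gene_id]) - 1L, 0L)
  rownames(out) <- NULL
  out
}

#' Write mobile-element spans as BED
#'
#' The BED name field carries `family|element_id`.
#'
#' @param elements Element table (`chromosome`, `start`, `end`, `family`,
#'   `element_id`), 0-based half-open.
#' @param path Output file.
#' @export
write_elements_bed <- function(elements, path) {
  if (nrow(elements) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    elements$chromosome,
    IRanges::IRanges(start = elements$start + 1L, end = elements$end),
    name = paste(elements$family, elements$element_id, sep = "|"))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a mobile-element BED file
#'
#' @param path BED file whose name field is `family|element_id` (a bare
#'   family label is also accepted).
#' @return Element table (`chromosome`, `start`, `end`, `family`,
#'   `element_id`), 0-based half-open.
#' @export
read_elements_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      element_id = character(0), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "bed")
  parts <- strsplit(gr$name, "|", fixed = TRUE)
  data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    family = vapply(parts, `[`, character(1), 1),
    element_id = vapply(parts, function(p)
      if (length(p) > 1L) p[2] else NA_character_, character(1)),
    stringsAsFactors = FALSE)
}

#' Read a genome bundle written by [write_genome_files()]
#'
#' @param dir Bundle directory.
#' @return A genome bundle: gene table with `protein`/`cds` columns merged
#'   from the FASTA files, `elements`, `homolog_pairs`, `ground_truth`.
#' @export
read_genome_files <- function(dir) {
  genes <- read_gff3(file.path(dir, "genes.gff3"))
  prot <- Biostrings::readAAStringSet(file.path(dir, "proteins.faa"))
  cds <- Biostrings::readDNAStringSet(file.path(dir, "cds.fna"))
  genes$protein <- as.character(prot)[genes$gene_id]
  genes$cds <- as.character(cds)[genes$gene_id]
  list(
    genes = genes,
    elements = read_elements_bed(file.path(dir, "elements.bed")),
    homolog_pairs = utils::read.delim(file.path(dir, "homolog_pairs.tsv"),
                                      stringsAsFactors = FALSE),
    ground_truth = jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                       simplifyVector = TRUE))
}

#' Write an expression matrix and its sample map as TSV
#'
#' @param mat Genes x samples numeric matrix.
#' @param sample_map Data frame (`sample`, `group`, `replicate`).
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.samples.tsv`.
#' @export
write_expression_tsv <- function(mat, sample_map, prefix) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sample_map, paste0(prefix, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param prefix Path prefix used at write time.
#' @return List: `mat` (genes x samples matrix), `sample_map`.
#' @export
read_expression_tsv <- function(prefix) {
  df <- utils::read.delim(paste0(prefix, ".tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  list(mat = mat,
       sample_map = utils::read.delim(paste0(prefix, ".samples.tsv"),
                                      stringsAsFactors = FALSE))
}
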