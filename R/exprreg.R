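# Expression classification: tissue specificity / preference and treatment
# regulation under twofold rules, and co-expression by correlation
# thresholding across datasets.

#' Classify tissue-specific and tissue-preferred expression
#'
#' A gene is *detected* in a tissue when its mean abundance there reaches
#' `detect_threshold` (default 1 FPKM). It is *specific* to the focal
#' tissue set when it is detected only there, and *preferred* when the mean
#' over the focal set is at least `fold` times the maximum over every
#' remaining tissue (inclusive at the boundary). With at least two
#' replicates per group and `test = TRUE`, preference additionally requires
#' a two-sample t-test on log2 abundance (focal samples vs the
#' highest-mean remaining tissue), BH-adjusted across genes, below
#' `p_cutoff`. Specific genes count as preferred.
#'
#' @param mat Genes x samples abundance matrix.
#' @param sample_map Data frame (`sample`, `group`) mapping columns to
#'   tissues.
#' @param focal Character vector of focal tissues applied to every gene;
#'   `NULL` uses each gene's highest-mean tissue.
#' @param detect_threshold Detection threshold (mean abundance).
#' @param fold Preference fold threshold (default 2, inclusive).
#' @param test Apply the replicate-based test when possible.
#' @param p_cutoff BH-adjusted significance threshold.
#' @return Data frame per gene: `gene`, `focal`, `call` (`specific`,
#'   `preferred`, `none`), `fold`, `detected`, `pvalue`, `padj`.
#' @export
classify_tissue <- function(mat, sample_map, focal = NULL,
                            detect_threshold = 1, fold = 2, test = TRUE,
                            p_cutoff = 0.05) {
  groups <- tissue_groups(mat, sample_map)
  tissues <- names(groups)
  if (length(tissues) < 2L) stop("need at least 2 tissues", call. = FALSE)
  if (!is.null(focal) && !all(focal %in% tissues))
    stop("focal tissues absent from the sample map", call. = FALSE)
  means <- vapply(groups, function(cols)
    rowMeans(mat[, cols, drop = FALSE]), numeric(nrow(mat)))
  if (nrow(mat) == 1L) means <- matrix(means, nrow = 1,
                                       dimnames = list(rownames(mat),
                                                       tissues))
  out <- data.frame(gene = rownames(mat), focal = NA_character_,
                    call = "none", fold = NA_real_, detected = FALSE,
                    pvalue = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    foc <- if (is.null(focal)) tissues[which.max(means[i, ])] else focal
    rest <- setdiff(tissues, foc)
    detected_in <- tissues[means[i, ] >= detect_threshold]
    out$focal[i] <- paste(foc, collapse = ",")
    out$detected[i] <- length(detected_in) > 0L
    if (!out$detected[i]) next
    focal_mean <- mean(means[i, foc])
    rest_max <- max(means[i, rest])
    out$fold[i] <- if (rest_max > 0) focal_mean / rest_max else Inf
    specific <- all(detected_in %in% foc)
    fold_ok <- focal_mean >= fold * rest_max
    if (test && fold_ok && !specific) {
      top_rest <- rest[which.max(means[i, rest])]
      fs <- mat[i, groups[[foc[which.max(means[i, foc])]]]]
      if (length(foc) > 1L)
        fs <- unlist(lapply(foc, function(t) mat[i, groups[[t]]]))
      rs <- mat[i, groups[[top_rest]]]
      if (length(fs) >= 2L && length(rs) >= 2L)
        out$pvalue[i] <- tryCatch(
          stats::t.test(log2(fs + 1), log2(rs + 1))$p.value,
          error = function(e) NA_real_)
    }
    out$call[i] <- if (specific) "specific"
      else if (fold_ok) "preferred" else "none"
  }
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  demote <- out$call == "preferred" & !is.na(out$padj) & out$padj >= p_cutoff
  out$call[demote] <- "none"
  rownames(out) <- NULL
  out
}

tissue_groups <- function(mat, sample_map) {
  missing <- setdiff(colnames(mat), sample_map$sample)
  if (length(missing) > 0L)
    stop("samples missing from the map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  split(sample_map$sample[sample_map$sample %in% colnames(mat)],
        sample_map$group[sample_map$sample %in% colnames(mat)])
}

#' Classify up- and down-regulation under a treatment
#'
#' A gene is *up*-regulated when its mean treated abundance is at least
#' `fold` times the control mean (inclusive), *down* in the mirror case,
#' and unregulated otherwise; genes below the detection threshold in both
#' groups are reported undetected. With at least two replicates per group
#' and `test = TRUE`, calls additionally require a BH-adjusted two-sample
#' t-test on log2 abundance below `p_cutoff`.
#'
#' @param mat Genes x samples abundance matrix.
#' @param sample_map Data frame (`sample`, `group`) with groups `control`
#'   and `treated` (or set `control`/`treated` explicitly).
#' @param control,treated Sample (column) names of the two groups;
#'   defaults come from `sample_map`.
#' @param fold Regulation fold threshold (default 2, inclusive).
#' @param detect_threshold Detection threshold on the group means.
#' @param test,p_cutoff As in [classify_tissue()].
#' @return Data frame per gene: `gene`, `call` (`up`, `down`, `none`),
#'   `fold` (treated/control), `detected`, `pvalue`, `padj`.
#' @export
classify_treatment <- function(mat, sample_map = NULL, control = NULL,
                               treated = NULL, fold = 2,
                               detect_threshold = 1, test = TRUE,
                               p_cutoff = 0.05) {
  if (is.null(control) || is.null(treated)) {
    if (is.null(sample_map))
      stop("either a sample map or explicit groups required", call. = FALSE)
    control <- sample_map$sample[sample_map$group == "control"]
    treated <- sample_map$sample[sample_map$group == "treated"]
  }
  if (length(control) == 0L || length(treated) == 0L)
    stop("both control and treated groups must be non-empty", call. = FALSE)
  mc <- rowMeans(mat[, control, drop = FALSE])
  mt <- rowMeans(mat[, treated, drop = FALSE])
  out <- data.frame(gene = rownames(mat),
                    call = "none",
                    fold = ifelse(mc > 0, mt / mc, Inf),
                    detected = mc >= detect_threshold | mt >= detect_threshold,
                    pvalue = NA_real_, stringsAsFactors = FALSE)
  up <- out$detected & mt >= fold * mc
  down <- out$detected & mc >= fold * mt
  out$call[up] <- "up"
  out$call[down] <- "down"
  if (test && length(control) >= 2L && length(treated) >= 2L) {
    idx <- which(up | down)
    for (i in idx) {
      out$pvalue[i] <- tryCatch(
        stats::t.test(log2(mat[i, treated] + 1),
                      log2(mat[i, control] + 1))$p.value,
        error = function(e) NA_real_)
    }
  }
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  demote <- out$call != "none" & !is.na(out$padj) & out$padj >= p_cutoff
  out$call[demote] <- "none"
  rownames(out) <- NULL
  out
}

#' Call co-expressed gene pairs across expression datasets
#'
#' Computes the Pearson correlation of every candidate gene pair in each
#' dataset. A pair is called co-expressed when `|r| >= r_threshold`
#' (inclusive) in at least `min_datasets` datasets and, by default, the
#' supporting correlations agree in sign. Datasets where either gene is
#' absent or constant are skipped for that pair.
#'
#' @param matrices List of genes x samples matrices (bare matrices or
#'   `list(mat = ...)` entries as produced by [simulate_expression()]).
#' @param focal_genes Restrict pairs to those involving at least one of
#'   these genes (`NULL`: all pairs among shared genes).
#' @param r_threshold Absolute correlation threshold (default 0.8,
#'   inclusive).
#' @param min_datasets Minimum supporting datasets (default 3).
#' @param require_sign_consistency Drop pairs whose supporting datasets
#'   disagree in sign (default TRUE).
#' @param log_transform Correlate `log2(x + 1)`-transformed abundances
#'   (default TRUE, the usual scale for co-expression on FPKM-like data;
#'   set FALSE to correlate the matrices as given).
#' @param all_pairs Return every evaluated pair with a `called` flag
#'   instead of called pairs only.
#' @return Data frame: `gene_a`, `gene_b`, `n_supporting`, `sign` (`"+"`,
#'   `"-"`, `"mixed"`), `called`; per-dataset correlations are attached as
#'   the `"correlations"` attribute (pairs x datasets matrix).
#' @export
coexpression_pairs <- function(matrices, focal_genes = NULL,
                               r_threshold = 0.8, min_datasets = 3,
                               require_sign_consistency = TRUE,
                               log_transform = TRUE,
                               all_pairs = FALSE) {
  mats <- lapply(matrices, function(m) if (is.list(m)) m$mat else m)
  if (log_transform) mats <- lapply(mats, function(m) log2(m + 1))
  if (length(mats) < min_datasets)
    stop("fewer datasets than min_datasets", call. = FALSE)
  genes <- sort(unique(unlist(lapply(mats, rownames))))
  cors <- lapply(mats, function(m) {
    g <- intersect(genes, rownames(m))
    cc <- suppressWarnings(stats::cor(t(m[g, , drop = FALSE])))
    sds <- apply(m[g, , drop = FALSE], 1, stats::sd)
    cc[sds == 0, ] <- NA
    cc[, sds == 0] <- NA
    cc
  })
  pair_idx <- utils::combn(genes, 2)
  if (!is.null(focal_genes)) {
    keep <- pair_idx[1, ] %in% focal_genes | pair_idx[2, ] %in% focal_genes
    pair_idx <- pair_idx[, keep, drop = FALSE]
  }
  n_pairs <- ncol(pair_idx)
  rmat <- matrix(NA_real_, n_pairs, length(mats))
  for (d in seq_along(cors)) {
    cc <- cors[[d]]
    ok <- pair_idx[1, ] %in% rownames(cc) & pair_idx[2, ] %in% rownames(cc)
    rmat[ok, d] <- cc[cbind(pair_idx[1, ok], pair_idx[2, ok])]
  }
  sup_pos <- rowSums(rmat >= r_threshold, na.rm = TRUE)
  sup_neg <- rowSums(rmat <= -r_threshold, na.rm = TRUE)
  n_sup <- sup_pos + sup_neg
  sign <- ifelse(sup_pos > 0 & sup_neg > 0, "mixed",
                 ifelse(sup_pos > 0, "+", ifelse(sup_neg > 0, "-", "")))
  called <- n_sup >= min_datasets
  if (require_sign_consistency) called <- called & sign != "mixed"
  out <- data.frame(gene_a = pair_idx[1, ], gene_b = pair_idx[2, ],
                    n_supporting = n_sup, sign = sign, called = called,
                    stringsAsFactors = FALSE)
  if (!all_pairs) {
    keep <- out$called
    rmat <- rmat[keep, , drop = FALSE]
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "correlations") <- rmat
  out
}

#' Co-expression modules as connected components of the called-pair graph
#'
#' @param pairs Called pairs from [coexpression_pairs()].
#' @return Data frame `gene`, `module` (module ids are arbitrary but
#'   deterministic).
#' @export
coexpression_modules <- function(pairs) {
  pairs <- pairs[pairs$called, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(gene = character(0), module = character(0),
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_edgelist(as.matrix(pairs[, c("gene_a", "gene_b")]),
                                   directed = FALSE)
  comp <- igraph::components(g)
  out <- data.frame(gene = igraph::V(g)$name,
                    module = paste0("module_", comp$membership),
                    stringsAsFactors = FALSE)
  out <- out[order(out$module, out$gene), ]
  rownames(out) <- NULL
  out
}
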