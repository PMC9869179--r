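# Metagene scoring: rank-based quantile transform and summed-quantile
# score for bulk cohorts; normalized-mean and expression-matched
# control-bin scores for single cells; dropout diagnostics.

# internal: evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Per-gene quantile transform across samples
#'
#' Replaces each requested gene's row by its rank transform
#' `(rank - 0.5) / n` across the n samples (average ranks for ties), so
#' that highly expressed genes do not dominate a summed signature score.
#' Values lie strictly in (0, 1). The transform is invariant under any
#' per-gene strictly monotone map of the input values.
#'
#' @param matrix an [expression_matrix] with at least 2 samples.
#' @param genes gene ids to transform; genes absent from the matrix are
#'   dropped with a warning.
#' @return an [expression_matrix] (`layer = "quantile"`) restricted to
#'   the requested genes.
#' @export
gene_quantiles <- function(matrix, genes) {
  if (ncol(matrix) < 2) {
    stop("gene_quantiles: need >= 2 samples (ranks undefined otherwise)")
  }
  present <- intersect(genes, rownames(matrix))
  missing <- setdiff(genes, present)
  if (length(missing) > 0) {
    warning("gene_quantiles: dropping ", length(missing),
            " gene(s) absent from matrix")
  }
  if (length(present) == 0) {
    stop("gene_quantiles: none of the requested genes are in the matrix")
  }
  sub <- unclass(matrix)[present, , drop = FALSE]
  n <- ncol(sub)
  q <- t(apply(sub, 1, function(v) (rank(v, ties.method = "average") - 0.5) / n))
  dimnames(q) <- dimnames(sub)
  expression_matrix(q, layer = "quantile")
}

#' Bulk metagene score
#'
#' Quantile-transforms the signature genes ([gene_quantiles]) and sums
#' their per-sample quantiles. When only G of the S signature genes are
#' present, the sum is rescaled by S/G so scores remain comparable
#' across datasets with different gene coverage.
#'
#' @param matrix an [expression_matrix] with at least 2 samples.
#' @param signature a [signature_set] (or character vector of gene ids).
#' @return a [score_table] (`method = "quantile_sum"`).
#' @export
score_bulk <- function(matrix, signature) {
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else as.character(signature)
  S <- length(genes)
  q <- gene_quantiles(matrix, genes)
  G <- nrow(q)
  scores <- (S / G) * colSums(unclass(q))
  hif_log("score_bulk: %d/%d signature genes over %d samples", G, S,
          ncol(matrix))
  score_table(colnames(matrix), scores, n_genes_used = G,
              method = "quantile_sum")
}

# internal: library-size normalization to log2(1 + 1e4 * c / total)
.log_normalize_cells <- function(counts) {
  totals <- colSums(counts)
  zero_cells <- totals == 0
  if (any(zero_cells)) {
    warning(sum(zero_cells), " cell(s) have zero total counts; scored 0")
    totals[zero_cells] <- 1  # avoids 0/0; the cell's values are all zero
  }
  log2(1 + sweep(counts, 2, totals, "/") * 1e4)
}

#' Single-cell metagene score
#'
#' `normalized_mean`: per-cell mean over signature genes of
#' `log2(1 + 1e4 * c / total)`. `control_bin` (default): that mean minus
#' the mean over an expression-matched control gene pool: genes are
#' binned by average normalized expression into `n_bins` equal-frequency
#' bins, and `n_controls` control genes are drawn (seeded) from the bin
#' of each signature gene.
#'
#' @param counts an [expression_matrix] with `layer = "counts"`.
#' @param signature a [signature_set] or character vector.
#' @param method `"control_bin"` (default) or `"normalized_mean"`.
#' @param n_bins number of average-expression bins.
#' @param n_controls control genes drawn per signature gene.
#' @param seed integer seed for the control draw.
#' @return a [score_table].
#' @export
score_cells <- function(counts, signature,
                        method = c("control_bin", "normalized_mean"),
                        n_bins = 24L, n_controls = 100L, seed = 1L) {
  method <- match.arg(method)
  if (matrix_layer(counts) != "counts") {
    stop("score_cells: expected a counts-layer matrix")
  }
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else as.character(signature)
  present <- intersect(genes, rownames(counts))
  if (length(present) == 0) {
    stop("score_cells: no signature gene present in matrix")
  }
  norm <- .log_normalize_cells(unclass(counts))
  sig_mean <- colMeans(norm[present, , drop = FALSE])
  if (method == "normalized_mean") {
    return(score_table(colnames(counts), sig_mean,
                       n_genes_used = length(present),
                       method = "normalized_mean"))
  }
  avg <- rowMeans(norm)
  # equal-frequency bins over all genes (Seurat-style expression matching)
  n_bins <- min(n_bins, length(unique(avg)))
  breaks <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(avg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(counts)
  controls <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, size = n_controls, replace = length(pool) < n_controls)
    }))
  })
  ctrl_mean <- colMeans(norm[controls, , drop = FALSE])
  score_table(colnames(counts), sig_mean - ctrl_mean,
              n_genes_used = length(present), method = "control_bin")
}

#' Fraction of cells with total dropout of a gene panel
#'
#' Fraction of cells in which every listed gene has zero counts. With a
#' multi-gene panel this is never larger than the dropout fraction of
#' any single member gene.
#'
#' @param counts an [expression_matrix] with `layer = "counts"`.
#' @param genes non-empty character vector of gene ids.
#' @return a single number in \[0, 1\].
#' @export
dropout_fraction <- function(counts, genes) {
  if (length(genes) == 0) stop("dropout_fraction: empty gene list")
  present <- intersect(genes, rownames(counts))
  if (length(present) < length(genes)) {
    warning("dropout_fraction: ", length(genes) - length(present),
            " gene(s) absent from matrix (counted as zero)")
  }
  if (length(present) == 0) return(1)
  sub <- unclass(counts)[present, , drop = FALSE]
  mean(colSums(sub > 0) == 0)
}
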