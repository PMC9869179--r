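#' Construct a table of genomic binding sites
#'
#' A binding-site table holds ChIP-seq peaks as 0-based, half-open
#' genomic intervals `[start, end)` together with an optional summit
#' coordinate, a non-negative read count (raw or RPKM-normalized), and an
#' isoform class label.
#'
#' @param chrom character vector of chromosome names (compared as exact
#'   strings; no "chr" normalization is applied).
#' @param start,end integer vectors; 0-based, half-open coordinates with
#'   `start >= 0` and `end > start`.
#' @param summit optional integer vector of summit coordinates with
#'   `start <= summit < end`; `NA` when no summit was called.
#' @param count numeric vector of non-negative per-peak read counts.
#' @param isoform_class character vector; one of `"HIF1"`, `"HIF2"`,
#'   `"SHARED"`, `"UNCLASSIFIED"`.
#' @return A `data.frame` of class `binding_sites` with columns `chrom`,
#'   `start`, `end`, `summit`, `count`, `isoform_class`.
#' @examples
#' binding_sites("chr1", 100, 200, summit = 150, count = 12)
#' @export
binding_sites <- function(chrom = character(), start = integer(),
                          end = integer(), summit = NA_integer_,
                          count = 0, isoform_class = "UNCLASSIFIED") {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0 || length(start) == 0 || length(end) == 0) n <- 0
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    summit = as.integer(rep_len(summit, n)),
    count = as.numeric(rep_len(count, n)),
    isoform_class = as.character(rep_len(isoform_class, n)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("binding_sites", "data.frame")
  validate_binding_sites(df)
}

#' @rdname binding_sites
#' @param x a `binding_sites` data.frame to validate.
#' @export
validate_binding_sites <- function(x) {
  req <- c("chrom", "start", "end", "summit", "count", "isoform_class")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("binding_sites: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$start < 0)) stop("binding_sites: start must be >= 0")
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    stop("binding_sites: end <= start at record ", bad[1],
         " (", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]], ")")
  }
  has_summit <- !is.na(x$summit)
  if (any(has_summit & (x$summit < x$start | x$summit >= x$end))) {
    stop("binding_sites: summit outside [start, end)")
  }
  if (any(x$count < 0)) stop("binding_sites: count must be >= 0")
  ok <- x$isoform_class %in% c("HIF1", "HIF2", "SHARED", "UNCLASSIFIED")
  if (!all(ok)) stop("binding_sites: invalid isoform_class: ",
                     paste(unique(x$isoform_class[!ok]), collapse = ", "))
  x
}

#' Construct a gene annotation table
#'
#' One canonical transcription start site (TSS) per gene; multi-TSS
#' resolution is the annotation producer's job. Coordinates are 0-based.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom character vector of chromosome names.
#' @param tss integer vector of TSS coordinates, `>= 0`.
#' @param strand character vector, `"+"` or `"-"`. Carried but unused for
#'   distance computation (distance to a TSS is strand-symmetric).
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand = "+") {
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    tss = as.integer(tss),
    strand = as.character(rep_len(strand, length(gene_id))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) {
    stop("gene_annotation: duplicated gene_id: ",
         df$gene_id[duplicated(df$gene_id)][1])
  }
  if (any(df$tss < 0)) stop("gene_annotation: tss must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene_annotation: strand must be '+' or '-'")
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Construct a differential-expression table
#'
#' Per-gene log2 fold-change and BH-adjusted p-value for one cell line or
#' condition, as produced by a DESeq2-style analysis upstream.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param log2fc finite numeric vector of log2 fold-changes.
#' @param padj numeric vector of adjusted p-values in (0, 1].
#' @return A `data.frame` of class `diffexpr_table`.
#' @export
diffexpr_table <- function(gene_id, log2fc, padj) {
  df <- data.frame(
    gene_id = as.character(gene_id),
    log2fc = as.numeric(log2fc),
    padj = as.numeric(padj),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) {
    stop("diffexpr_table: duplicated gene_id: ",
         df$gene_id[duplicated(df$gene_id)][1])
  }
  if (any(!is.finite(df$log2fc))) stop("diffexpr_table: log2fc must be finite")
  if (any(df$padj <= 0 | df$padj > 1)) {
    stop("diffexpr_table: padj must lie in (0, 1]")
  }
  class(df) <- c("diffexpr_table", "data.frame")
  df
}

#' Construct an expression matrix
#'
#' A genes x samples (or genes x cells) numeric matrix with an explicit
#' normalization state.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample or cell ids); all values must be non-negative when
#'   `layer = "counts"`.
#' @param layer one of `"counts"`, `"normalized"`, `"log_normalized"`,
#'   `"quantile"`.
#' @return The matrix with class `expr_matrix` and a `layer` attribute.
#' @export
expression_matrix <- function(values,
                              layer = c("counts", "normalized",
                                        "log_normalized", "quantile")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix: values must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("expression_matrix: duplicated gene ids")
  }
  if (anyDuplicated(colnames(values))) {
    stop("expression_matrix: duplicated sample/cell ids")
  }
  storage.mode(values) <- "double"
  if (layer == "counts" && any(values < 0)) {
    stop("expression_matrix: counts layer must be non-negative")
  }
  structure(values, layer = layer, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, layer=%s\n",
              nrow(x), ncol(x), attr(x, "layer")))
  invisible(x)
}

#' Layer of an expression matrix
#' @param x an `expr_matrix`.
#' @return the layer string, or `"normalized"` for a bare matrix.
#' @export
matrix_layer <- function(x) {
  l <- attr(x, "layer")
  if (is.null(l)) "normalized" else l
}

#' Construct a signature set
#'
#' An ordered gene list with optional per-cell-line provenance (was the
#' gene HIF-bound and hypoxia-upregulated in that line) and optional
#' published-signature membership flags.
#'
#' @param genes character vector of unique gene ids (order preserved).
#' @param provenance optional logical matrix, genes x cell lines.
#' @param published_membership optional logical matrix, genes x published
#'   signature names; `NA` marks unverified membership.
#' @param provenance_note optional free-text note on flag provenance.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(genes, provenance = NULL,
                          published_membership = NULL,
                          provenance_note = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("signature_set: genes must be unique")
  for (m in list(provenance, published_membership)) {
    if (!is.null(m) && !identical(as.character(rownames(m)), genes)) {
      stop("signature_set: matrix rownames must equal the gene list")
    }
  }
  structure(
    list(genes = genes, provenance = provenance,
         published_membership = published_membership,
         provenance_note = provenance_note),
    class = "signature_set"
  )
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d genes", length(x$genes)))
  if (!is.null(x$provenance)) {
    cat(sprintf(", provenance over %d lines", ncol(x$provenance)))
  }
  if (!is.null(x$published_membership)) {
    cat(sprintf(", membership in %d published signatures",
                ncol(x$published_membership)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.signature_set <- function(x) length(x$genes)

#' Analysis configuration
#'
#' Bundles the thresholds of the signature-derivation and screening chain.
#' Defaults follow the derivation protocol: differential expression calls
#' at adjusted p < 0.05 and fold change > 1.2; target assignment to the 3
#' closest genes; peak background filtering at the 99.99th percentile;
#' correlation screens at p <= 1e-6; pre-ranked GSEA with 10,000
#' permutations and weight 1.
#'
#' @param padj_threshold adjusted p-value cutoff for differential calls.
#' @param fc_threshold fold-change cutoff (linear scale; applied as
#'   `log2fc > log2(fc_threshold)`).
#' @param k_nearest number of closest genes assigned to each binding site.
#' @param background_percentile percentile of background counts above
#'   which peaks are retained, in (0, 100).
#' @param corr_p_threshold p-value cutoff for the correlation screen.
#' @param gsea_nperm number of GSEA permutations.
#' @param gsea_weight GSEA running-sum weight exponent.
#' @param min_lines number of cell lines a gene must hit to enter the
#'   consensus; `NULL` means "all lines" and is resolved at use.
#' @param seed integer seed for seeded operations.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(padj_threshold = 0.05, fc_threshold = 1.2,
                            k_nearest = 3L, background_percentile = 99.99,
                            corr_p_threshold = 1e-6, gsea_nperm = 10000L,
                            gsea_weight = 1.0, min_lines = NULL,
                            seed = 1L) {
  stopifnot(padj_threshold > 0, padj_threshold <= 1,
            fc_threshold > 0,
            k_nearest >= 1,
            background_percentile > 0, background_percentile < 100,
            corr_p_threshold > 0, corr_p_threshold <= 1,
            gsea_nperm >= 1, gsea_weight >= 0)
  structure(
    list(padj_threshold = padj_threshold, fc_threshold = fc_threshold,
         k_nearest = as.integer(k_nearest),
         background_percentile = background_percentile,
         corr_p_threshold = corr_p_threshold,
         gsea_nperm = as.integer(gsea_nperm), gsea_weight = gsea_weight,
         min_lines = if (is.null(min_lines)) NULL else as.integer(min_lines),
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Construct a score table
#'
#' Per-sample (or per-cell) metagene scores.
#'
#' @param ids character vector of sample or cell ids.
#' @param score numeric vector of finite scores.
#' @param n_genes_used number of signature genes found in the matrix.
#' @param method scoring method label.
#' @return A `data.frame` of class `score_table` with attributes
#'   `n_genes_used` and `method`.
#' @export
score_table <- function(ids, score, n_genes_used,
                        method = c("quantile_sum", "normalized_mean",
                                   "control_bin")) {
  method <- match.arg(method)
  if (any(!is.finite(score))) stop("score_table: scores must be finite")
  df <- data.frame(sample_id = as.character(ids), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  attr(df, "n_genes_used") <- as.integer(n_genes_used)
  attr(df, "method") <- method
  class(df) <- c("score_table", "data.frame")
  df
}

# internal: INFO-level stage logging; silenced via options(hifmeta.verbose = FALSE)
hif_log <- function(fmt, ...) {
  if (isTRUE(getOption("hifmeta.verbose", TRUE))) {
    message(sprintf(paste0("[hifmeta] ", fmt), ...))
  }
  invisible(NULL)
}
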