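#' Read binding-site intervals from a BED file
#'
#' BED semantics: tab-separated, 0-based half-open coordinates. Two
#' dialects are supported: `bed3` (chrom, start, end) and `bed5_count`
#' (chrom, start, end, name, count) in which column 5 carries the
#' per-peak read count.
#'
#' @param path path to a BED file (no header).
#' @param dialect `"bed3"` or `"bed5_count"`.
#' @return a [binding_sites] table in file order.
#' @export
read_intervals <- function(path, dialect = c("bed3", "bed5_count")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_intervals: no such file: ", path)
  ncols <- if (dialect == "bed3") 3L else 5L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(binding_sites())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncols)) {
    stop("read_intervals: line ", which(nf < ncols)[1], " has ",
         nf[nf < ncols][1], " fields, expected >= ", ncols)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("read_intervals: non-integer coordinate at line ", bad[1])
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop("read_intervals: malformed record at line ", bad[1],
         ": start >= end (", start[bad[1]], " >= ", end[bad[1]], ")")
  }
  count <- if (dialect == "bed5_count") {
    cnt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (anyNA(cnt)) {
      stop("read_intervals: non-numeric count at line ", which(is.na(cnt))[1])
    }
    cnt
  } else {
    rep(0, length(chrom))
  }
  binding_sites(chrom = chrom, start = start, end = end, count = count)
}

#' Write binding sites to a BED file
#'
#' Inverse of [read_intervals]: `bed5_count` writes chrom, start, end,
#' isoform_class (name column), count.
#'
#' @param sites a [binding_sites] table.
#' @param path output path.
#' @param dialect `"bed3"` or `"bed5_count"`.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(sites, path, dialect = c("bed3", "bed5_count")) {
  dialect <- match.arg(dialect)
  df <- if (dialect == "bed3") {
    sites[, c("chrom", "start", "end")]
  } else {
    data.frame(sites$chrom, sites$start, sites$end,
               sites$isoform_class, sites$count)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.table_schemas <- list(
  annotation = c("gene_id", "chrom", "tss", "strand"),
  diffexpr = c("gene_id", "log2fc", "padj"),
  metadata = c("sample_id"),
  scores = c("sample_id", "score")
)

#' Read a typed tabular file
#'
#' Tab-separated with a header row. Required columns per schema:
#' `annotation` (gene_id, chrom, tss, strand), `diffexpr` (gene_id,
#' log2fc, padj), `metadata` (sample_id plus free columns), `scores`
#' (sample_id, score).
#'
#' @param path path to a TSV file.
#' @param schema one of `"annotation"`, `"diffexpr"`, `"metadata"`,
#'   `"scores"`.
#' @return a typed data.frame ([gene_annotation], [diffexpr_table], plain
#'   metadata data.frame, or [score_table]).
#' @export
read_table <- function(path, schema = c("annotation", "diffexpr",
                                        "metadata", "scores")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("read_table: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- .table_schemas[[schema]]
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("read_table: schema '", schema, "' requires missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  switch(schema,
    annotation = gene_annotation(df$gene_id, df$chrom, df$tss, df$strand),
    diffexpr = diffexpr_table(df$gene_id, df$log2fc, df$padj),
    metadata = df,
    scores = {
      ngu <- if ("n_genes_used" %in% names(df)) df$n_genes_used[1] else NA_integer_
      score_table(df$sample_id, df$score, n_genes_used = ngu)
    }
  )
}

#' Write a typed tabular file
#'
#' @param x a data.frame; a `score_table` additionally writes its
#'   `n_genes_used` attribute as a column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "score_table")) {
    x <- data.frame(sample_id = x$sample_id,
                    score = sprintf("%.12g", x$score),
                    n_genes_used = attr(x, "n_genes_used"),
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' `tsv_dense`: genes in rows (first column = gene id, header row =
#' sample ids). `mtx_triplet`: MatrixMarket coordinate file with
#' companion `genes` and `barcodes` text files (one id per line); absent
#' triplet entries are zeros.
#'
#' @param path path to the matrix file.
#' @param format `"tsv_dense"` or `"mtx_triplet"`.
#' @param genes,barcodes companion id files (mtx_triplet only).
#' @param layer normalization state of the stored values.
#' @return an [expression_matrix].
#' @export
read_matrix <- function(path, format = c("tsv_dense", "mtx_triplet"),
                        genes = NULL, barcodes = NULL, layer = "normalized") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_matrix: no such file: ", path)
  if (format == "tsv_dense") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    expression_matrix(m, layer = layer)
  } else {
    if (is.null(genes) || is.null(barcodes)) {
      stop("read_matrix: mtx_triplet requires companion gene and barcode files")
    }
    mm <- Matrix::readMM(path)
    gid <- readLines(genes)
    bid <- readLines(barcodes)
    gid <- gid[nzchar(gid)]
    bid <- bid[nzchar(bid)]
    if (nrow(mm) != length(gid) || ncol(mm) != length(bid)) {
      stop("read_matrix: matrix is ", nrow(mm), "x", ncol(mm),
           " but companion lists declare ", length(gid), " genes and ",
           length(bid), " barcodes")
    }
    m <- as.matrix(mm)
    dimnames(m) <- list(gid, bid)
    expression_matrix(m, layer = layer)
  }
}

#' Write an expression matrix
#'
#' @param x an [expression_matrix].
#' @param path output path; for `mtx_triplet` the companion files are
#'   written next to it as `<path>.genes.txt` and `<path>.barcodes.txt`
#'   unless given.
#' @param format `"tsv_dense"` or `"mtx_triplet"`.
#' @param genes,barcodes companion file paths (mtx_triplet only).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv_dense", "mtx_triplet"),
                         genes = NULL, barcodes = NULL) {
  format <- match.arg(format)
  if (format == "tsv_dense") {
    df <- data.frame(gene_id = rownames(x),
                     as.data.frame(unclass(x)[, , drop = FALSE]),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(genes)) genes <- paste0(path, ".genes.txt")
    if (is.null(barcodes)) barcodes <- paste0(path, ".barcodes.txt")
    Matrix::writeMM(methods::as(Matrix::Matrix(unclass(x), sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(x), genes)
    writeLines(colnames(x), barcodes)
  }
  invisible(path)
}
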