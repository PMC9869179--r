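# Binding-site-to-gene assignment by TSS distance, and the combined
# "HIF-bound and hypoxia-upregulated" gene call.

# internal: distance anchor of a site = summit if present, else integer
# floor of the interval midpoint
.site_anchor <- function(sites) {
  anchor <- sites$summit
  mid <- (sites$start + sites$end) %/% 2L
  ifelse(is.na(anchor), mid, anchor)
}

#' Assign the k nearest genes to each binding site
#'
#' For each site, the k genes on the same chromosome with the smallest
#' absolute distance between the site anchor (summit when present,
#' otherwise the interval midpoint) and the gene TSS. Ties in distance
#' are broken by lexicographic gene id. Chromosomes with fewer than k
#' genes contribute all of them; sites on chromosomes absent from the
#' annotation are skipped with a warning.
#'
#' @param sites a [binding_sites] table.
#' @param annotation a [gene_annotation] table (non-empty).
#' @param k number of genes per site, `>= 1`.
#' @return a data.frame with columns `site` (row index into `sites`),
#'   `gene_id`, `distance` (bp, non-negative), `rank` (1 = closest).
#' @export
k_nearest_genes <- function(sites, annotation, k = 3L) {
  stopifnot(nrow(annotation) > 0, k >= 1)
  k <- as.integer(k)
  anchors <- .site_anchor(sites)
  ann_by_chrom <- split(seq_len(nrow(annotation)), annotation$chrom)
  missing_chrom <- setdiff(unique(sites$chrom), names(ann_by_chrom))
  if (length(missing_chrom) > 0) {
    warning("k_nearest_genes: skipping sites on chromosome(s) absent from ",
            "annotation: ", paste(missing_chrom, collapse = ", "))
  }
  out <- vector("list", nrow(sites))
  for (s in seq_len(nrow(sites))) {
    idx <- ann_by_chrom[[sites$chrom[s]]]
    if (is.null(idx)) next
    d <- abs(anchors[s] - annotation$tss[idx])
    ord <- order(d, annotation$gene_id[idx])
    take <- ord[seq_len(min(k, length(ord)))]
    out[[s]] <- data.frame(
      site = s,
      gene_id = annotation$gene_id[idx][take],
      distance = d[take],
      rank = seq_along(take),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(site = integer(), gene_id = character(),
                      distance = numeric(), rank = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Nearest-TSS distances and their median
#'
#' Distance of every site to its closest gene TSS, plus the median
#' (midpoint convention for even counts, i.e. `stats::median`).
#'
#' @param sites a non-empty [binding_sites] table.
#' @param annotation a [gene_annotation] table.
#' @return a list with `distances` (one per site retained) and `median`.
#' @export
tss_distances <- function(sites, annotation) {
  if (nrow(sites) == 0) stop("tss_distances: empty site list")
  nearest <- k_nearest_genes(sites, annotation, k = 1L)
  list(distances = nearest$distance, median = stats::median(nearest$distance))
}

#' Call HIF-bound, hypoxia-upregulated genes
#'
#' A gene is called when (i) it is among the `cfg$k_nearest` closest
#' genes to at least one binding site and (ii) its differential
#' expression passes `padj < cfg$padj_threshold` and
#' `log2fc > log2(cfg$fc_threshold)` (strict inequalities; upregulation
#' only). Genes absent from the DE table are treated as not upregulated,
#' with a warning.
#'
#' @param sites a [binding_sites] table (replicate-consensus,
#'   background-filtered, isoform-classified upstream).
#' @param annotation a [gene_annotation] table.
#' @param de a [diffexpr_table].
#' @param cfg an [analysis_config].
#' @return character vector of called gene ids (sorted).
#' @export
bound_upregulated <- function(sites, annotation, de,
                              cfg = analysis_config()) {
  near <- k_nearest_genes(sites, annotation, k = cfg$k_nearest)
  candidates <- unique(near$gene_id)
  not_tested <- setdiff(candidates, de$gene_id)
  if (length(not_tested) > 0) {
    warning("bound_upregulated: ", length(not_tested),
            " candidate gene(s) absent from DE table; treated as not ",
            "upregulated")
  }
  idx <- match(candidates, de$gene_id)
  pass <- !is.na(idx) &
    de$padj[idx] < cfg$padj_threshold &
    de$log2fc[idx] > log2(cfg$fc_threshold)
  out <- sort(candidates[pass])
  hif_log("bound_upregulated: %d sites, %d candidates -> %d genes",
          nrow(sites), length(candidates), length(out))
  out
}
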