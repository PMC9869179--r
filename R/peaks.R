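# Replicate consensus, background filtering and isoform classification of
# ChIP-seq peaks. Interval arithmetic is delegated to GenomicRanges;
# brute-force oracles in the test suite check the component logic.

.sites_to_gr <- function(sites) {
  # BED half-open 0-based -> IRanges closed 1-based
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end)
  )
}

#' Replicate-consensus peaks
#'
#' Two replicate peak lists are merged into consensus sites: connected
#' components of peaks overlapping by at least 1 base pair (same
#' chromosome) that contain at least one peak from each replicate. The
#' consensus interval is the union span of the component, its count the
#' mean of the member counts, and its summit the midpoint of the union.
#'
#' @param rep1,rep2 [binding_sites] tables for the two replicates.
#' @return a [binding_sites] table of consensus sites (possibly empty).
#' @export
consensus_peaks <- function(rep1, rep2) {
  rep1 <- validate_binding_sites(rep1)
  rep2 <- validate_binding_sites(rep2)
  pooled <- rbind(
    data.frame(chrom = rep1$chrom, start = rep1$start, end = rep1$end,
               count = rep1$count, rep = rep(1L, nrow(rep1)),
               stringsAsFactors = FALSE),
    data.frame(chrom = rep2$chrom, start = rep2$start, end = rep2$end,
               count = rep2$count, rep = rep(2L, nrow(rep2)),
               stringsAsFactors = FALSE)
  )
  if (nrow(pooled) == 0) return(binding_sites())
  gr <- .sites_to_gr(pooled)
  # min.gapwidth = 0: merge strictly overlapping ranges only; BED-touching
  # intervals share no base and stay separate
  comp <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, comp)
  member_of <- rep(NA_integer_, nrow(pooled))
  member_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  keep <- vapply(seq_along(comp), function(i) {
    reps <- pooled$rep[member_of == i]
    any(reps == 1L) && any(reps == 2L)
  }, logical(1))
  idx <- which(keep)
  if (length(idx) == 0) return(binding_sites())
  start0 <- GenomicRanges::start(comp)[idx] - 1L
  end0 <- GenomicRanges::end(comp)[idx]
  counts <- vapply(idx, function(i) mean(pooled$count[member_of == i]),
                   numeric(1))
  out <- binding_sites(
    chrom = as.character(GenomicRanges::seqnames(comp))[idx],
    start = start0, end = end0,
    summit = (start0 + end0) %/% 2L,
    count = counts
  )
  hif_log("consensus_peaks: %d + %d peaks -> %d consensus sites",
          nrow(rep1), nrow(rep2), nrow(out))
  out
}

#' Filter peaks against an empirical background
#'
#' Retains exactly the peaks whose count is strictly greater than the
#' given empirical percentile (linear-interpolation quantile, type 7) of
#' the background count distribution.
#'
#' @param peaks a [binding_sites] table.
#' @param background_counts non-empty numeric vector of background
#'   counts (e.g., read counts over random DNase-accessible regions).
#' @param percentile percentile in (0, 100); default 99.99.
#' @return the retained subset of `peaks`.
#' @export
filter_by_background <- function(peaks, background_counts,
                                 percentile = 99.99) {
  if (length(background_counts) == 0) {
    stop("filter_by_background: background_counts must be non-empty")
  }
  stopifnot(percentile > 0, percentile < 100)
  thr <- stats::quantile(background_counts, percentile / 100,
                         names = FALSE, type = 7)
  out <- peaks[peaks$count > thr, , drop = FALSE]
  rownames(out) <- NULL
  hif_log("filter_by_background: threshold %.4g (p%.4g) retains %d/%d peaks",
          thr, percentile, nrow(out), nrow(peaks))
  out
}

#' Classify consensus sites by HIF isoform
#'
#' HIF binds DNA as an alpha/beta heterodimer, so a site requires
#' HIF-1beta (ARNT) support. Each ARNT peak is an anchor: it yields a
#' `HIF1` site if overlapped (>= 1 bp) by an HIF-1alpha peak and by no
#' HIF-2alpha peak, `HIF2` symmetrically, and `SHARED` if overlapped by
#' both. ARNT peaks with no alpha-isoform overlap, and alpha peaks with
#' no ARNT overlap, are dropped. The output interval spans the anchor
#' and all contributing alpha peaks; its count is the mean of the
#' contributing peak counts.
#'
#' @param h1,h2,arnt [binding_sites] tables for HIF-1alpha, HIF-2alpha
#'   and HIF-1beta/ARNT, each already replicate-consensus and
#'   background-filtered.
#' @return a [binding_sites] table with `isoform_class` set and an
#'   attribute `support` (list of contributing source labels per site).
#' @export
classify_isoform <- function(h1, h2, arnt) {
  h1 <- validate_binding_sites(h1)
  h2 <- validate_binding_sites(h2)
  arnt <- validate_binding_sites(arnt)
  if (nrow(arnt) == 0) return(binding_sites())
  gr_a <- .sites_to_gr(arnt)
  ov1 <- if (nrow(h1) > 0) {
    GenomicRanges::findOverlaps(gr_a, .sites_to_gr(h1))
  } else S4Vectors::Hits(nLnode = length(gr_a), nRnode = 0L)
  ov2 <- if (nrow(h2) > 0) {
    GenomicRanges::findOverlaps(gr_a, .sites_to_gr(h2))
  } else S4Vectors::Hits(nLnode = length(gr_a), nRnode = 0L)
  h1_by_anchor <- split(S4Vectors::subjectHits(ov1),
                        factor(S4Vectors::queryHits(ov1),
                               levels = seq_len(nrow(arnt))))
  h2_by_anchor <- split(S4Vectors::subjectHits(ov2),
                        factor(S4Vectors::queryHits(ov2),
                               levels = seq_len(nrow(arnt))))
  rows <- vector("list", nrow(arnt))
  support <- vector("list", nrow(arnt))
  for (i in seq_len(nrow(arnt))) {
    i1 <- h1_by_anchor[[i]]
    i2 <- h2_by_anchor[[i]]
    if (length(i1) == 0 && length(i2) == 0) next
    cls <- if (length(i1) > 0 && length(i2) > 0) "SHARED"
           else if (length(i1) > 0) "HIF1" else "HIF2"
    starts <- c(arnt$start[i], h1$start[i1], h2$start[i2])
    ends <- c(arnt$end[i], h1$end[i1], h2$end[i2])
    counts <- c(arnt$count[i], h1$count[i1], h2$count[i2])
    s <- min(starts); e <- max(ends)
    rows[[i]] <- data.frame(
      chrom = arnt$chrom[i], start = s, end = e,
      summit = (s + e) %/% 2L, count = mean(counts),
      isoform_class = cls, stringsAsFactors = FALSE
    )
    support[[i]] <- c(paste0("arnt:", i),
                      if (length(i1)) paste0("h1:", i1),
                      if (length(i2)) paste0("h2:", i2))
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(binding_sites())
  df <- do.call(rbind, rows[keep])
  out <- binding_sites(chrom = df$chrom, start = df$start, end = df$end,
                       summit = df$summit, count = df$count,
                       isoform_class = df$isoform_class)
  attr(out, "support") <- support[keep]
  hif_log("classify_isoform: %d anchors -> %d sites (%d HIF1, %d HIF2, %d SHARED)",
          nrow(arnt), nrow(out), sum(out$isoform_class == "HIF1"),
          sum(out$isoform_class == "HIF2"),
          sum(out$isoform_class == "SHARED"))
  out
}
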