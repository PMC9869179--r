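# Overlap profiles across per-cell-line gene sets, expected counts under
# an independence null, consensus derivation, and the promoter-proximal
# vs distal TSS-distance comparison.

.pattern_key <- function(membership_row) {
  paste(as.integer(membership_row), collapse = "")
}

#' Exact-membership overlap profile across gene sets
#'
#' For L sets over a common gene universe of size N, tabulates for every
#' exact membership pattern P (subset of set labels) the observed count
#' of genes belonging to exactly the sets in P, and the expected count
#' under an independence null in which gene g belongs to set i with
#' probability |set_i|/N independently:
#' `expected(P) = N * prod_{i in P} p_i * prod_{j not in P} (1 - p_j)`.
#' Counts are also aggregated by pattern cardinality ("shared by exactly
#' m sets").
#'
#' @param sets named list of character vectors, each a subset of
#'   `universe`.
#' @param universe character vector of all genes testable in every set.
#' @return a list of class `overlap_profile` with elements `patterns`
#'   (data.frame: pattern key over set names, cardinality, observed,
#'   expected, deviation), `by_cardinality` (aggregated data.frame),
#'   `set_names`, `universe_size`.
#' @export
overlap_profile <- function(sets, universe) {
  stopifnot(length(sets) >= 1)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  universe <- unique(as.character(universe))
  N <- length(universe)
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], universe)
    if (length(extra) > 0) {
      stop("overlap_profile: set '", nm, "' contains ", length(extra),
           " gene(s) outside the universe (e.g. ", extra[1], ")")
    }
  }
  L <- length(sets)
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(N))
  if (N == 1) membership <- matrix(membership, nrow = 1)
  keys <- apply(membership, 1, .pattern_key)
  # all 2^L patterns, including the empty pattern; column j <-> set j,
  # matching the membership key order
  all_pat <- as.matrix(expand.grid(rep(list(c(0L, 1L)), L)))
  colnames(all_pat) <- names(sets)
  pat_keys <- apply(all_pat, 1, paste, collapse = "")
  obs <- table(factor(keys, levels = pat_keys))
  p_i <- vapply(sets, length, integer(1)) / N
  expected <- vapply(seq_len(nrow(all_pat)), function(r) {
    inP <- all_pat[r, ] == 1L
    N * prod(p_i[inP]) * prod(1 - p_i[!inP])
  }, numeric(1))
  patterns <- data.frame(
    pattern = pat_keys,
    cardinality = rowSums(all_pat),
    observed = as.integer(obs),
    expected = expected,
    stringsAsFactors = FALSE
  )
  patterns$deviation <- patterns$observed - patterns$expected
  by_card <- stats::aggregate(
    cbind(observed, expected) ~ cardinality, data = patterns, FUN = sum
  )
  by_card$deviation <- by_card$observed - by_card$expected
  structure(
    list(patterns = patterns, by_cardinality = by_card,
         set_names = names(sets), universe_size = N),
    class = "overlap_profile"
  )
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat(sprintf("<overlap_profile> %d sets over %d genes\n",
              length(x$set_names), x$universe_size))
  print(x$by_cardinality)
  invisible(x)
}

#' Derive a consensus signature from per-line gene sets
#'
#' Genes present in at least `min_lines` of the per-cell-line
#' HIF-bound/upregulated sets, ordered lexicographically, with per-line
#' provenance flags.
#'
#' @param sets named list of character vectors (one per cell line).
#' @param min_lines integer between 1 and `length(sets)`; defaults to
#'   all lines.
#' @return a [signature_set] with a genes x lines `provenance` matrix.
#' @export
derive_consensus <- function(sets, min_lines = length(sets)) {
  stopifnot(min_lines >= 1, min_lines <= length(sets))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("line", seq_along(sets))
  }
  all_genes <- sort(unique(unlist(sets)))
  if (length(all_genes) == 0) {
    return(signature_set(character()))
  }
  prov <- vapply(sets, function(s) all_genes %in% s,
                 logical(length(all_genes)))
  if (length(all_genes) == 1) prov <- matrix(prov, nrow = 1)
  rownames(prov) <- all_genes
  keep <- rowSums(prov) >= min_lines
  genes <- all_genes[keep]
  hif_log("derive_consensus: %d lines, min_lines=%d -> %d genes",
          length(sets), min_lines, length(genes))
  signature_set(genes, provenance = prov[keep, , drop = FALSE])
}

#' Compare TSS distances of consensus vs other target assignments
#'
#' Tests whether consensus (shared) binding sites sit closer to their
#' target TSS than line-specific sites: medians of both distance lists
#' plus a one-sided rank-sum test (consensus less than other).
#'
#' @param consensus_assignments,other_assignments data.frames with a
#'   `distance` column (as returned by [k_nearest_genes]), or bare
#'   numeric distance vectors.
#' @return a list with `median_consensus`, `median_other`, `ranksum`
#'   (a `ranksum_result`).
#' @export
compare_tss_distance <- function(consensus_assignments, other_assignments) {
  dist_of <- function(a) if (is.data.frame(a)) a$distance else as.numeric(a)
  dc <- dist_of(consensus_assignments)
  do <- dist_of(other_assignments)
  if (length(dc) == 0 || length(do) == 0) {
    stop("compare_tss_distance: both assignment lists must be non-empty")
  }
  list(
    median_consensus = stats::median(dc),
    median_other = stats::median(do),
    ranksum = ranksum_test(dc, do, alternative = "less")
  )
}
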