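#' Run the full signature-derivation chain on a panel
#'
#' For each cell line: replicate-consensus peaks per ChIP target,
#' background filtering, isoform classification (ARNT-anchored), then
#' the HIF-bound/upregulated gene call; finally the per-line sets are
#' combined into a consensus signature.
#'
#' @param panel output of [simulate_panel], or any list with the same
#'   shape (`de`, `peaks`, `annotation`, `background`).
#' @param cfg an [analysis_config]; `min_lines = NULL` means all lines.
#' @return a list with `signature` (a [signature_set]), `per_line_sets`
#'   (named list of gene-id vectors), `sites` (named list of classified
#'   [binding_sites] per line).
#' @export
derive_panel_signature <- function(panel, cfg = analysis_config()) {
  line_names <- names(panel$de)
  per_line_sets <- list()
  sites_by_line <- list()
  for (l in line_names) {
    pk <- panel$peaks[[l]]
    filtered <- lapply(pk, function(target) {
      cons <- consensus_peaks(target$rep1, target$rep2)
      filter_by_background(cons, panel$background,
                           cfg$background_percentile)
    })
    sites <- classify_isoform(filtered$h1, filtered$h2, filtered$arnt)
    sites_by_line[[l]] <- sites
    per_line_sets[[l]] <- bound_upregulated(sites, panel$annotation,
                                            panel$de[[l]], cfg)
  }
  min_lines <- if (is.null(cfg$min_lines)) length(line_names)
               else cfg$min_lines
  list(
    signature = derive_consensus(per_line_sets, min_lines = min_lines),
    per_line_sets = per_line_sets,
    sites = sites_by_line
  )
}
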