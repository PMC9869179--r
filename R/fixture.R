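#' Load a packaged gene-signature fixture
#'
#' The package ships the 48-gene conserved HIF target signature: genes
#' that were HIF-bound and hypoxia-upregulated in all six cell lines of
#' the derivation panel (lung, colorectal, breast, prostate, liver,
#' kidney).  The fixture also records, for each of 14 previously
#' published hypoxia mRNA signatures, how many of the 48 genes that
#' signature contains.  Per-gene membership flags in those published
#' signatures are stored as `NA` with provenance note
#' `"unverified_alignment"`: the membership matrix could not be
#' column-aligned reliably from the available rendering of the source
#' table, so only the per-signature totals are asserted.
#'
#' @param name fixture name; currently `"conserved48"`.
#' @return a [signature_set]. For `conserved48` the set carries a
#'   genes x 14 `published_membership` matrix (all `NA`) whose column
#'   names are the 14 published signature names, plus an attribute-level
#'   count table available via `attr(sig$published_membership,
#'   "n_members")`.
#' @examples
#' sig <- load_signature("conserved48")
#' length(sig$genes)  # 48
#' @export
load_signature <- function(name = "conserved48") {
  available <- "conserved48"
  if (!name %in% available) {
    stop("load_signature: unknown fixture '", name, "'. Available: ",
         paste(available, collapse = ", "),
         ". (The 14 published hypoxia signatures are recorded only as ",
         "membership-count metadata on 'conserved48'.)")
  }
  genes <- readLines(system.file("extdata", "conserved48_genes.txt",
                                 package = "hifmeta", mustWork = TRUE))
  genes <- genes[nzchar(genes)]
  pub <- utils::read.delim(
    system.file("extdata", "published_signatures.tsv",
                package = "hifmeta", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
  membership <- matrix(NA, nrow = length(genes), ncol = nrow(pub),
                       dimnames = list(genes, pub$signature_name))
  attr(membership, "n_members") <- stats::setNames(
    pub$n_conserved48_members, pub$signature_name
  )
  signature_set(genes, published_membership = membership,
                provenance_note = "unverified_alignment")
}
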