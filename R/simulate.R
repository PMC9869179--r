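# Seeded synthetic-data generators with planted ground truth: a
# cell-line panel (DE tables + replicate ChIP peak sets), a bulk tumor
# cohort with a latent activation level, and a sparse single-cell count
# matrix. All generators are pure functions of (config, seed).

#' Panel generator configuration
#'
#' The panel emulates the structure of the derivation experiment: a
#' consensus gene set bound and upregulated in every line with
#' promoter-proximal peaks, plus line-specific targets with distal
#' (enhancer-like) peaks, on a single fixed chromosome layout ("chr1",
#' genes spaced 50 kb apart).
#'
#' @param n_lines number of cell lines.
#' @param n_genes genes in the panel universe.
#' @param n_consensus planted consensus genes (bound + upregulated in
#'   every line).
#' @param n_specific_per_line planted line-specific target genes.
#' @param consensus_log2fc_mean,specific_log2fc_mean mean observed log2
#'   fold-change of planted genes.
#' @param log2fc_sd sd of planted log2 fold-changes.
#' @param null_log2fc_sd sd of null-gene log2 fold-changes (mean 0).
#' @param se standard error used for the two-sided z p-value of each
#'   gene's log2 fold-change.
#' @param consensus_tss_distance_sd sd (bp) of the half-normal
#'   summit-to-TSS distance of consensus peaks (promoter-proximal
#'   regime).
#' @param specific_tss_distance_mean mean (bp) of the exponential
#'   summit-to-TSS distance of line-specific peaks (distal regime).
#' @param peak_count_signal mean count of planted peaks.
#' @param peak_count_background_mean mean of the exponential background
#'   count distribution.
#' @return a list of class `panel_config`.
#' @export
panel_config <- function(n_lines = 6L, n_genes = 5000L, n_consensus = 48L,
                         n_specific_per_line = 300L,
                         consensus_log2fc_mean = 1.5,
                         specific_log2fc_mean = 1.0, log2fc_sd = 0.3,
                         null_log2fc_sd = 0.2, se = 0.15,
                         consensus_tss_distance_sd = 500L,
                         specific_tss_distance_mean = 12000L,
                         peak_count_signal = 50,
                         peak_count_background_mean = 2) {
  cfg <- list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
              n_consensus = as.integer(n_consensus),
              n_specific_per_line = as.integer(n_specific_per_line),
              consensus_log2fc_mean = consensus_log2fc_mean,
              specific_log2fc_mean = specific_log2fc_mean,
              log2fc_sd = log2fc_sd, null_log2fc_sd = null_log2fc_sd,
              se = se,
              consensus_tss_distance_sd = consensus_tss_distance_sd,
              specific_tss_distance_mean = specific_tss_distance_mean,
              peak_count_signal = peak_count_signal,
              peak_count_background_mean = peak_count_background_mean)
  with(cfg, {
    if (n_consensus + n_lines * n_specific_per_line >= n_genes) {
      stop("panel_config: infeasible gene budget: n_consensus + ",
           "n_lines * n_specific_per_line must be < n_genes")
    }
    stopifnot(consensus_log2fc_mean > 0, specific_log2fc_mean > 0,
              log2fc_sd > 0, null_log2fc_sd > 0, se > 0,
              consensus_tss_distance_sd > 0,
              specific_tss_distance_mean > 0, peak_count_signal > 0,
              peak_count_background_mean > 0)
  })
  structure(cfg, class = c("panel_config", "list"))
}

# genes every 50 kb on a single chromosome; distances, not positions,
# carry the signal
.panel_gene_spacing <- 50000L
.panel_peak_halfwidth <- 200L

# internal: one called-peak replicate = parent interval with boundaries
# jittered by +/- 25 bp, exercising the >=1 bp replicate-overlap rule
.jitter_peak <- function(start, end) {
  s <- start + sample.int(51L, length(start), replace = TRUE) - 26L
  e <- end + sample.int(51L, length(end), replace = TRUE) - 26L
  s <- pmax(0L, s)
  e <- pmax(e, s + 1L)
  list(start = s, end = e)
}

#' Simulate a cell-line panel with planted consensus targets
#'
#' For each line: a differential-expression table (observed log2
#' fold-changes with two-sided z p-values BH-adjusted across all genes
#' of the line) and duplicate peak lists for the three ChIP targets
#' (HIF-1alpha, HIF-2alpha, ARNT). Consensus genes are upregulated and
#' peaked in every line with promoter-proximal peaks (half-normal
#' summit-to-TSS distance); line-specific genes only in their own line
#' with distal peaks (exponential distance); null genes have no planted
#' peak. A background count sample (1e5 exponential draws) accompanies
#' the peaks.
#'
#' @param cfg a [panel_config].
#' @param seed integer seed.
#' @return a list with elements `de` (named list of [diffexpr_table]),
#'   `peaks` (per line: per target `h1`/`h2`/`arnt`: list of two
#'   [binding_sites] replicates), `annotation` ([gene_annotation]),
#'   `background` (numeric vector), `truth` (list: `consensus_genes`,
#'   `specific_genes` per line), `config`.
#' @export
simulate_panel <- function(cfg = panel_config(), seed = 1L) {
  with_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    tss <- seq_len(cfg$n_genes) * .panel_gene_spacing
    annotation <- gene_annotation(gene_ids, "chr1", tss, "+")
    idx <- sample.int(cfg$n_genes,
                      cfg$n_consensus + cfg$n_lines * cfg$n_specific_per_line)
    consensus_idx <- idx[seq_len(cfg$n_consensus)]
    specific_idx <- split(
      idx[-seq_len(cfg$n_consensus)],
      rep(seq_len(cfg$n_lines), each = cfg$n_specific_per_line)
    )
    line_names <- paste0("line", seq_len(cfg$n_lines))
    names(specific_idx) <- line_names

    de <- list(); peaks <- list()
    for (l in seq_len(cfg$n_lines)) {
      lfc <- stats::rnorm(cfg$n_genes, 0, cfg$null_log2fc_sd)
      lfc[consensus_idx] <- stats::rnorm(cfg$n_consensus,
                                         cfg$consensus_log2fc_mean,
                                         cfg$log2fc_sd)
      sp <- specific_idx[[l]]
      lfc[sp] <- stats::rnorm(length(sp), cfg$specific_log2fc_mean,
                              cfg$log2fc_sd)
      p <- 2 * stats::pnorm(-abs(lfc) / cfg$se)
      padj <- pmin(1, pmax(stats::p.adjust(p, "BH"), 1e-300))
      de[[line_names[l]]] <- diffexpr_table(gene_ids, lfc, padj)

      # planted peaks for this line: consensus + line-specific genes
      planted <- c(consensus_idx, sp)
      dist_c <- round(abs(stats::rnorm(cfg$n_consensus, 0,
                                       cfg$consensus_tss_distance_sd)))
      dist_s <- round(stats::rexp(length(sp),
                                  1 / cfg$specific_tss_distance_mean))
      dist <- c(dist_c, dist_s)
      side <- sample(c(-1L, 1L), length(planted), replace = TRUE)
      summit <- pmax(.panel_peak_halfwidth,
                     tss[planted] + side * as.integer(dist))
      p_start <- summit - .panel_peak_halfwidth
      p_end <- summit + .panel_peak_halfwidth
      line_peaks <- list()
      for (target in c("h1", "h2", "arnt")) {
        reps <- lapply(1:2, function(r) {
          jit <- .jitter_peak(p_start, p_end)
          binding_sites(
            chrom = "chr1", start = jit$start, end = jit$end,
            count = cfg$peak_count_signal *
              (1 + stats::rnorm(length(planted), 0, 0.1))
          )
        })
        names(reps) <- c("rep1", "rep2")
        line_peaks[[target]] <- reps
      }
      peaks[[line_names[l]]] <- line_peaks
    }
    background <- stats::rexp(1e5, 1 / cfg$peak_count_background_mean)
    truth <- list(
      consensus_genes = gene_ids[consensus_idx],
      specific_genes = lapply(specific_idx, function(i) gene_ids[i])
    )
    list(de = de, peaks = peaks, annotation = annotation,
         background = background, truth = truth, config = cfg)
  })
}

#' Cohort generator configuration
#'
#' Emulates a bulk tumor cohort: each sample carries a latent HIF
#' activation level (increased by a mutation label, e.g. VHL loss)
#' driving the signature genes and a small fraction of companion genes
#' on the log scale; values are exponentiated to an FPKM-like
#' non-negative scale.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param activation_sd sd of the latent activation.
#' @param signature_loading_mean mean loading of signature genes on the
#'   activation (half-normal, sd 0.2).
#' @param companion_fraction fraction of non-signature genes that also
#'   load on the activation.
#' @param companion_loading_mean mean loading of companion genes.
#' @param noise_sd per-gene log-scale residual sd.
#' @param mutation_fraction fraction of mutated samples.
#' @param mutation_effect additive shift of activation in mutated
#'   samples.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 2000L,
                          activation_sd = 1.0,
                          signature_loading_mean = 0.8,
                          companion_fraction = 0.05,
                          companion_loading_mean = 0.5, noise_sd = 0.5,
                          mutation_fraction = 0.3, mutation_effect = 1.0) {
  stopifnot(n_samples >= 2, n_genes >= 1, activation_sd > 0,
            companion_fraction >= 0, companion_fraction <= 1,
            mutation_fraction >= 0, mutation_fraction <= 1,
            noise_sd > 0)
  structure(
    list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
         activation_sd = activation_sd,
         signature_loading_mean = signature_loading_mean,
         companion_fraction = companion_fraction,
         companion_loading_mean = companion_loading_mean,
         noise_sd = noise_sd, mutation_fraction = mutation_fraction,
         mutation_effect = mutation_effect),
    class = c("cohort_config", "list")
  )
}

#' Simulate a bulk tumor cohort with latent HIF activation
#'
#' @param cfg a [cohort_config].
#' @param seed integer seed.
#' @param signature a [signature_set] (or character vector) marking
#'   which genes are signature genes; they are placed in the gene
#'   universe (error if more signature genes than `n_genes`).
#' @return a list with `matrix` (an [expression_matrix],
#'   `layer = "normalized"`), `metadata` (data.frame: sample_id,
#'   mutated), `truth` (list: `activation`, `mutation_labels`,
#'   `companion_genes`, `signature_genes`), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1L,
                            signature = load_signature("conserved48")) {
  sig_genes <- if (inherits(signature, "signature_set")) signature$genes
               else as.character(signature)
  if (length(sig_genes) > cfg$n_genes) {
    stop("simulate_cohort: signature larger than gene universe")
  }
  with_seed(seed, {
    n_other <- cfg$n_genes - length(sig_genes)
    gene_ids <- c(sig_genes, sprintf("CG%05d", seq_len(n_other)))
    sample_ids <- sprintf("S%04d", seq_len(cfg$n_samples))
    mutated <- stats::rbinom(cfg$n_samples, 1, cfg$mutation_fraction) == 1
    activation <- stats::rnorm(cfg$n_samples, 0, cfg$activation_sd) +
      cfg$mutation_effect * mutated
    loading <- numeric(cfg$n_genes)
    loading[seq_along(sig_genes)] <-
      abs(stats::rnorm(length(sig_genes), cfg$signature_loading_mean, 0.2))
    n_comp <- floor(cfg$companion_fraction * n_other)
    companion_pos <- if (n_comp > 0) {
      length(sig_genes) + sample.int(n_other, n_comp)
    } else integer()
    loading[companion_pos] <-
      abs(stats::rnorm(n_comp, cfg$companion_loading_mean, 0.2))
    baseline <- stats::runif(cfg$n_genes, 2, 8)
    logx <- outer(loading, activation) + baseline +
      matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, 0, cfg$noise_sd),
             cfg$n_genes, cfg$n_samples)
    values <- 2^logx
    dimnames(values) <- list(gene_ids, sample_ids)
    list(
      matrix = expression_matrix(values, layer = "normalized"),
      metadata = data.frame(sample_id = sample_ids, mutated = mutated,
                            stringsAsFactors = FALSE),
      truth = list(activation = stats::setNames(activation, sample_ids),
                   mutation_labels = stats::setNames(mutated, sample_ids),
                   companion_genes = gene_ids[companion_pos],
                   signature_genes = sig_genes),
      config = cfg
    )
  })
}

#' Single-cell generator configuration
#'
#' Emulates a sparse droplet-style count matrix: cells belong to
#' clusters with differing baseline HIF activation; counts are negative
#' binomial around library-size-scaled expected proportions, so dropout
#' zeros arise from the count model itself (no extra zero inflation).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_clusters number of cell clusters.
#' @param lib_size_mean expected total counts per cell.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param activation_by_cluster numeric vector of cluster baseline
#'   activations (length `n_clusters`); default an even grid from 0
#'   to 2.
#' @param signature_loading_mean mean loading of signature genes.
#' @return a list of class `sc_config`.
#' @export
sc_config <- function(n_cells = 2000L, n_genes = 1500L, n_clusters = 4L,
                      lib_size_mean = 5000L, nb_dispersion = 0.5,
                      activation_by_cluster = NULL,
                      signature_loading_mean = 0.8) {
  if (is.null(activation_by_cluster)) {
    activation_by_cluster <- seq(0, 2, length.out = n_clusters)
  }
  if (length(activation_by_cluster) != n_clusters) {
    stop("sc_config: activation_by_cluster must have length n_clusters")
  }
  stopifnot(nb_dispersion > 0, lib_size_mean > 0, n_cells >= 2)
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters),
         lib_size_mean = as.integer(lib_size_mean),
         nb_dispersion = nb_dispersion,
         activation_by_cluster = as.numeric(activation_by_cluster),
         signature_loading_mean = signature_loading_mean),
    class = c("sc_config", "list")
  )
}

#' Simulate a single-cell count matrix with planted activation clusters
#'
#' @param cfg an [sc_config].
#' @param seed integer seed.
#' @param signature a [signature_set] or character vector.
#' @return a list with `counts` (an [expression_matrix],
#'   `layer = "counts"`), `metadata` (data.frame: cell_id, cluster),
#'   `truth` (list: `activation` per cell, `cluster`,
#'   `signature_genes`), `config`.
#' @export
simulate_cells <- function(cfg = sc_config(), seed = 1L,
                           signature = load_signature("conserved48")) {
  sig_genes <- if (inherits(signature, "signature_set")) signature$genes
               else as.character(signature)
  if (length(sig_genes) > cfg$n_genes) {
    stop("simulate_cells: signature larger than gene universe")
  }
  with_seed(seed, {
    n_other <- cfg$n_genes - length(sig_genes)
    gene_ids <- c(sig_genes, sprintf("CG%05d", seq_len(n_other)))
    cell_ids <- sprintf("C%05d", seq_len(cfg$n_cells))
    cluster <- sample.int(cfg$n_clusters, cfg$n_cells, replace = TRUE)
    activation <- cfg$activation_by_cluster[cluster] +
      stats::rnorm(cfg$n_cells, 0, 0.3)
    loading <- numeric(cfg$n_genes)
    loading[seq_along(sig_genes)] <-
      abs(stats::rnorm(length(sig_genes), cfg$signature_loading_mean, 0.2))
    baseline <- stats::runif(cfg$n_genes, 2, 8)
    logmu <- outer(loading, activation) + baseline
    # softmax-normalized expected proportions per cell
    mu_lin <- 2^logmu
    prop <- sweep(mu_lin, 2, colSums(mu_lin), "/")
    mu <- prop * cfg$lib_size_mean
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = cfg$n_genes, ncol = cfg$n_cells,
      dimnames = list(gene_ids, cell_ids)
    )
    list(
      counts = expression_matrix(counts, layer = "counts"),
      metadata = data.frame(cell_id = cell_ids, cluster = cluster,
                            stringsAsFactors = FALSE),
      truth = list(activation = stats::setNames(activation, cell_ids),
                   cluster = stats::setNames(cluster, cell_ids),
                   signature_genes = sig_genes),
      config = cfg
    )
  })
}
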