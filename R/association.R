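# Downstream screens: per-gene correlation with the metagene, sharing
# counts across datasets, the pre-ranked GSEA ranking statistic and
# enrichment test, covariate-adjusted regression, and score comparisons
# between sample groups.

#' Correlate every gene with the metagene score
#'
#' Pearson correlation between `log2(x + 1)`-transformed expression
#' (quantile-layer matrices are correlated as-is) and the per-sample
#' score, for every gene not in `exclude` (typically the signature genes
#' themselves). Two-sided p-values come from the t statistic with n - 2
#' degrees of freedom. Genes with zero variance are flagged undefined
#' and excluded from significance counting.
#'
#' @param matrix an [expression_matrix] whose columns match
#'   `scores$sample_id`.
#' @param scores a [score_table].
#' @param exclude character vector of gene ids to skip.
#' @return a data.frame with columns `gene_id`, `r`, `p_value`, `n`,
#'   `direction` (`"positive"`/`"negative"`), `defined` (FALSE for
#'   zero-variance genes, whose `r` and `p_value` are `NA`).
#' @export
correlate_with_score <- function(matrix, scores, exclude = character()) {
  if (!setequal(colnames(matrix), scores$sample_id) ||
      ncol(matrix) != nrow(scores)) {
    stop("correlate_with_score: matrix samples do not match score ids")
  }
  n <- ncol(matrix)
  if (n < 3) stop("correlate_with_score: need n >= 3 samples")
  s <- scores$score[match(colnames(matrix), scores$sample_id)]
  keep <- setdiff(rownames(matrix), exclude)
  x <- unclass(matrix)[keep, , drop = FALSE]
  if (matrix_layer(matrix) != "quantile") x <- log2(x + 1)
  # vectorized Pearson r of each row against s
  xc <- x - rowMeans(x)
  sc <- s - mean(s)
  denom_x <- sqrt(rowSums(xc^2))
  denom_s <- sqrt(sum(sc^2))
  defined <- denom_x > 0 & denom_s > 0
  r <- rep(NA_real_, length(keep))
  r[defined] <- (xc %*% sc)[defined] / (denom_x[defined] * denom_s)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(
    gene_id = keep, r = r, p_value = p, n = n,
    direction = ifelse(r >= 0, "positive", "negative"),
    defined = defined, stringsAsFactors = FALSE
  )
  out$p_value[!defined] <- NA_real_
  out$direction[!defined] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Count genes shared across dataset-level correlation screens
#'
#' For each gene and direction, counts the datasets in which that gene
#' passed `p <= p_threshold` with that direction, then tabulates how
#' many genes reach at least m datasets, for every m. A gene positive in
#' some datasets and negative in others is counted once per direction,
#' never pooled.
#'
#' @param per_dataset_records list of data.frames from
#'   [correlate_with_score].
#' @param p_threshold significance cutoff (default 1e-6).
#' @return a data.frame with columns `direction`, `min_datasets`,
#'   `n_genes`.
#' @export
sharing_counts <- function(per_dataset_records, p_threshold = 1e-6) {
  stopifnot(length(per_dataset_records) >= 1)
  tally <- list(positive = list(), negative = list())
  for (rec in per_dataset_records) {
    sig <- rec[!is.na(rec$p_value) & rec$p_value <= p_threshold, ,
               drop = FALSE]
    for (dir in c("positive", "negative")) {
      g <- sig$gene_id[sig$direction == dir]
      for (gene in g) {
        tally[[dir]][[gene]] <- (tally[[dir]][[gene]] %||% 0L) + 1L
      }
    }
  }
  max_m <- length(per_dataset_records)
  rows <- list()
  for (dir in c("positive", "negative")) {
    counts <- unlist(tally[[dir]])
    for (m in seq_len(max_m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        direction = dir, min_datasets = m,
        n_genes = if (is.null(counts)) 0L else sum(counts >= m),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ranking statistic for pre-ranked GSEA
#'
#' Scores each gene as `pi = log2fc * (-log10 padj)` (adjusted p floored
#' at 1e-300 before the log) and returns genes sorted by `pi`
#' descending, ties broken lexicographically by gene id.
#'
#' @param de a [diffexpr_table].
#' @return a data.frame with columns `gene_id`, `score`, sorted.
#' @export
rank_score <- function(de) {
  p <- pmax(de$padj, 1e-300)
  pi_score <- de$log2fc * (-log10(p))
  ord <- order(-pi_score, de$gene_id)
  data.frame(gene_id = de$gene_id[ord], score = pi_score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

# internal: weighted running-sum enrichment score over a ranked list
.gsea_es <- function(scores, is_hit, weight) {
  N <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight
  hit_mass <- sum(w[is_hit])
  if (hit_mass == 0) {
    # degenerate: all hit scores are zero; fall back to equal increments
    inc <- ifelse(is_hit, 1 / nh, -1 / (N - nh))
  } else {
    inc <- ifelse(is_hit, w / hit_mass, -1 / (N - nh))
  }
  run <- cumsum(inc)
  i <- which.max(abs(run))
  run[i]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov-style running sum over a ranked gene
#' list: hits increment by `|score|^weight / sum(|score_hits|^weight)`,
#' misses decrement by `1/(N - |S|)`; the enrichment score (ES) is the
#' signed maximum deviation. The null distribution is built from
#' `n_perm` random gene sets of equal size (gene-label permutation,
#' seeded); `p = (1 + #{|ES_null| >= |ES|}) / (n_perm + 1)` and
#' `NES = ES / mean(|ES_null|)` over null ES values of the same sign as
#' the observed ES.
#'
#' @param ranked data.frame from [rank_score] (columns `gene_id`,
#'   `score`, already sorted).
#' @param gene_set character vector; must intersect the ranked genes.
#' @param weight running-sum weight exponent (default 1).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return a list of class `enrichment_result` with `es`, `nes`,
#'   `p_value`, `n_perm`, `seed`, `n_hits`.
#' @export
preranked_gsea <- function(ranked, gene_set, weight = 1, n_perm = 10000L,
                           seed = 1L) {
  stopifnot(n_perm >= 1)
  is_hit <- ranked$gene_id %in% gene_set
  nh <- sum(is_hit)
  N <- nrow(ranked)
  if (nh == 0) stop("preranked_gsea: gene_set does not intersect ranked list")
  if (nh == N) stop("preranked_gsea: gene_set covers the whole ranked list")
  es <- .gsea_es(ranked$score, is_hit, weight)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hits <- logical(N)
      hits[sample.int(N, nh)] <- TRUE
      .gsea_es(ranked$score, hits, weight)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  structure(
    list(es = es, nes = nes, p_value = p, n_perm = as.integer(n_perm),
         seed = as.integer(seed), n_hits = nh),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d hits, %d perms)\n",
              x$es, x$nes, x$p_value, x$n_hits, x$n_perm))
  invisible(x)
}

#' Covariate-adjusted gene-score association
#'
#' Least-squares regression of a gene's values on the metagene score
#' plus covariates (with intercept); returns the score coefficient and
#' its two-sided t-test p-value. With no covariates this reduces to the
#' simple-regression p of the Pearson correlation.
#'
#' @param gene_values numeric response vector.
#' @param scores numeric metagene scores, same length.
#' @param covariates numeric matrix of covariate columns (may have zero
#'   columns); must be full rank jointly with the score and intercept.
#' @return a list with `coefficient`, `p_value`, `se`.
#' @export
adjusted_association <- function(gene_values, scores,
                                 covariates = matrix(0, length(scores), 0)) {
  covariates <- as.matrix(covariates)
  n <- length(gene_values)
  stopifnot(length(scores) == n, nrow(covariates) == n)
  if (n <= ncol(covariates) + 2) {
    stop("adjusted_association: need n > n_covariates + 2")
  }
  X <- cbind(score = scores, covariates)
  fit <- stats::lm(gene_values ~ X)
  if (any(is.na(stats::coef(fit)))) {
    stop("adjusted_association: rank-deficient design")
  }
  # row 1 is the intercept; the score column is always first in X
  sm <- summary(fit)$coefficients
  list(coefficient = sm[2, "Estimate"],
       p_value = sm[2, "Pr(>|t|)"],
       se = sm[2, "Std. Error"])
}

#' Compare metagene scores between two groups
#'
#' Medians of the two groups and a two-sided Wilcoxon rank-sum test.
#'
#' @param scores a [score_table].
#' @param labels character vector of group labels, parallel to
#'   `scores$sample_id` (or named by sample id).
#' @param contrast character vector of two group names to compare.
#' @return a list of class `group_comparison` with `group_labels`,
#'   `medians` (named), `ranksum`.
#' @export
compare_groups <- function(scores, labels, contrast) {
  stopifnot(length(contrast) == 2)
  if (!is.null(names(labels))) {
    labels <- labels[scores$sample_id]
  }
  stopifnot(length(labels) == nrow(scores))
  missing_grp <- setdiff(contrast, unique(labels))
  if (length(missing_grp) > 0) {
    stop("compare_groups: unknown or empty group(s): ",
         paste(missing_grp, collapse = ", "))
  }
  a <- scores$score[labels == contrast[1]]
  b <- scores$score[labels == contrast[2]]
  structure(
    list(group_labels = contrast,
         medians = stats::setNames(c(stats::median(a), stats::median(b)),
                                   contrast),
         ranksum = ranksum_test(a, b, alternative = "two_sided")),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s median %.4g vs %s median %.4g; ",
              x$group_labels[1], x$medians[1],
              x$group_labels[2], x$medians[2]))
  print(x$ranksum)
  invisible(x)
}
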