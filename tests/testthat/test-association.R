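cohort_fixture <- function(seed = 1, n = 30, g = 25) {
  set.seed(seed)
  v <- matrix(2^rnorm(g * n, 6, 1), g, n,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(n))))
  v
}

test_that("correlate_with_score recovers exact linear relations and flags constants", {
  v <- cohort_fixture()
  scores <- score_table(colnames(v), seq_len(ncol(v)), n_genes_used = 5L)
  # plant a gene whose log2(x+1) is exactly linear in the score
  v["g1", ] <- 2^(0.5 * scores$score + 1) - 1
  v["g2", ] <- 7  # constant
  rec <- correlate_with_score(expression_matrix(v, "normalized"), scores)
  expect_equal(rec$r[rec$gene_id == "g1"], 1, tolerance = 1e-12)
  g2 <- rec[rec$gene_id == "g2", ]
  expect_false(g2$defined)
  expect_true(is.na(g2$p_value))

  # signature genes are excluded on request
  rec2 <- correlate_with_score(expression_matrix(v, "normalized"), scores,
                               exclude = c("g1", "g2"))
  expect_false(any(c("g1", "g2") %in% rec2$gene_id))

  # affine rescaling of the score leaves r unchanged
  resc <- score_table(scores$sample_id, 3 * scores$score - 10,
                      n_genes_used = 5L)
  rec3 <- correlate_with_score(expression_matrix(v, "normalized"), resc)
  expect_equal(rec$r, rec3$r, tolerance = 1e-12)

  bad <- score_table(paste0("x", seq_len(ncol(v))), seq_len(ncol(v)),
                     n_genes_used = 5L)
  expect_error(correlate_with_score(expression_matrix(v, "normalized"), bad),
               "match")
})

test_that("sharing_counts separates directions and matches the tally oracle", {
  rec1 <- data.frame(gene_id = c("A", "B", "C"), r = c(0.9, 0.8, -0.9),
                     p_value = c(1e-9, 1e-8, 1e-9), n = 100,
                     direction = c("positive", "positive", "negative"),
                     defined = TRUE)
  out1 <- sharing_counts(list(rec1), p_threshold = 1e-6)
  expect_equal(out1$n_genes[out1$direction == "positive" &
                              out1$min_datasets == 1], 2)

  # a gene positive in one dataset, negative in another is never pooled
  rec2 <- rec1
  rec2$direction <- c("negative", "positive", "negative")
  out2 <- sharing_counts(list(rec1, rec2), 1e-6)
  expect_equal(out2$n_genes[out2$direction == "positive" &
                              out2$min_datasets == 2], 1)  # only B
  expect_equal(out2$n_genes[out2$direction == "negative" &
                              out2$min_datasets == 2], 1)  # only C

  set.seed(88)
  recs <- lapply(1:5, function(i) {
    data.frame(gene_id = paste0("g", 1:40),
               r = runif(40, -1, 1),
               p_value = 10^runif(40, -9, 0), n = 100,
               direction = sample(c("positive", "negative"), 40, TRUE),
               defined = TRUE)
  })
  got <- sharing_counts(recs, 1e-3)
  oracle <- oracle_sharing(recs, 1e-3)
  expect_equal(got$n_genes, oracle$n_genes)
})

test_that("rank_score computes log2fc * -log10(padj) with deterministic ordering", {
  de <- diffexpr_table(c("a", "b", "c", "d"),
                       c(2, -1, 5, 0.5), c(0.001, 0.01, 1, 0.01))
  rk <- rank_score(de)
  expect_equal(rk$score[rk$gene_id == "a"], 6)
  expect_equal(rk$score[rk$gene_id == "b"], -2)
  expect_equal(rk$score[rk$gene_id == "c"], 0)  # padj = 1
  expect_equal(rk$gene_id[1], "a")
  expect_true(!is.unsorted(rev(rk$score)))

  # ties broken lexicographically
  de2 <- diffexpr_table(c("zz", "aa"), c(1, 1), c(0.1, 0.1))
  expect_equal(rank_score(de2)$gene_id, c("aa", "zz"))

  # padj floor keeps the statistic finite
  de3 <- diffexpr_table("x", 1, 1e-320)
  expect_true(is.finite(rank_score(de3)$score))
  expect_equal(rank_score(de3)$score, 300)
})

test_that("adjusted_association reduces to simple regression and recovers effects", {
  set.seed(66)
  n <- 80
  score <- rnorm(n)
  gene <- 0.7 * score + rnorm(n, 0, 0.5)
  # equivalence with the correlation t-test when there are no covariates:
  # feed the screen a matrix whose log2(x+1) transform equals `gene`
  gene_pos <- gene - min(gene)
  fit <- adjusted_association(gene_pos, score)
  v <- rbind(g1 = 2^gene_pos - 1, other = runif(n))
  colnames(v) <- paste0("s", 1:n)
  rec <- correlate_with_score(
    expression_matrix(v, "normalized"),
    score_table(paste0("s", 1:n), score, n_genes_used = 1L)
  )
  expect_equal(fit$p_value, rec$p_value[rec$gene_id == "g1"],
               tolerance = 1e-9)

  # planted confound: gene = score + 2*covariate + noise
  covar <- rnorm(n)
  gene2 <- score + 2 * covar + rnorm(n, 0, 0.3)
  fit2 <- adjusted_association(gene2, score, cbind(covar))
  expect_lt(abs(fit2$coefficient - 1), 3 * fit2$se)

  # gene identical to covariate, score independent: coefficient ~ 0
  fit3 <- suppressWarnings(adjusted_association(covar, score, cbind(covar)))
  expect_lt(abs(fit3$coefficient), 1e-10)

  expect_error(adjusted_association(gene, score, cbind(score)),
               "rank-deficient")
  expect_error(adjusted_association(1:3, 1:3, matrix(rnorm(9), 3, 3)),
               "n >")
})

test_that("compare_groups reports medians and the rank-sum comparison", {
  sc <- score_table(paste0("s", 1:4), c(1, 4, 2, 3), n_genes_used = 2L)
  labels <- c("a", "a", "b", "b")
  res <- compare_groups(sc, labels, c("a", "b"))
  expect_equal(unname(res$medians), c(2.5, 2.5))
  expect_equal(res$ranksum$p_value, 1)
  expect_equal(res$ranksum$method, "exact")

  expect_error(compare_groups(sc, labels, c("a", "nope")), "unknown")

  # named labels are matched by sample id
  named <- setNames(labels, sc$sample_id)
  res2 <- compare_groups(sc, named[c(4, 3, 2, 1)], c("a", "b"))
  expect_equal(res2$medians, res$medians)
})
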