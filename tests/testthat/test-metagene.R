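make_expr <- function(vals, layer = "normalized") {
  expression_matrix(vals, layer = layer)
}

test_that("gene_quantiles is the (rank - 0.5)/n transform with average ties", {
  v <- rbind(g1 = c(5, 1, 9), g2 = c(7, 7, 7))
  colnames(v) <- paste0("s", 1:3)
  q <- gene_quantiles(make_expr(v), c("g1", "g2"))
  expect_equal(unname(unclass(q)["g1", ]), c(0.5, 1 / 6, 5 / 6))
  expect_equal(unname(unclass(q)["g2", ]), rep(0.5, 3))
  expect_equal(matrix_layer(q), "quantile")
  expect_true(all(unclass(q) > 0 & unclass(q) < 1))

  # rank invariance under strictly monotone per-gene maps
  q2 <- gene_quantiles(make_expr(exp(v)), c("g1", "g2"))
  expect_equal(unclass(q), unclass(q2))

  one_col <- make_expr(matrix(1, 1, 1, dimnames = list("g1", "s1")))
  expect_error(gene_quantiles(one_col, "g1"), ">= 2 samples")
  expect_warning(gene_quantiles(make_expr(v), c("g1", "nope")), "dropping")
  expect_error(suppressWarnings(gene_quantiles(make_expr(v), "nope")),
               "none of")
})

test_that("score_bulk sums quantiles and rescales for missing genes", {
  v <- rbind(g1 = c(5, 1, 9), g2 = c(9, 5, 1))
  colnames(v) <- paste0("s", 1:3)
  sc <- score_bulk(make_expr(v), c("g1", "g2"))
  expect_equal(sc$score, c(0.5 + 5 / 6, 1 / 6 + 0.5, 5 / 6 + 1 / 6))
  expect_equal(sc$score, c(4 / 3, 2 / 3, 1))
  expect_equal(attr(sc, "n_genes_used"), 2L)
  expect_equal(attr(sc, "method"), "quantile_sum")

  # S/G rescaling: requesting a 3-gene signature of which 2 are present
  sc3 <- suppressWarnings(score_bulk(make_expr(v), c("g1", "g2", "g3")))
  expect_equal(sc3$score, (3 / 2) * sc$score)
  expect_equal(attr(sc3, "n_genes_used"), 2L)

  # permutation equivariance over samples
  perm <- c(3, 1, 2)
  scp <- score_bulk(make_expr(v[, perm]), c("g1", "g2"))
  expect_equal(scp$score, sc$score[perm])
  expect_equal(scp$sample_id, sc$sample_id[perm])

  expect_error(suppressWarnings(score_bulk(make_expr(v), c("x", "y"))),
               "none of")
})

test_that("score_bulk is exactly invariant under per-gene monotone transforms", {
  set.seed(9)
  v <- matrix(rexp(20 * 12, 0.1), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  sig <- paste0("g", 1:8)
  base <- score_bulk(make_expr(v), sig)
  transforms <- list(function(x) x^3, exp, function(x) 5 * x + 2, sqrt,
                     function(x) log1p(x) - 100)
  for (f in transforms) {
    w <- t(apply(v, 1, f))
    dimnames(w) <- dimnames(v)
    expect_identical(score_bulk(make_expr(w), sig)$score, base$score)
  }
})

test_that("adding a duplicate sample preserves per-gene quantile orderings", {
  # The summed score is cohort-relative: appending a duplicate sample
  # rescales each gene's quantiles monotonically, so per-gene orderings
  # of the prior samples are preserved exactly (the sum of differently
  # deformed ranks can reorder near-tied totals, which is inherent to
  # rank-based scoring and not asserted).
  set.seed(77)
  v <- matrix(runif(10 * 8), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  sig <- paste0("g", 1:5)
  q0 <- gene_quantiles(make_expr(v), sig)
  v2 <- cbind(v, s_dup = v[, 3])
  q1 <- gene_quantiles(make_expr(v2), sig)
  for (g in sig) {
    expect_equal(order(unclass(q0)[g, ]),
                 order(unclass(q1)[g, 1:8]))
  }
  # and scores of prior samples remain tightly rank-correlated
  sc0 <- score_bulk(make_expr(v), sig)
  sc1 <- score_bulk(make_expr(v2), sig)
  expect_gt(cor(sc0$score, sc1$score[1:8], method = "spearman"), 0.9)
})

test_that("score_cells normalized mean and control-bin behave as specified", {
  set.seed(101)
  counts <- matrix(rpois(50 * 40, 4), 50, 40,
                   dimnames = list(paste0("g", 1:50), paste0("c", 1:40)))
  counts[, 1] <- 0  # an all-zero cell
  em <- expression_matrix(counts, layer = "counts")

  expect_warning(sc <- score_cells(em, paste0("g", 1:10),
                                   method = "normalized_mean"),
                 "zero total")
  expect_equal(sc$score[1], 0)
  expect_equal(nrow(sc), 40)  # cell retained

  # signature = all genes: controls come from the same pool, mean ~ 0
  em2 <- expression_matrix(counts[, -1], layer = "counts")
  sc_all <- score_cells(em2, paste0("g", 1:50), method = "control_bin",
                        seed = 5)
  expect_lt(abs(mean(sc_all$score)), 0.05)

  # seeded determinism
  a <- score_cells(em2, paste0("g", 1:10), seed = 42)
  b <- score_cells(em2, paste0("g", 1:10), seed = 42)
  expect_identical(a$score, b$score)

  expect_error(score_cells(em2, "nope"), "no signature gene")
  norm_layer <- expression_matrix(counts[, -1], layer = "normalized")
  expect_error(score_cells(norm_layer, "g1"), "counts-layer")
})

test_that("dropout_fraction counts cells with zero counts across the panel", {
  z <- matrix(0, 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  em0 <- expression_matrix(z, layer = "counts")
  expect_equal(dropout_fraction(em0, paste0("g", 1:3)), 1)

  o <- z; o[1, ] <- 1
  expect_equal(dropout_fraction(expression_matrix(o, layer = "counts"),
                                paste0("g", 1:3)), 0)
  expect_error(dropout_fraction(em0, character()), "empty")

  # panel dropout never exceeds any single-gene dropout
  set.seed(23)
  counts <- matrix(rbinom(30 * 50, 1, 0.1), 30, 50,
                   dimnames = list(paste0("g", 1:30), paste0("c", 1:50)))
  em <- expression_matrix(counts, layer = "counts")
  panel <- paste0("g", 1:10)
  singles <- vapply(panel, function(g) dropout_fraction(em, g), numeric(1))
  expect_lte(dropout_fraction(em, panel), min(singles))
})
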