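test_that("generators are pure functions of (config, seed)", {
  cfg <- small_panel_cfg()
  a <- simulate_panel(cfg, seed = 5)
  b <- simulate_panel(cfg, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_panel(cfg, seed = 6)
  expect_false(identical(a$de, c2$de))

  sig <- paste0("SG", 1:10)
  co_cfg <- cohort_config(n_samples = 40, n_genes = 100)
  expect_identical(simulate_cohort(co_cfg, 3, sig),
                   simulate_cohort(co_cfg, 3, sig))
  sc_cfg <- sc_config(n_cells = 50, n_genes = 60)
  expect_identical(simulate_cells(sc_cfg, 3, sig),
                   simulate_cells(sc_cfg, 3, sig))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_panel(small_panel_cfg(), seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("panel truth has the declared structure", {
  cfg <- small_panel_cfg()
  sim <- simulate_panel(cfg, seed = 2)
  expect_length(sim$truth$consensus_genes, cfg$n_consensus)
  expect_length(sim$truth$specific_genes, cfg$n_lines)
  # planted sets are pairwise disjoint
  all_specific <- unlist(sim$truth$specific_genes)
  expect_equal(anyDuplicated(all_specific), 0)
  expect_length(intersect(sim$truth$consensus_genes, all_specific), 0)
  # replicate peak lists exist for all three ChIP targets
  expect_setequal(names(sim$peaks[[1]]), c("h1", "h2", "arnt"))
  expect_length(sim$background, 1e5)

  expect_error(panel_config(n_genes = 100, n_consensus = 50,
                            n_lines = 6, n_specific_per_line = 20),
               "infeasible")
})

test_that("planted consensus genes pass the DE thresholds in every line", {
  cfg <- panel_config()
  sim <- simulate_panel(cfg, seed = 10)
  for (de in sim$de) {
    idx <- match(sim$truth$consensus_genes, de$gene_id)
    frac <- mean(de$padj[idx] < 0.05 & de$log2fc[idx] > log2(1.2))
    expect_gte(frac, 0.95)
  }
})

test_that("DE pass fraction is monotone in the planted effect size", {
  grid <- c(0.5, 1.0, 1.5)
  frac <- sapply(grid, function(mu) {
    mean(sapply(1:20, function(s) {
      cfg <- panel_config(n_lines = 2, n_genes = 300, n_consensus = 20,
                          n_specific_per_line = 10,
                          consensus_log2fc_mean = mu)
      sim <- simulate_panel(cfg, seed = s)
      de <- sim$de[[1]]
      idx <- match(sim$truth$consensus_genes, de$gene_id)
      mean(de$padj[idx] < 0.05 & de$log2fc[idx] > log2(1.2))
    }))
  })
  expect_true(all(diff(frac) >= -0.02))  # monotone in expectation
})

test_that("cohort activation carries the mutation effect", {
  sig <- paste0("SG", 1:12)
  cfg <- cohort_config(n_samples = 400, n_genes = 60)
  sim <- simulate_cohort(cfg, seed = 8, signature = sig)
  act <- sim$truth$activation
  mut <- sim$truth$mutation_labels
  d <- mean(act[mut]) - mean(act[!mut])
  se <- sqrt(var(act[mut]) / sum(mut) + var(act[!mut]) / sum(!mut))
  expect_lt(abs(d - cfg$mutation_effect), 2 * se)

  # with mutation_effect = 0 the group distributions coincide in law
  ks_p <- sapply(1:50, function(s) {
    sim0 <- simulate_cohort(cohort_config(n_samples = 120, n_genes = 15,
                                          mutation_effect = 0),
                            seed = s, signature = paste0("SG", 1:5))
    a <- sim0$truth$activation[sim0$truth$mutation_labels]
    b <- sim0$truth$activation[!sim0$truth$mutation_labels]
    suppressWarnings(ks.test(a, b)$p.value)
  })
  # p-values should look uniform, not concentrated near 0
  expect_gt(suppressWarnings(ks.test(ks_p, "punif")$p.value), 0.01)

  expect_error(simulate_cohort(cohort_config(n_genes = 5), 1,
                               paste0("SG", 1:10)),
               "larger than")
})

test_that("single-cell counts respect library size and planted clusters", {
  sig <- paste0("SG", 1:15)
  cfg <- sc_config(n_cells = 400, n_genes = 200)
  sim <- simulate_cells(cfg, seed = 6, signature = sig)
  totals <- colSums(sim$counts)
  expect_lt(abs(mean(totals) - cfg$lib_size_mean) / cfg$lib_size_mean, 0.05)

  # highest-activation cluster expresses more signature counts
  cl <- sim$metadata$cluster
  sig_counts <- colSums(unclass(sim$counts)[sig, ])
  hi <- sig_counts[cl == which.max(cfg$activation_by_cluster)]
  lo <- sig_counts[cl == which.min(cfg$activation_by_cluster)]
  expect_lt(ranksum_test(hi, lo, "greater")$p_value, 0.01)

  expect_error(sc_config(n_clusters = 3, activation_by_cluster = c(0, 1)),
               "length")
})
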