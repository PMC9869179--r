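# Shared helpers: random-instance generators and independent brute-force
# oracles used by the unit and acceptance suites. Oracles are written
# naively (all pairs, explicit loops) and never share code with the
# implementation paths they check.

options(hifmeta.verbose = FALSE)

rand_sites <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                       max_width = 400) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  binding_sites(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    count = round(stats::runif(n, 0, 100), 4)
  )
}

# 0-based half-open overlap (>= 1 shared base)
.bed_overlap <- function(s1, e1, c1, s2, e2, c2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# O(n^2) connected-component consensus: pool both replicates, build the
# full all-pairs overlap adjacency matrix, BFS the components, keep
# components containing both replicates
oracle_consensus <- function(rep1, rep2) {
  pooled <- rbind(
    data.frame(chrom = rep1$chrom, start = rep1$start, end = rep1$end,
               count = rep1$count, rep = rep(1L, nrow(rep1))),
    data.frame(chrom = rep2$chrom, start = rep2$start, end = rep2$end,
               count = rep2$count, rep = rep(2L, nrow(rep2)))
  )
  n <- nrow(pooled)
  if (n == 0) return(binding_sites())
  adj <- outer(pooled$chrom, pooled$chrom, "==") &
    outer(pooled$start, pooled$end, "<") &
    outer(pooled$end, pooled$start, ">")
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier) > 0) {
      nxt <- which(is.na(comp) & colSums(adj[frontier, , drop = FALSE]) > 0)
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  rows <- lapply(seq_len(cid), function(cc) {
    members <- pooled[comp == cc, ]
    if (!(any(members$rep == 1L) && any(members$rep == 2L))) return(NULL)
    s <- min(members$start); e <- max(members$end)
    data.frame(chrom = members$chrom[1], start = s, end = e,
               count = mean(members$count))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(binding_sites())
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start), ]
  binding_sites(chrom = df$chrom, start = df$start, end = df$end,
                summit = (df$start + df$end) %/% 2L, count = df$count)
}

# all-pairs k-nearest-gene oracle via the full site x gene distance
# matrix (off-chromosome pairs masked to Inf)
oracle_knn <- function(sites, annotation, k) {
  anchor <- ifelse(is.na(sites$summit),
                   (sites$start + sites$end) %/% 2L, sites$summit)
  D <- abs(outer(anchor, annotation$tss, "-"))
  D[outer(sites$chrom, annotation$chrom, "!=")] <- Inf
  out <- list()
  for (s in seq_len(nrow(sites))) {
    ord <- order(D[s, ], annotation$gene_id)
    ord <- ord[is.finite(D[s, ord])]
    if (length(ord) == 0) next
    take <- utils::head(ord, k)
    out[[length(out) + 1]] <- data.frame(
      site = s, gene_id = annotation$gene_id[take],
      distance = as.integer(D[s, take]), rank = seq_along(take)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# all-pairs isoform classification oracle, anchored on arnt peaks
oracle_classify <- function(h1, h2, arnt) {
  out <- character(nrow(arnt))
  for (a in seq_len(nrow(arnt))) {
    ov1 <- any(.bed_overlap(h1$start, h1$end, h1$chrom,
                            arnt$start[a], arnt$end[a], arnt$chrom[a]))
    ov2 <- any(.bed_overlap(h2$start, h2$end, h2$chrom,
                            arnt$start[a], arnt$end[a], arnt$chrom[a]))
    out[a] <- if (ov1 && ov2) "SHARED" else if (ov1) "HIF1"
              else if (ov2) "HIF2" else "DROPPED"
  }
  out
}

# literal GSEA running-sum re-implementation (explicit loop)
oracle_gsea_es <- function(scores, is_hit, weight) {
  N <- length(scores)
  denom <- 0
  for (i in which(is_hit)) denom <- denom + abs(scores[i])^weight
  miss_dec <- 1 / (N - sum(is_hit))
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- if (is_hit[i]) run + abs(scores[i])^weight / denom
           else run - miss_dec
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# per-gene tally oracle for sharing counts
oracle_sharing <- function(records, p_threshold) {
  genes <- unique(unlist(lapply(records, `[[`, "gene_id")))
  rows <- list()
  for (dir in c("positive", "negative")) {
    hits_per_gene <- sapply(genes, function(g) {
      sum(vapply(records, function(rec) {
        row <- rec[rec$gene_id == g, ]
        nrow(row) == 1 && !is.na(row$p_value) &&
          row$p_value <= p_threshold && row$direction == dir
      }, logical(1)))
    })
    for (m in seq_along(records)) {
      rows[[length(rows) + 1]] <- data.frame(
        direction = dir, min_datasets = m,
        n_genes = sum(hits_per_gene >= m)
      )
    }
  }
  do.call(rbind, rows)
}

# sorted comparison of two binding-site tables on coordinates + count
expect_same_sites <- function(a, b, tol = 1e-9) {
  ord <- function(x) x[order(x$chrom, x$start, x$end), ]
  a <- ord(a); b <- ord(b)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$chrom, b$chrom)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_equal(a$count, b$count, tolerance = tol)
}

# small panel config keeping unit tests fast
small_panel_cfg <- function(...) {
  panel_config(n_lines = 3L, n_genes = 400L, n_consensus = 10L,
               n_specific_per_line = 20L, ...)
}
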