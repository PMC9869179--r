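# hifmeta

Derives a consensus HIF (hypoxia-inducible factor) target-gene signature
from replicated ChIP-seq peak lists combined with differential-expression
tables, scores HIF-pathway activation in bulk and single-cell expression
matrices with a quantile-normalized metagene, and runs the downstream
association screens (per-gene correlation with the metagene, cross-dataset
sharing counts, pre-ranked GSEA, covariate-adjusted regression, group
comparisons).

It is written for computational biologists who want a tested,
self-contained implementation of the "bound AND upregulated, in every
line" strategy for pinning down direct HIF targets, and of the rank-based
metagene used to read HIF activation out of heterogeneous cohorts —
including ccRCC, where VHL loss makes HIF constitutively active and
transcription-only hypoxia signatures notoriously misrank tumors.

## The method in brief

For each cell line, replicated peaks for HIF-1&alpha;, HIF-2&alpha; and
HIF-1&beta;/ARNT are merged (&ge;1 bp replicate overlap), filtered against
the 99.99th percentile of a background count distribution, and classified
by isoform against ARNT anchors. A gene is a direct target candidate in a
line when it is one of the 3 closest genes to a binding site *and* is
hypoxia-upregulated (adjusted p &lt; 0.05, fold change &gt; 1.2). Genes
called in all lines form the consensus signature; the package ships the
48-gene conserved signature (ADM ... ZNF395) as a fixture.

The bulk metagene score of sample s is

score(s) = (S/G) &Sigma;<sub>g</sub> (rank<sub>g</sub>(s) &minus; 0.5)/n,

the sum over available signature genes of each gene's rank-quantile
across the n samples of the cohort — exactly invariant to any per-gene
monotone normalization, and rescaled by S/G when only G of the S
signature genes are measured. Single cells are scored by the mean
log-normalized signature expression minus an expression-matched control
pool (Seurat-style control bins).

All generators, screens and statistics are seeded and deterministic; a
synthetic-data module plants known consensus genes, activation levels and
clusters so the full chain is testable offline.

## Worked example

```r
library(hifmeta)

sig <- load_signature("conserved48")
sig
#> <signature_set> 48 genes, membership in 14 published signatures
head(sig$genes, 6)
#> ADM AK4 ALDOA ANGPTL4 ANKRD37 BHLHE40

# a small synthetic panel: 3 lines, 12 planted consensus genes
cfg <- panel_config(n_lines = 3, n_genes = 600, n_consensus = 12,
                    n_specific_per_line = 40)
panel <- simulate_panel(cfg, seed = 11)
res <- derive_panel_signature(panel)
res$signature
#> <signature_set> 12 genes, provenance over 3 lines
mean(panel$truth$consensus_genes %in% res$signature$genes)
#> [1] 1    # every planted consensus gene recovered

# score a synthetic tumor cohort and test the mutation contrast
co <- simulate_cohort(cohort_config(n_samples = 120, n_genes = 500),
                      seed = 11, signature = sig)
sc <- score_bulk(co$matrix, sig)
cor(sc$score, co$truth$activation[sc$sample_id], method = "spearman")
#> [1] 0.995    # score tracks the planted activation
compare_groups(sc, ifelse(co$metadata$mutated, "mutated", "wildtype"),
               c("mutated", "wildtype"))
#> mutated median 34.99 vs wildtype median 21.39;
#> rank-sum U = 1729, p = 1.025e-05 (normal_approx)
```

The recovered sensitivity of 1 means the chain (replicate consensus
&rarr; background filter &rarr; isoform classification &rarr; k-nearest
target call &rarr; all-lines intersection) found every planted consensus
gene; the Spearman correlation of 0.995 and the rank-sum p of 1e-05 show
the metagene recovering the latent activation and the planted mutation
effect in the cohort.

A command-line interface mirrors the API (`exec/hifmeta`): `hifmeta
simulate panel|cohort|cells`, `hifmeta peaks consensus`, `hifmeta targets
assign`, `hifmeta signature derive|overlap`, `hifmeta score bulk|cells`,
`hifmeta screen correlate|gsea`, `hifmeta compare groups`.

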