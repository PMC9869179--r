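---
title: "Methods: consensus HIF signatures and metagene scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus HIF signatures and metagene scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hypoxia-inducible factor (HIF) is the master transcriptional regulator of
the cellular response to low oxygen. It binds DNA as a heterodimer of a
regulated alpha subunit (HIF-1&alpha; or HIF-2&alpha;) with the
constitutive beta subunit HIF-1&beta;/ARNT. HIF target repertoires are
strongly cell-type specific, so hypoxia signatures derived from one
lineage often fail to transfer — most notoriously in clear cell renal
cell carcinoma, where VHL loss makes HIF constitutively active yet many
published hypoxia signatures score the tumors mid-range. The remedy
implemented here is to intersect *direct* evidence of HIF binding
(replicated ChIP-seq for both alpha subunits and ARNT) with hypoxic
upregulation across a panel of cell lines, keep only genes supported in
every line, and summarize the resulting conserved gene set as a single
rank-based "metagene" score per sample or cell.

`hifmeta` implements that chain end to end: peak-level consensus and
filtering, peak-to-gene assignment, cross-line overlap statistics and
consensus derivation, bulk and single-cell metagene scoring, and the
downstream association screens. Every stage is exercisable on seeded
synthetic data with planted ground truth, so the whole pipeline is
testable without any external download.

## Deriving the consensus signature

**Replicate consensus.** Peaks from two replicates are merged when they
overlap by at least one base (same chromosome, BED half-open
semantics — touching intervals share no base and are kept separate). A
consensus site is a connected component of overlapping peaks that
contains at least one peak from each replicate; its interval is the
union span of the component, its count the mean of member counts, and
its summit the midpoint of the union. The union (rather than the
intersection) is used so that the full candidate regulatory region is
retained for distance measurement; counts are averaged rather than
summed so that replicate sequencing depth does not leak into the
background filter.

**Background filter.** Sites are kept only if their count *strictly
exceeds* the 99.99th percentile (linear-interpolation quantile, type 7)
of an empirical background count distribution, e.g. read counts over
random DNase-accessible regions. The filter is applied to the consensus
site's mean count; whether the original analysis filtered per replicate
or after pooling is not recoverable, and this choice is ours.

**Isoform classification.** Because HIF binds as an alpha/beta dimer,
ARNT peaks anchor the classification: an anchor overlapped only by
HIF-1&alpha; is `HIF1`, only by HIF-2&alpha; is `HIF2`, by both is
`SHARED`; anchors with no alpha support, and alpha peaks with no ARNT
support, are dropped.

**Target assignment.** Each site is assigned its k nearest genes
(default k = 3) by absolute distance between the site anchor (summit if
present, otherwise the interval midpoint) and a single canonical TSS
per gene. Ties break lexicographically by gene id so results are
deterministic. Strand is carried but unused — distance to a point TSS
is strand-symmetric.

**Bound-and-upregulated call.** A gene is called in a line when it is
among the k nearest genes of at least one site *and* its differential
expression passes adjusted p < 0.05 and fold change > 1.2 (applied as
`log2fc > log2(1.2)`, strictly; upregulation only). The consensus
signature is the set of genes called in at least `min_lines` lines
(default: all of them), ordered lexicographically.

**Overlap statistics.** The cross-line overlap profile tabulates genes
by exact membership pattern. The "expected" count for a pattern P uses
an independence null with per-set inclusion probability |set_i|/N:

expected(P) = N &prod;<sub>i&in;P</sub> p<sub>i</sub>
&prod;<sub>j&notin;P</sub> (1 &minus; p<sub>j</sub>).

This is the minimal null — it conditions on set sizes only in
expectation. A fixed-size (hypergeometric-style) null would differ at
order 1/N; the Monte-Carlo oracle in the test suite draws independent
Bernoulli memberships, for which the product formula is exact.

## The metagene score

**Bulk.** "Quantile normalization" is implemented as the per-gene rank
transform q = (rank &minus; 0.5)/n across the n samples of a cohort
(average ranks for ties), so each gene contributes on the same (0, 1)
scale and highly expressed genes cannot dominate. The score of a sample
is the sum of its signature-gene quantiles, rescaled by S/G when only G
of the S signature genes are present so scores remain comparable across
datasets with different gene coverage. Consequences worth knowing:

* the score is **exactly** invariant under any per-gene strictly
  monotone transformation of the input — normalization choices upstream
  (FPKM vs TPM vs log) cannot change it;
* scores are cohort-relative. Comparing scores across cohorts requires
  joint ranking; the CLI refuses silent merges;
* appending samples deforms each gene's rank scale slightly
  differently, so *summed* scores of previous samples can swap when
  nearly tied (per-gene orderings are preserved exactly). This is
  inherent to rank-based scoring, and is why the package tests per-gene
  order preservation rather than total-order stability.

**Single cell.** Counts are library-normalized to
log2(1 + 10<sup>4</sup>·c/total). The default `control_bin` score is
the mean over signature genes minus the mean over an
expression-matched control pool (genes binned into 24 equal-frequency
bins of average expression; 100 control genes drawn per signature gene,
seeded) — the standard module-score construction for sparse data. The
plain `normalized_mean` is retained for transparency. The exact formula
used in the original analysis is unstated; neither method claims to be
it. Cells with zero total counts score 0 with a warning and are
retained. `dropout_fraction` reports the fraction of cells with zero
counts across an entire panel; with a 48-gene panel this is bounded
above by the dropout of its best-detected member gene, which is the
formal reason a multi-gene score is assignable to nearly all cells.

## Association screens

* **Correlation screen:** Pearson r between log2(x+1)-transformed
  expression and the score for every gene outside the signature;
  two-sided p from the t statistic with n &minus; 2 df; zero-variance
  genes are flagged undefined. Significance uses the fixed threshold
  p &le; 10<sup>&minus;6</sup> (no FDR), matching the original screen's
  multiplicity handling. Sharing counts tally genes by direction and by
  the number of datasets reaching that threshold, never pooling
  directions.
* **Ranking statistic:** &pi; = log2FC &times;
  (&minus;log<sub>10</sub> p<sub>adj</sub>), with p floored at
  10<sup>&minus;300</sup>. The source formula's symbols are garbled
  between &phi; and u; we read both as the signed log2 fold-change.
* **Pre-ranked GSEA:** weighted running sum (hit increments
  |score|<sup>w</sup> normalized over hits, miss decrement 1/(N&minus;|S|)),
  ES = signed maximum deviation. The null permutes gene-set membership
  (equal-size random sets), the standard convention for pre-ranked
  input; p = (1 + #{|ES&prime;| &ge; |ES|})/(n<sub>perm</sub> + 1) is
  never zero, and NES divides by the mean |ES&prime;| of the same sign.
* **Rank-sum test:** exact enumeration of the permutation null when
  n + m &le; 12 with no ties; otherwise normal approximation with tie
  and continuity corrections. The method used is recorded in the
  result.
* **Adjusted association:** ordinary least squares of gene on score
  plus covariates, reporting the score coefficient and its t-test p;
  with no covariates this is algebraically the correlation test.

## The synthetic world

The generators state fixed experimental conditions; they are not tuned
to tests.

**Panel** (`panel_config`): 6 lines, 5,000 genes on one chromosome
spaced 50 kb apart, 48 consensus genes and 300 line-specific genes per
line. Consensus genes get log2FC ~ N(1.5, 0.3) in every line,
line-specific genes N(1.0, 0.3) in their line only, null genes
N(0, 0.2); p-values are two-sided z with SE 0.15, BH-adjusted per line
(matching per-dataset adjustment of a DESeq2-style analysis). DE tables
are simulated directly rather than via read counts because model
fitting is upstream of this package's scope. Planted peaks appear in
both replicates of all three ChIP targets with count 50·(1 + N(0, 0.1))
against an Exponential(mean 2) background (10<sup>5</sup> draws);
replicate boundaries are jittered ±25 bp so the 1-bp overlap rule is
exercised nontrivially. Summit-to-TSS distances follow two regimes:
half-normal with sd 500 bp for consensus genes (promoter-proximal) and
exponential with mean 12,000 bp for specific genes (enhancer-like),
emulating the observed contrast between a few-hundred-bp median for
shared targets and a ~12-kb median for cell-type-specific ones.

**Cohort** (`cohort_config`): 300 samples, 2,000 genes. A latent
activation a ~ N(0, 1) plus +1 for the 30% mutated samples drives
signature genes with loadings |N(0.8, 0.2)| and a 5% companion fraction
with loadings |N(0.5, 0.2)| on the log2 scale (baselines Uniform(2, 8),
noise sd 0.5), then values are exponentiated to an FPKM-like scale. The
global-null configuration for type-I calibration sets the companion
fraction to 0: every screened gene is then independent of the latent
activation (signature genes are excluded from the screen by contract).

**Single cell** (`sc_config`): 2,000 cells, 1,500 genes, 4 clusters
with baseline activations on an even grid from 0 to 2 (no default was
stated; an even grid spanning the cohort's typical activation range is
the natural choice and gives adjacent-cluster gaps well above the
within-cluster sd of 0.3). Per-cell activation adds N(0, 0.3); expected
proportions are the softmax of the log-scale means; counts are negative
binomial with mean lib_size · proportion (lib size fixed at 5,000 —
totals still vary through the count noise) and dispersion 0.5, so
zeros arise from the count model with no added zero inflation. Not
emulated: batch effects, doublets, ambient RNA, realistic read-level
noise — a green test establishes recovery under the stated model, not
robustness to artifacts the model omits.

## Numerical choices and edge cases

* Coordinates are 0-based half-open throughout; an interval [a, a+1)
  has length 1; chromosome names compare as exact strings.
* Quantiles use R's default type-7 linear interpolation; the background
  filter is a strict inequality ("above the percentile").
* Medians use the midpoint convention for even counts.
* Degenerate inputs fail loudly: empty backgrounds, single-sample
  matrices (ranks undefined), empty gene lists, rank-deficient designs,
  unknown fixture or group names. Empty peak lists flow through the
  peak chain and yield empty output.
* All seeded operations (generators, control-bin draws, GSEA
  permutations) run in a temporary RNG scope and restore the caller's
  stream.

## Known limitations

* The packaged fixture's per-gene membership flags in the 14 published
  hypoxia signatures are `NA`: the published membership matrix could
  not be column-aligned reliably from the available rendering of the
  source table, so only per-signature member counts are recorded
  (provenance note `"unverified_alignment"`).
* One canonical TSS per gene; multi-TSS genes must be resolved by the
  annotation producer.
* Peak calling, read alignment, DE model fitting, motif analysis, and
  pathway enrichment are out of scope; the package consumes their
  outputs.
* Bulk scores are cohort-relative by construction (see above); they are
  not comparable across separately ranked cohorts.
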