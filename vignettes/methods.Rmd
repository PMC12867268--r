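---
title: "Methods: gene-environment association with summary-statistics TWAS and chemical set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-environment association with summary-statistics TWAS and chemical set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtwas)
```

## What the package computes

`chemtwas` chains four analyses that together relate genes and environmental
chemicals to a complex trait:

1. **Summary-statistics TWAS.** For each gene, eQTL weights $w$ trained on a
   cis window around the transcription start site are combined with GWAS
   Z-scores $Z$ and an LD reference correlation matrix $L$ into the
   association statistic
   $$Z_{\mathrm{TWAS}} = \frac{w^\top Z}{\sqrt{w^\top L\, w}}.$$
   Under the null, $Z \sim \mathcal{N}(0, L)$ marginally, so the denominator
   standardizes the weighted sum to unit variance and
   $Z_{\mathrm{TWAS}} \sim \mathcal{N}(0,1)$. Two-sided normal p-values are
   adjusted by Benjamini-Hochberg both within tissue (`q_tissue`) and pooled
   across tissues (`q_pooled`); per-tissue counting and pooled headline
   significance answer slightly different questions, so both columns are
   always emitted.

2. **Differential expression.** A two-group Welch $t$-test per gene on a
   log2-scale matrix, with a gene called differentially expressed when
   `adj_p < 0.05` **and** `|log2FC| > 0.5`, both strict inequalities. The
   fold-change convention is fixed as case minus control.

3. **Chemical gene-set enrichment (CGSEA).** Genes are ranked by a signed
   TWAS score (by default the Z from the tissue with the smallest p-value),
   and each chemical's interacting-gene set is tested with a weighted
   Kolmogorov-Smirnov running sum: hits advance the sum by
   $|s_i|^p / \sum_{\mathrm{hits}} |s_j|^p$, misses retreat it by
   $1/(N - N_{\mathrm{hit}})$, and the enrichment score (ES) is the extreme
   deviation. A gene-label permutation null (membership resampled at the
   same set size) yields $p_{\mathrm{perm}} = (1 + \#\{|ES_\pi| \ge
   |ES|\})/(n_{\mathrm{perm}} + 1)$ — never exactly zero — and a normalized
   enrichment score $NES = ES / \overline{|ES_\pi|}$ over same-sign
   permutations. A chemical is significant when $p_{\mathrm{perm}} < 0.05$,
   BH FDR $< 0.05$ and $|NES| > 1$ simultaneously.

4. **Network post-processing.** A protein-interaction graph is built from a
   weighted edge list at an inclusive confidence cutoff of 0.4 and analyzed
   unweighted thereafter: Degree, Maximal Clique Centrality
   ($MCC(v) = \sum_{C \ni v} (|C|-1)!$ over maximal cliques of size at least
   2) and Edge Percolated Component (mean co-component size under random
   edge deletion at probability 0.5) rank hubs; MCODE (vertex weighting by
   the k-core density of closed neighborhoods, seeded growth at node score
   cutoff 0.2, haircut, 2-core filter, maximum depth 100) extracts dense
   modules scored by density times size.

A hypergeometric over-representation test (`ora()`) is provided for
user-supplied gene-set files; the universe defaults to all genes scored by
the calling stage and is always explicit in the output.

## Form of the association statistic

The TWAS statistic is sometimes written with the quadratic form
$w^\top L w$ in the denominator without a square root. As written that
quantity has variance units and the ratio is not standard normal; the
implementation uses the square-root form above so that the null reference
distribution is $\mathcal{N}(0,1)$ and two-sided normal p-values are valid.
The package treats this as the only defensible reading and applies it
throughout.

## Feature clustering

For joint interpretation, genes with $p \le 0.05$ are clustered by the
correlation of their predicted expressions,
$r_{ij} = w_i^\top L w_j / \sqrt{(w_i^\top L w_i)(w_j^\top L w_j)}$ on a
shared SNP frame with zero padding. Pairs with $|r| > 0.9$ are redundant and
merged by transitive closure; a singleton whose correlation with every other
included feature is below $0.008$ is independent. A singleton that is
correlated above that floor with some feature but never above the merge
threshold is labelled *joint*: it cannot be treated as independent evidence,
but the package deliberately does not refit a joint model, so membership
stays with the singleton and the label is a flag for downstream care.
Representatives are the smallest-p member, with lexicographic tie-breaks so
output is deterministic. A 100-kb segment identifier is carried as metadata
(`segment_id = TSS %/% 100000`) for positional grouping; it plays no role in
the clustering itself.

## The synthetic-data generator

Every analysis stage is exercised against generated data with a known
ground truth, so recovery can be measured exactly.

* **LD** is block-diagonal with AR(1) blocks, $corr(i,j) = \rho^{|i-j|}$
  (default 20 blocks of 50 SNPs, $\rho = 0.6$) — AR(1) blocks are positive
  definite by construction and a reasonable stand-in for local LD decay.
* **Weights**: each gene draws `snps_per_gene` SNPs (default 5) from its
  block; weights are standard normal scaled so $w^\top L w = 1$, i.e. unit
  predicted-expression variance, the scale on which effect recovery is
  checkable. Tissues share a gene's SNPs; per-tissue weights add Gaussian
  jitter (SD 0.2) and are re-normalized, giving realistically correlated but
  non-identical cross-tissue predictors.
* **GWAS Z**: multivariate normal with covariance $L$ and mean
  $\mu = \sum_g \alpha_g L w_g / \sqrt{w_g^\top L w_g}$ over planted causal
  genes, where $w_g$ is the gene's tissue-independent base weight vector.
  This makes the causal gene's own TWAS Z have expectation exactly
  $\alpha_g$; effects are defined directly on the standardized gene
  statistic scale, not on a phenotypic scale. The default plants 10 causal
  genes at $\alpha = 6$, a strong but not degenerate signal.
* **Chemical sets**: 100 sets of 10-50 genes; 5 active chemicals draw 80% of
  their members from the causal genes (capped by the size of the causal
  pool, since membership is sampled without replacement), the rest
  uniformly.
* **Expression**: Gaussian on the log2 scale (baseline $\mathcal{N}(7,1)$
  per gene, noise SD 0.5, 10 samples per group, 20 planted fold changes of
  $\pm 2$), matching the plain two-sample test in the differential
  expression stage rather than a count model.
* **PPI**: two planted cliques (sizes 6 and 4) over background edge
  probability 0.02, confidence scores uniform on $[0.4, 1]$. Cliques make
  module recovery exactly checkable; planted density is a generator
  parameter when partial recovery is of interest.

Sub-seeds are derived by hashing a generator label with the master seed
(`derive_seed()`), so adding a generator never perturbs the random streams
of existing ones, and every generator is a pure function of its
configuration.

What the generator does **not** emulate: real allele-frequency spectra,
imputation noise, long-range LD, count-based RNA-seq noise, batch structure,
or scale-free PPI topology. Passing recovery tests therefore demonstrates
the correctness and calibration of the statistics, not robustness to those
real-data complications.

## Study conditions used by the checks

The packaged checks run at desk scale, sized so the full suite completes in
minutes while keeping Monte-Carlo error well below the tested margins:

* Null calibration: 500 genes on 50 AR(1) blocks of 50 SNPs, $\rho = 0.6$;
  the fraction of $p < 0.05$ must fall in $[0.03, 0.07]$ and the p-value
  ECDF must pass a KS uniformity test at $\alpha = 0.01$.
* Effect recovery: 10 genes at $\alpha = 6$ among 190 null genes, 20
  replicates. This scenario places **one gene per LD block**: genes sharing
  a block with a causal gene have correlated predicted expression and are
  expected to reach significance (the usual co-regulation caveat of TWAS),
  so a meaningful false-discovery measurement requires LD-independent null
  genes.
* CGSEA recovery: 5 active chemicals among 100 (active fraction 0.8 over 20
  causal genes, set sizes 10-25 so the without-replacement cap does not
  bite, 1000 permutations); all five must be flagged with at most one false
  flag, and an all-null configuration must flag at most 5% of chemicals.
* Graph oracles: brute-force clique enumeration on random graphs with up to
  10 nodes; EPC of a single edge against its closed form 0.5; MCODE on a
  5-clique with a pendant vertex (the pendant is removed by the haircut and
  the module scores exactly $1.0 \times 5$); planted 6- and 4-cliques over
  background 0.02 recovered at Jaccard $\ge 0.8$ across 10 seeds.

## Numerical choices

* p-values are floored at the smallest positive double before BH so the
  adjustment's domain requirement ($p > 0$) holds even for effectively-zero
  tails.
* ES tie rule: when the maximal positive and negative running-sum deviations
  tie in magnitude, the positive one is reported. Rank ties in the gene
  ranking, representative selection, MCODE seed order and output ordering
  are all broken lexicographically, so every result table is deterministic.
* The permutation null of the CGSEA depends only on the set size, so
  `run_cgsea()` generates one null ES sample per distinct retained size and
  shares it across chemicals; `permutation_null()` remains available per
  set. NES magnitudes under this convention are typically in $[1, 3]$;
  published chemical-set NES values on other normalizations are not
  comparable in scale.
* EPC uses 1,000 iterations by default (adjustable) — the Monte-Carlo
  standard error is far below the differences that affect hub ranking at
  that size.
* Zero within-group variance with equal means yields $p = 1$ by convention;
  zero variance with different means is treated as deterministic separation.
* Harmonization matches alleles by exact labels, flipping the weight sign
  for swapped (ref, alt) pairs and dropping incompatible SNPs with a count;
  no strand flipping is attempted, which avoids silent sign errors for
  strand-ambiguous SNPs at the cost of assuming co-stranded inputs.

## Known limitations

* The differential expression stage uses an unmoderated Welch test; with
  very few samples a moderated variance estimator would be more powerful.
* `cluster_features` labels joint features but does not refit a joint or
  conditional model.
* The MCODE *fluff* stage is not implemented (off in common practice); the
  haircut stage is.
* Weight training (e.g. Bayesian sparse linear mixed models) is out of
  scope: weight panels are inputs, and the generator produces them directly.
* Chemical classification (drug / nutrient / pollutant classes) is curation,
  not computation, and is not attempted.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 1),
                       out_dir = "chemtwas_demo")
res <- run_all(cfg)
head(res$twas[order(res$twas$p), ])
subset(res$cgsea, significant)
res$recovery
```
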