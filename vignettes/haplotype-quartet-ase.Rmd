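---
title: "Haplotype-quartet ASE and tissue enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-quartet ASE and tissue enrichment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrASE)
```

# The analysis problem

In an autotetraploid genome assembled to haplotype resolution, every locus
is present as four homologous copies, one per haplotype (A–D, named by the
trailing letter of the chromosome identifier, `chr1a` … `chr7d`). With
gene models annotated separately on each haplotype, RNA-Seq read counts can
be compared *among the four copies of the same gene*: this is
allele-specific expression (ASE) at the haplotype level. The package
answers three questions:

1. **Is expression balanced across the four copies, or does one allele
   dominate?** (allelic bias, dominance classes)
2. **Do the haplotype ratios shift between control and stress conditions,
   and does the top-expressing copy change?** (chi-square contrast,
   rank switching, Δ effect sizes)
3. **Which genes are enriched in particular tissues, and which respond to
   stress?** (negative-binomial LRT atlas and two-group DE)

# Quartet construction

Genes are grouped into orthogroups across the four haplotypes treated as
pseudo-species. Only **1:1:1:1 quartets** — orthogroups with exactly one
gene on each haplotype — enter ASE analysis (`select_quartets()`), because
only there is the four-way comparison unambiguous. `classify_retention()`
summarizes the full table as tetra-/tri-/bi-/mono-allelic, either strictly
(no within-haplotype duplicates tolerated) or leniently (duplicates
tolerated, classes by number of haplotypes represented).

Quartets must then pass read-support filters (`filter_quartets()`), all
four per contrast: ≥ 50 reads in total across the four genes, ≥ 20 reads
per condition, ≥ 10 reads per gene, and ≥ 2 replicates per condition with
detectable quartet-level expression. Two points were genuinely open and are
settled as follows:

* *Per-gene scope.* The ≥ 10-reads-per-gene rule is applied to each gene's
  total over all samples of the contrast (`per_gene_scope = "overall"`),
  paralleling the other per-entity totals; a per-condition variant is
  available (`"per-condition"`).
* *Detectability.* A replicate is "detectable" when the quartet-level sum
  reaches `detect_count` (default 1 read) — the weakest defensible
  definition, configurable upward.

Filters are evaluated separately for each contrast, so a quartet may
qualify for one stress comparison and not another.

# ASE statistics

Within a condition, replicates are **pooled (summed)** and each haplotype's
share of the quartet total gives the proportion vector
$p = (p_A, p_B, p_C, p_D)$, $\sum_h p_h = 1$. Pooling matches the
chi-square test on read counts; a replicate-mean alternative
(`proportion-mode mean`) would weight shallow replicates equally and is
deliberately not the default.

* **Bias** is $\max_h p_h - \min_h p_h$; classes: balanced (< 0.25), mild
  (0.25 ≤ bias ≤ 0.5), strong (> 0.5). The boundaries are deliberately
  asymmetric: strong dominance requires bias *strictly above* 0.5, so a
  bias of exactly 0.5 (and exactly 0.25) is mild.
* **Chi-square contrast.** The 2 × 4 table of pooled counts
  (conditions × haplotypes) is tested for independence with Pearson's
  statistic, no continuity correction, no pseudo-counts, df = 3.
  Haplotypes with zero counts in *both* conditions are dropped and df
  reduced; with fewer than two live columns the p-value is undefined and
  the quartet is excluded from the FDR adjustment. Tables with an expected
  cell below 1 are flagged (`low_expected`) but still tested, preserving
  auditability. p-values are BH-adjusted within each contrast separately.
* **Rank switching and Δ.** The top haplotype is the argmax of $p$
  (alphabetical tie-break, tie flagged; tied quartets are counted as
  switches unless `strict_ties`). Δ is the **absolute** difference in the
  maximum proportion between conditions,
  $\Delta = |\max_h p^{stress}_h - \max_h p^{control}_h|$, whether or not
  the identity of the top copy changed; Δ ≥ 0.10 is moderate and Δ ≥ 0.20
  pronounced. The signed per-haplotype differences remain available in the
  output table for auxiliary use.

# The NB GLM engine

Tissue enrichment and stress DE both rest on per-gene negative-binomial
log-link GLMs with log size-factor offsets (`fit_nb_glm()`), a deliberately
transparent engine: gene-wise dispersion, likelihood-ratio tests, no
empirical-Bayes shrinkage, no fold-change shrinkage. Numerical choices:

* **Normalization** is median-of-ratios: the reference is the per-gene
  geometric mean over genes positive in every sample, each sample's factor
  is the median of its count/reference ratios, and factors are rescaled to
  median 1. Small matrices can lack all-positive genes, so a fallback uses
  genes positive in ≥ 90 % of samples with zeros masked.
* **Dispersion** ($\alpha$, variance $\mu + \alpha\mu^2$) is initialized by
  method of moments on Poisson residuals and refined by maximizing the
  Cox–Reid-adjusted profile likelihood on $\log\alpha \in
  [\log 10^{-6}, \log 10]$. The IRLS inner loop converges at a coefficient
  tolerance of 1e-8 or 100 iterations; non-converged genes are flagged and
  excluded from testing.
* **Shared dispersion for the LRT.** A nested-model LRT needs one
  dispersion for both fits. Using the full-model estimate alone is
  anticonservative: whenever chance spread among group means inflates the
  likelihood ratio, the same spread deflates the full-model dispersion
  estimate, and the two errors compound. Using the reduced-model estimate
  alone inverts the coupling and over-corrects. The package therefore
  shares the **geometric mean of the two designs' Cox–Reid estimates**,
  which balances the couplings; the null fraction of p < 0.01 in a
  6-category, 4-replicate atlas at $\alpha = 0.05$ then sits near nominal
  (the acceptance suite verifies the 1 % tail directly).
* **log2 fold-changes** are computed on size-factor-normalized group means
  with a moderation constant of 0.5 added to both means, avoiding
  infinities at zero without shrinking large effects.

The engine makes no claim of numeric equality with any specific DE
package; its contract is a sound, calibrated NB GLM, verified by
simulation.

# Tissue atlas

Genes are **expressed** if CPM ≥ 1 in at least 2 libraries; only expressed
genes are tested and BH adjustment runs over exactly that set. Nine raw
tissues collapse to six categories (young leaves, mature leaves, roots,
stem, floral buds, open flowers) to gain replication; the scheme is a plain
named mapping and fully configurable. Per gene, the LRT compares the
tissue-factor model to the intercept model (df = categories − 1); the gene
is assigned to the category with the highest **mean variance-stabilized**
expression, and is called enriched if q < 0.01 and the top-vs-second
difference is ≥ 1 on the log2 scale.

* The variance-stabilizing transform is the parameter-free stand-in
  $\log_2(\text{count}/s_j + 1)$ — monotone, zero-preserving, invariant to
  jointly scaling a count and its size factor. It is not a
  fitted-dispersion VST; for the ranking and differencing purposes it
  serves here the two agree in ordering.
* Stability: the coefficient of variation is computed on the
  variance-stabilized values across **all** samples (raw-scale CV by
  flag). The tier operators are deliberately mixed — CV ≤ 0.20, CV < 0.15,
  CV < 0.10 — preserving the asymmetry at the boundaries; tiers are
  nested and the strictest satisfied tier is reported.
* "Highest expression" means highest category mean of transformed values,
  not the maximum single sample, so one outlier library cannot assign a
  gene to a tissue.

# Term over-representation

`fisher_enrichment()` performs the one-sided (over-representation)
Fisher's exact test: the p-value is the hypergeometric upper tail of the
2 × 2 study/annotation table, with BH adjustment across tested terms. The
odds ratio reported is the plain sample odds ratio
$k(N-n-K+k)/((n-k)(K-k))$, infinite when a denominator cell is empty. The
background population defaults to the genes that survived the relevant
expression filter rather than the whole annotation — the standard guard
against detection bias. Terms are flat labels: no ontology-graph
propagation is performed.

# The synthetic-data generator

`simulate_quartets()` draws, per quartet and condition, a true proportion
vector from a Dirichlet distribution; per replicate, a quartet total from a
negative binomial (mean 500 reads, dispersion 0.1 — deep enough that the
read-support filters are typically passed) split multinomially by the
condition's true vector. Two modelling points matter:

* The proportion vector is drawn **once per quartet per condition**, not
  re-drawn per replicate. Conditional on the condition totals, counts are
  then exactly multinomial, which is the null the chi-square contrast
  assumes — so the generator can serve as a clean type-I-error harness
  (`simulate_null_contrast()`). Re-drawing per replicate would inject
  extra-multinomial noise and make any pooled-count test anticonservative
  by construction, a deliberate non-feature of the default generator (and
  a caveat for real data, where replicate-level regulatory variation does
  exist; see Limitations).
* Planted classes are expressed as constraints on **true** proportions, so
  recovery is well-posed: strong dominance tilts the Dirichlet towards a
  (0.70, 0.10, 0.10, 0.10) target and rejects draws with true bias < 0.55;
  mild uses a 0.50 target constrained to bias ∈ [0.25, 0.5]; switch
  quartets move the top to a different haplotype in stress with the
  maximum proportion changed by exactly `delta_planted`. Unplanted
  quartets draw from a symmetric Dirichlet with total concentration 200,
  under which bias rarely approaches 0.25. Default planted fractions are
  3 % strong (matching the observed few-percent share of strongly dominant
  quartets in real tetraploid leaf data), 10 % mild and 10 % switch.

`simulate_atlas()` draws per-gene baselines log-normally (sdlog 1, the
typical spread of expression levels), NB counts with dispersion 0.05, and
multiplies one tissue's mean by $2^{\text{planted lfc}}$ for the enriched
fraction; "stable" genes are Poisson with no tissue effect. Because the
generator plants enrichment in one *raw* tissue, recovery experiments run
the atlas on raw labels (`scheme = NULL`): collapsing a merged pair
averages the planted effect down to the decision boundary on the log
scale, which tests the scheme rather than the estimator. All generators
are byte-reproducible from their seed.

What the generator does **not** emulate: read-level effects (mapping bias
towards the reference haplotype, multi-mapping among near-identical
copies), gene-length effects, correlated quartets, batch structure, or
replicate-level regulatory variation. Passing tests therefore demonstrate
the estimators' correctness under the stated statistical model, not
robustness to alignment artifacts — on real data, mapping bias in
particular can masquerade as stable allelic dominance.

# Problem sizes and runtime posture

The test and acceptance workloads use 2,000 quartets for calibration and
FDR studies, 200–500 quartets for recovery studies, and 1,000 genes for
atlas calibration/recovery — sizes at which binomial noise on the measured
rates is a few tenths of a percent, chosen so the whole suite completes in
a couple of minutes on a single core while leaving clear margins around
every decision threshold.

# Known limitations

* The chi-square contrast assumes pooled counts are multinomial given
  totals; replicate-level overdispersion in real data would inflate its
  type-I error (a Dirichlet-multinomial contrast would be the next step).
* Gene-wise dispersion without information sharing is noisy at 4
  replicates; the symmetrized sharing fixes calibration of the LRT but
  does not recover the power an empirical-Bayes prior would give.
* The VST stand-in under-stabilizes very low counts relative to a
  fitted-dispersion transform; CV-based stability tiers for weakly
  expressed genes should be read with that in mind.
* Retention classification and quartet selection trust the orthogroup
  table; mis-grouped paralogs propagate silently.
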