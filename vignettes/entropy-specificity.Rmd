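---
title: "Entropy decomposition as a specificity metric: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy decomposition as a specificity metric: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrospec)
```

## The model

`entrospec` treats a single gene's expression across cells as a
probability distribution: with counts (or normalized values) $x_i$ over
$n$ cells, $p_i = x_i / \sum_j x_j$, and the gene's total Shannon entropy
is $E_T = -\sum_i p_i \log p_i$. The values are taken as nonnegative
weights; raw and library-normalized inputs are both accepted, and because
the three reported metrics are ratios of entropies they are invariant to
rescaling a gene, but *not* to the normalization itself — scores computed
on raw and normalized layers differ, and which layer was used should be
reported with the results.

Given a partition of the cells into $r \ge 2$ labeled blocks (a metadata
column, or an interaction of several columns), the grouping property of
Shannon entropy decomposes $E_T = E_B + E_W$ with
$E_W = \sum_C p_C E_C$, where $p_C$ is the share of the gene's expression
mass in block $C$ and $E_C$ the entropy of the within-block distribution.
This identity is what makes the framework compositional across partition
hierarchies: for a refinement of a partition, the fine between-block
entropy equals the coarse one plus the mass-weighted between entropies
computed inside each coarse block. The test suite asserts this additivity
to 1e-10 on random matrices.

The three metrics reported per gene:

* $\Psi = E_W/E_T \in [0,1]$ — how much of the gene's information the
  partition explains. Note that $\Psi$ depends on block sizes even for a
  perfectly uniform gene ($\Psi = \log m / \log(rm)$ for $r$ equal blocks
  of $m$ cells), so it is interpreted jointly with $\zeta$ or
  $\psi_{\mathrm{block}}$, never alone.
* $\psi_{\mathrm{block}}(C) = p_C E_C / E_W$ — the share of within-block
  information carried by block $C$. These form a composition summing to
  one. We use the mass-weighted numerator $p_C E_C$ rather than the bare
  ratio $E_C/E_W$: since $E_W = \sum_C p_C E_C$, only the weighted form
  yields a probability vector, which both the $\zeta$ definition and the
  Aitchison aggregation require. The unweighted ratio would also reward
  large blocks for their size alone ($E_C \le \log|C|$).
* $\zeta = 1 - H(\psi_{\mathrm{blocks}})/\log r \in [0,1]$ — the
  normalized KL divergence of that composition from uniform; 1 means all
  within-block information sits in one block, 0 means it is evenly
  spread.

All entropies use natural logarithms internally; any common base cancels
in the three ratios (asserted to 1e-12 against a base-2 oracle).

### Degenerate genes

Two limits need conventions, both flagged in the output rather than
silently dropped. A gene expressed in at most one cell has $E_T = 0$;
every ratio is undefined and the gene is reported with
`degenerate = "zero_total"` and missing scores. A gene with $E_T > 0$ but
no block containing two expressing cells has $E_W = 0$; we set
$\Psi = 0$, fall back to the mass fractions $p_C$ as the composition (its
natural limit), and compute $\zeta$ from that. The default gene filter
(genes expressed in fewer than 100 cells removed, strict inequality, ties
retained) makes both cases rare in practice. $0\log 0 := 0$ throughout;
empty blocks are dropped from partitions rather than carried at zero
weight, because the $\log r$ normalizations should reflect realized
blocks.

## Balanced replicate sampling

Unbalanced replication (one strain with six mice, another with two)
biases any pooled statistic. The sampling layer draws subsets of whole
samples such that each draw holds exactly one sample per
(category, condition) pair — e.g. one mouse per strain×sex — requiring at
least one sample per pair. Within a pair the least-used sample (usage
tracked across draws) is chosen, ties broken by one seeded RNG stream, so
a fixed seed reproduces the draw sequence exactly and sample usage stays
as even as possible. The default is 100 draws; the per-draw scores are
then summarized per gene: arithmetic mean/SD for $\Psi$ and $\zeta$, and
for the compositional $\psi_{\mathrm{block}}$ vectors the Aitchison mean
(component-wise geometric mean, renormalized) with per-block geometric
SDs. Aitchison geometry is undefined at zero, so zero components are
multiplicatively replaced by $\delta$ = half the smallest nonzero
component observed for that gene before taking logs — a conventional
choice the output records (`delta` in `aitchison_mean`). Draws that
collapse the partition to one block are skipped with a warning (more than
half skipped is an error); a gene losing all expression in a draw is
excluded from that draw only, with `n_draws_used` reported.

## Inference

Significance comes from scrambling block labels: each permutation
shuffles the cell-to-block assignment (block sizes preserved) and reruns
the whole statistic pipeline — including the mean over balanced draws
when sampling is active, so the null statistic is computed exactly like
the observed one. P-values are one-sided (high is significant) and use
the add-one estimator $p = (1 + \#\{perm \ge obs\})/(1 + n_{perm})$,
which cannot return zero and keeps BH ranks meaningful; the raw
proportion is available via `add_one = FALSE`. Comparisons use an
absolute $10^{-12}$ tolerance (all metrics have magnitude $\le 1$) so
exact ties count as $\ge$ regardless of floating-point jitter and
p-values are invariant to rescaling a gene. All p-values — $\Psi$,
$\zeta$, every $\psi_{\mathrm{block}}$, across every partition scored in
a run — are pooled into a single Benjamini–Hochberg correction
(`stats::p.adjust`), so q-values are comparable across metrics and
partitions.

Permutation count trades resolution against time: with $B$ permutations
the smallest attainable p-value is $1/(B+1)$, and after global pooling
over $G$ genes and $3 + r$ metrics a discovery at $q < 0.05$ needs
roughly $1/(B+1) \le 0.05\,k/m$ for $k$ true signals among $m$ pooled
p-values. The default $B = 100$ suits exploratory scoring; the false
discovery calibration in the acceptance checks uses $B = 1000$ so that
q < 0.05 calls actually occur at its problem size (200 genes, 10%
signal).

## Selection workflows

Three gene lists, all gated on significance before thresholds (strict
inequalities, defaults 0.5 absent prior knowledge, q < 0.05):

* **markers of block $C$** — $q$ small for both $\psi_C$ and $\Psi$,
  $\psi_C$ and $\Psi$ above threshold, ranked by $\psi_C$ then $\Psi$;
* **partition-specific** — high $\Psi$ and high $\zeta$, both
  significant, ranked by $\zeta$ then $\Psi$;
* **housekeeping** — high significant $\Psi$ with a low $\zeta$ point
  estimate (no low-tail test is needed); `zeta_max` has deliberately no
  default, because "low" is a biological judgment.

Ranking ties break lexicographically by gene id for determinism.
Per-partition selections feed `upset_membership` (exclusive-intersection
regions whose sizes sum to the union) and `psi_feature_matrix` exports
the Aitchison-mean compositions for external clustering.

## Polygon projection

A composition over $r$ blocks lives on an $(r-1)$-simplex;
`project_composition` maps it to the barycentric average of the vertices
of a regular $r$-gon (unit circle, first vertex at the top,
counter-clockwise). The projection is affine and exact at the vertices,
centroid, and edge midpoints (tested to 1e-12). Orderings related by a
rotation or reflection of the polygon give the same picture, so there are
$(r-1)!/2$ genuinely distinct projections — 2520 for an octagon — a count
cross-checked by exhaustive dihedral-orbit enumeration for $r \le 6$.
Which ordering to use is domain knowledge (e.g. genetic distance between
strains) supplied by the user; the default is the partition's block
order.

## The synthetic generator

`simulate_expression` emulates a factorial atlas: crossed categorical
factors, several samples per combination, fixed cells per sample. Counts
are negative binomial (default mean 5, dispersion 0.5) with a lognormal
per-sample random effect (SD 0.2 on the log scale) shared across genes,
so balanced sampling has genuine replicate variance to average over.
Planted classes: markers (mean × fold, default 8, inside the target
block; a small residual mean, default baseline/20, elsewhere — the
infinite-fold limit is block-exclusive), housekeeping genes (one mean
everywhere) and noise genes (sparse, mean 0.3, unstructured).
`simulate_null` produces block-exchangeable data for calibration. The
generator is a test scaffold with known truth, not a fit to real data: it
has no dropout model, no library-size variation within samples, no
correlated gene programs, and no continuous covariates. Passing its
recovery checks (AUROC ≥ 0.95 at fold 8 with 200 cells per block; planted
housekeeping median $\zeta$ < 0.1; marker median $\zeta$ > 0.8)
demonstrates the metrics separate planted structure under these
idealized conditions — it does not certify performance on any real
dataset.

## Problem sizes and determinism

The shipped checks use sizes chosen to exercise the mathematics while
staying desk-scale: 1000 random gene/partition pairs for conservation,
100 random matrices for hierarchical additivity, 400 cells × 200 genes ×
4 blocks with 100 permutations for calibration, twenty seeded 90%-null
mixtures with 1000 permutations for realized FDP, and an 8-block × 200
cells-per-block recovery run. Every stochastic step flows from one seed
(draws, permutations, simulation), so a rerun with identical
configuration is byte-identical, and scoring is independent of the
gene-chunking used to bound memory — both asserted in the tests.

## Known limitations

Continuous covariates must be binned by the user before partitioning.
$\Psi$ is block-size dependent under uniformity (see above), so absolute
$\Psi$ thresholds mean different things for different $r$ and $n$.
Permutation nulls assume cells are exchangeable across blocks under the
null; strong within-sample correlation (batch structure not captured by
the partition) can make them anti-conservative — the balanced-sampling
mode, which permutes within the same draw structure as the observed
statistic, mitigates but does not remove this. Aitchison aggregation
requires the zero-replacement convention; genes whose composition is
exactly sparse in most draws inherit sensitivity to $\delta$.
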