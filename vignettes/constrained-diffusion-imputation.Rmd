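---
title: "Constrained diffusion imputation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained diffusion imputation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdimpute)
```

## The problem

Single-cell RNA-seq count matrices are dominated by zeros. Some are
biological (the gene is truly silent in that cell), others are technical
dropouts: the transcript was present but missed by capture or
amplification. Dropout rates are strongly expression-dependent — lowly
expressed genes drop out far more often than highly expressed ones — and
the resulting sparsity degrades clustering, visualization and trajectory
analysis.

Diffusion-based smoothing imputes dropouts by averaging each cell's profile
over its neighbours on a cell-similarity graph. Its known failure mode is
*over-smoothing*: with one global diffusion operator, every gene is averaged
over the same neighbourhood, and highly expressed genes — whose zeros are
the ones most likely to be biologically real — get homogenized across cells,
erasing genuine inter-cell variability.

`cdimpute` addresses this by giving every gene in every cell its own
smoothing strength. The expression level of a gene among a cell's most
similar neighbours sets an exponent in $[1, 3]$ applied to the cell's
transition probabilities: the higher the neighbour-mean expression, the
larger the exponent, the more the smoothing weight concentrates on the very
nearest cells, and the less the gene diffuses.

## The procedure

Let $X \in \mathbb{R}^{g \times n}_{\ge 0}$ be the count matrix (genes by
cells) after filtering (genes with total expression $> 0.001$, cells
expressing $> 3$ genes).

1. **Normalization.** With $s_j = \sum_i x_{ij}$ the library size of cell
   $j$ and $m = \operatorname{median}_j s_j$,
   $$X^{N}_{ij} = \frac{x_{ij}}{s_j}\, m .$$
   Every normalized column sums to $m$; the transform is inverted exactly at
   the end by multiplying column $j$ by $s_j / m$.

2. **High-variance genes.** On $X^N$, genes with mean $\ge 0.01$ are
   eligible; among them, genes whose coefficient of variation
   ($\mathrm{sd}/\mathrm{mean}$) reaches the first quartile of eligible-gene
   CVs are kept, giving $X^h$.

3. **Cell graph.** Cells are embedded by PCA on $X^h$ (genes centred,
   default up to 50 components). For each cell $i$, the kernel bandwidth
   $\sigma_i$ is the distance to its $k$-th nearest neighbour ($k = 5$),
   and affinities
   $$A_{ij} = \exp\!\big(-(d_{ij}/\sigma_i)^2\big)$$
   are computed over the $3k$ nearest neighbours of $i$, then symmetrized
   additively, $A \leftarrow (A + A^\top)/2$. Row normalization gives the
   Markov transition matrix $M$.

4. **Diffusion time.** $M$ is raised to successive powers; after each step
   the smoothed data $S_t = X^h (M^t)^\top$ is compared with $S_{t-1}$ by
   the squared Pearson correlation of the flattened matrices. The smallest
   $t \ge 2$ with $R^2 \ge 0.95$ is selected (capped at $t_{\max} = 12$).

5. **Expression constraint.** Each cell's $n$ highest-probability
   neighbours in $M^t$ (self excluded) are averaged gene-wise on $X^N$,
   giving the neighbour-mean matrix $X^a$. The neighbour count follows the
   dataset size: $n = 100$ for 1000 cells or more, otherwise
   $n = \operatorname{round}\!\big((N - 15)/985 \cdot 100\big)$, clamped to
   $[1, N - 1]$ (datasets must have more than 15 cells). $X^a$ is min–max
   scaled *globally* onto $[1, 3]$ to give the power matrix $P$.

6. **Constrained smoothing.** For gene $g$ and cell $c$,
   $$\hat{X}_{gc} = \sum_k \frac{(M^t_{ck})^{P_{gc}}}{\sum_{k'} (M^t_{ck'})^{P_{gc}}}\; X^N_{gk} .$$
   With $P_{gc} = 1$ this is plain diffusion $X^N (M^t)^\top$; raising the
   exponent provably never increases the Shannon entropy of the weight
   vector, so larger exponents always concentrate the averaging on the most
   reachable cells.

7. **Output.** $\hat{X}$ is mapped back to the count scale by reversing the
   normalization, and merged with the observed matrix so that **only zeros
   are replaced** — observed non-zero counts pass through bit-exactly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 5 | neighbour index that sets the adaptive kernel bandwidth |
| `neighbor_multiplier` | 3 | kNN list length, as a multiple of `k` |
| `n_pcs` | 50 (capped) | PCA dimensionality of the cell embedding |
| `t_max`, `r2_threshold` | 12, 0.95 | diffusion-time search bound and stabilization level |
| `n_neighbors` | size rule above | neighbours averaged for the expression constraint |
| `power_lo`, `power_hi` | 1, 3 | exponent range; `lo = hi - 2 = 1` recovers the published behaviour, `power_hi = power_lo` disables the constraint entirely |
| `rescale` | `"none"` | optional per-gene max matching before reverse normalization (see below) |

All data-driven choices (selected $t$, $n$, HVG count, filtered genes and
cells, the $R^2$ trace) are logged and written to the JSON run report by the
command-line interface, so a run can be audited afterwards.

## Numerical and design choices

Several points are under-determined by the verbal description of the
method; the package fixes them as follows, and each is covered by a test.

* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile` type 7), the most widespread convention. The CV
  quartile is computed over mean-eligible genes only: genes with tiny means
  have wildly unstable CVs and would distort the cut-off.
* **Mean and standard deviation** for the CV use the population
  denominator $n$. Constant genes have CV 0 and are retained only if the
  first quartile is 0.
* **The mean $\ge 0.01$ gate** is applied on the normalized matrix, which
  is the matrix the selection step receives.
* **Self-exclusion** is used throughout: a cell is not its own nearest
  neighbour for bandwidths, affinities (zero diagonal) or constraint
  neighbour sets (the diagonal of $M^t$ is typically its largest entry and
  carries no neighbourhood information).
* **Duplicate cells**: if $\sigma_i = 0$ because a cell has $k$ or more
  exact duplicates, the bandwidth falls back to the smallest positive
  neighbour distance; a fully duplicated neighbour list is an error.
* **$R^2$** between diffusion steps is the squared Pearson correlation of
  the flattened smoothed matrices (a symmetric choice with no regression
  direction to pick); the high-variance-gene matrix is the one diffused for
  this purpose, since it is the matrix the graph was built from.
* **"Row normalization"** of the symmetrized affinity matrix is what makes
  the chain Markov; rows of $A$ are divided by their sums.
* **Tie-breaking** in top-$n$ neighbour selection is by ascending cell
  index; with continuous affinities ties are essentially impossible, but the
  rule makes runs bit-reproducible.
* **Rounding** in the neighbour-count rule is half-up.
* **Min–max scaling** of $X^a$ is global (a single minimum and maximum over
  the whole matrix), so the exponent is a monotone function of
  neighbour-mean expression across the entire dataset; a constant $X^a$
  yields all exponents 1, i.e. plain diffusion.
* **PCA** uses the exact deterministic solver with component signs fixed by
  the largest-magnitude loading, so embeddings are reproducible across
  platforms. At the dataset sizes this package targets (up to a few
  thousand cells, dense matrices) the exact solver is never the bottleneck.
* **Exponent source.** The constraint needs an exponent for *every* gene,
  but the neighbour-mean construction is described on the high-variance
  matrix. By default the neighbour means are computed from the full
  normalized matrix, the only reading under which the smoothing formula is
  defined for all genes. The literal alternative — neighbour means on the
  high-variance genes only, with all other genes assigned the minimum
  exponent — is available as `xa_source = "xh_default_lo"`.
* **Rescaling.** The published procedure rescales the smoothed matrix
  before reverse normalization but does not say how. The natural candidate,
  matching each gene's smoothed maximum to its maximum in $X^N$, turned out
  to be harmful in this pipeline: since only zeros are merged into the
  output, smoothed values act as *estimates at dropout positions*, and the
  observed per-gene maximum is a noisy extreme order statistic — under
  realistic dropout the match inflates every imputed entry several-fold.
  The default is therefore no rescaling (`rescale = "none"`), with
  `"gene-max"` retained as an option and covered by its own contract test.

## What the synthetic generator does and does not emulate

`simulate_counts()` produces the study conditions used by the tests and the
acceptance script: 1500 genes, 300 cells, 3 equally sized clusters. Each
gene has a log-normal base mean (median 2, log-scale sd 1) shared across
clusters; disjoint random 10% marker sets per cluster are up-shifted
five-fold; counts are negative binomial with size 2. Dropout zeroes each
entry independently with probability $\exp(-\lambda \cdot \text{count})$ —
strictly decreasing in expression, which reproduces the inverse
expression–dropout relationship the method is built on. By default
$\lambda$ is tuned by bisection so the observed matrix is ~62.5% zeros,
inside the 55–70% band spanned by typical real datasets.

The generator deliberately omits library-size variation, batch effects,
doublets and trajectory structure. Passing tests therefore demonstrate the
method's mechanics (graph construction, constraint, zero-only merge,
recovery of cluster-level signal under expression-dependent dropout), not
performance on the full complexity of real data.

One property of this dropout model matters when interpreting recovery
results: because the dropout probability depends on the *realized* count,
the true values at dropped positions are systematically smaller than their
gene's cluster mean. Recovery is therefore evaluated the way imputation
methods are evaluated against bulk references: each cell is correlated with
a dropout-free *average* reference profile (here, its cluster's mean
ground-truth profile) before and after imputation. The acceptance script
computes both medians; imputation raises the median per-cell correlation,
and k-means clustering on 20-component embeddings of the imputed matrix is
never worse than on the raw matrix.

## Problem sizes

The test-suite fixtures range from hand-checkable $2 \times 2$ examples to
the full study fixture (1500 × 300); oracle comparisons (dense all-pairs
kernels, triple-loop smoothing) run at up to 30 × 40, where brute force is
exact and fast. The whole suite completes in well under a minute on one
core; the acceptance script in a few seconds.

## Known limitations

* Biological zeros of genes that are expressed in a cell's neighbourhood
  are filled like technical ones; distinguishing the two is outside the
  method's scope.
* The neighbour-count rule saturates at 100 cells, which can be too many
  for datasets with many small cell types.
* Matrices are dense in memory; the implementation targets desk-scale
  datasets (up to a few thousand cells), not atlas-scale collections.
* Cells or genes removed by filtering are reported as dropped, not imputed.
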