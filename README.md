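# cdimpute

Constrained diffusion imputation of dropout zeros in single-cell RNA-seq
count matrices.

## What it does, and for whom

Single-cell RNA-seq matrices are 50–90% zeros, a mixture of biological
silence and technical *dropout*. Diffusion-based smoothing imputes dropouts
by averaging each cell over its graph neighbours, but a single global
diffusion operator over-smooths: highly expressed genes — the ones whose
zeros are most likely real — get homogenized across cells.

`cdimpute` gives every gene in every cell its own smoothing strength. Cells
are embedded by PCA on high-variance genes and connected by an adaptive
Gaussian kNN kernel,

&nbsp;&nbsp;&nbsp;&nbsp;*A<sub>ij</sub>* = exp( −(d<sub>ij</sub> / σ<sub>i</sub>)² ), σ<sub>i</sub> = distance to the k-th neighbour (k = 5),

which after additive symmetrization and row normalization gives a Markov
transition matrix *M*; the diffusion time *t* is the first power at which
the smoothed data stabilizes (R² ≥ 0.95 between successive steps). The mean
expression of each gene over each cell's *n* most reachable neighbours is
min–max scaled onto [1, 3] to give a power matrix *P*, and the smoothed
value of gene *g* in cell *c* is

&nbsp;&nbsp;&nbsp;&nbsp;X̂<sub>gc</sub> = Σ<sub>k</sub> w<sub>k</sub> X<sup>N</sup><sub>gk</sub>,&nbsp;&nbsp; w<sub>k</sub> ∝ (M<sup>t</sup><sub>ck</sub>)<sup>P<sub>gc</sub></sup>.

Raising the exponent concentrates weight on the most similar cells, so
highly expressed genes diffuse less. After reversing the library-size
normalization, **only zeros of the observed matrix are replaced; observed
counts pass through bit-exactly**.

The package is aimed at anyone preparing desk-scale scRNA-seq matrices
(hundreds to a few thousand cells) for clustering or trajectory analysis,
and ships a cluster-structured simulator with expression-dependent dropout
plus evaluation utilities (ARI/NMI/purity, expression–dropout correlation,
correlation to a reference profile).

## Worked example

```r
library(cdimpute)

sim <- simulate_counts(genes = 400, cells = 100, clusters = 3, seed = 42)
mean(sim$observed == 0)          # 0.625 — ~62% of entries are zeros

res <- impute_counts(sim$observed, seed = 42)
#> filter: kept 400/400 genes, 100/100 cells
#> select_hvg: 299 high-variance genes
#> select_diffusion_time: t = 2 (R^2 trace: 0.0000, 0.9764)
#> neighbor_count: n = 9
print(res)
#> Constrained-diffusion imputation: 400 genes x 100 cells
#>   diffusion time t = 2, constraint neighbours n = 9, 299 HVGs
#>   zeros imputed: 25000 of 40000 entries
```

The log shows every data-driven choice: nothing was filtered, 299 of 400
genes passed the variance filter, two diffusion steps were enough to
stabilize the smoothed data (R² = 0.976 between steps 2 and 1), and each
cell's expression constraint averaged its 9 most reachable neighbours
(the size rule for 100 cells).

How much signal does this recover? Correlate each cell with its cluster's
mean ground-truth profile (a bulk-like, dropout-free reference), before and
after:

```r
labs <- sim$labels[colnames(res$final)]
truth <- sim$truth[rownames(res$final), colnames(res$final)]
ref <- sapply(unique(labs), function(k) rowMeans(truth[, labs == k]))
mapping <- setNames(as.character(labs), names(labs))

median(correlation_to_reference(res$observed, ref, mapping = mapping))
#> 0.743
median(correlation_to_reference(res$final, ref, mapping = mapping))
#> 0.811
```

Imputation raises the median per-cell correlation from 0.743 to 0.811. The
dropout mechanism the method exploits is visible in the observed data: the
mean per-cell-type Pearson correlation between gene expression level and
gene dropout rate is strongly negative,

```r
expression_dropout_correlation(sim$observed, sim$labels)
#> -0.739
```

A command-line interface wraps the same pipeline
(`system.file("exec", "cdimpute", package = "cdimpute")`):

```sh
cdimpute simulate --genes 400 --cells 100 --clusters 3 --seed 42 --out-dir sim/
cdimpute impute --input sim/observed.tsv --output imputed.tsv --seed 42
cdimpute evaluate --pred pred.tsv --truth sim/labels.tsv
```

`impute` writes a JSON run report next to the output with the selected
*t*, *n*, HVG count, R² trace and all parameter values; runs with the same
seed are byte-identical.

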