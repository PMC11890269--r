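#' Generate cluster-structured ground-truth counts
#'
#' Cells are split evenly into `clusters` groups. Each gene receives a base
#' mean drawn log-normally (location `log(mean_scale)`, scale 1), shared
#' across clusters; a random 10% of genes per cluster — disjoint across
#' clusters, so each marker tags one cluster — are up-shifted five-fold in
#' their cluster as markers. Counts are drawn from a negative binomial with
#' those means and the given dispersion (`size` in `rnbinom` terms: larger
#' values approach Poisson).
#'
#' @param genes,cells,clusters Dataset dimensions; `clusters >= 2`.
#' @param mean_scale Median of the log-normal cluster means.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Random seed; output is deterministic given the seed.
#' @return List with `truth` (genes x cells integer count matrix), `labels`
#'   (named character vector of cluster assignments) and `markers` (list of
#'   marker gene indices per cluster).
#' @export
generate_truth <- function(genes, cells, clusters, mean_scale = 2,
                           dispersion = 2, seed = 1L) {
  if (clusters < 2L) stop("at least 2 clusters are required", call. = FALSE)
  if (genes < 1L || cells < clusters) {
    stop("invalid dataset size", call. = FALSE)
  }
  set.seed(seed)
  labels <- sort(rep_len(seq_len(clusters), cells))
  mu <- matrix(stats::rlnorm(genes, meanlog = log(mean_scale), sdlog = 1),
               genes, clusters)
  markers <- vector("list", clusters)
  n_mark <- max(1L, round(0.1 * genes))
  pool <- seq_len(genes)
  for (kk in seq_len(clusters)) {
    if (length(pool) < n_mark) {
      stop("too few genes to assign disjoint markers to every cluster",
           call. = FALSE)
    }
    markers[[kk]] <- sort(sample(pool, n_mark))
    pool <- setdiff(pool, markers[[kk]])
    mu[markers[[kk]], kk] <- mu[markers[[kk]], kk] * 5
  }
  truth <- matrix(as.double(stats::rnbinom(genes * cells, size = dispersion,
                                           mu = as.vector(mu[, labels]))),
                  genes, cells,
                  dimnames = list(paste0("gene", seq_len(genes)),
                                  paste0("cell", seq_len(cells))))
  labels <- stats::setNames(paste0("cluster", labels), colnames(truth))
  names(markers) <- paste0("cluster", seq_len(clusters))
  list(truth = truth, labels = labels, markers = markers)
}

#' Apply expression-dependent dropout to a count matrix
#'
#' Each entry is independently set to zero with probability
#' `exp(-lam * value)`: the higher the true expression, the less likely the
#' value drops out, reproducing the inverse relationship between expression
#' level and dropout rate seen in real single-cell data. Entries are never
#' altered, only zeroed, and true zeros stay zero.
#'
#' @param truth Genes x cells count matrix.
#' @param lam Dropout decay rate (> 0); smaller values drop more entries.
#' @param seed Random seed.
#' @return Matrix of the same shape with some entries zeroed.
#' @export
apply_dropout <- function(truth, lam, seed = 1L) {
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  truth <- as_count_matrix(truth)
  set.seed(seed)
  drop <- matrix(stats::runif(length(truth)) < exp(-lam * truth),
                 nrow(truth), ncol(truth))
  observed <- truth
  observed[drop] <- 0
  observed
}

# Bisection on lam so that the observed zero fraction hits `target`.
# The zero fraction is decreasing in lam (larger lam = fewer dropouts).
tune_dropout <- function(truth, target, seed, lo = 1e-4, hi = 20,
                         iter = 40L) {
  zero_frac <- function(lam) mean(apply_dropout(truth, lam, seed) == 0)
  if (zero_frac(hi) > target) return(hi)   # truth itself is sparser than target
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (zero_frac(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a dropout-affected single-cell dataset
#'
#' Convenience wrapper around [generate_truth()] and [apply_dropout()]. When
#' `lam` is `NULL` the dropout rate is tuned by bisection so that the
#' observed matrix has approximately `target_zero_fraction` zeros; the
#' defaults (1500 genes, 300 cells, 3 clusters, ~62% zeros) give a
#' desk-scale dataset whose sparsity is in the range typical of real
#' droplet- and plate-based experiments.
#'
#' @inheritParams generate_truth
#' @param lam Dropout decay rate; `NULL` (default) tunes it to
#'   `target_zero_fraction`.
#' @param target_zero_fraction Desired zero fraction of the observed matrix
#'   when `lam` is tuned.
#' @param seed Random seed for both generation and dropout.
#' @param verbose Report the tuned `lam` and achieved zero fraction.
#' @return List with `truth`, `observed`, `labels`, `markers` and `params`
#'   (including the `lam` actually used).
#' @export
simulate_counts <- function(genes = 1500, cells = 300, clusters = 3,
                            mean_scale = 2, dispersion = 2,
                            lam = NULL, target_zero_fraction = 0.625,
                            seed = 1L, verbose = FALSE) {
  gt <- generate_truth(genes, cells, clusters, mean_scale, dispersion, seed)
  drop_seed <- seed + 1L
  if (is.null(lam)) {
    lam <- tune_dropout(gt$truth, target_zero_fraction, drop_seed)
    if (verbose) {
      message(sprintf("tuned dropout lam = %.6f", lam))
    }
  }
  observed <- apply_dropout(gt$truth, lam, drop_seed)
  if (verbose) {
    message(sprintf("observed zero fraction: %.3f", mean(observed == 0)))
  }
  list(truth = gt$truth, observed = observed, labels = gt$labels,
       markers = gt$markers,
       params = list(genes = genes, cells = cells, clusters = clusters,
                     mean_scale = mean_scale, dispersion = dispersion,
                     lam = lam, seed = seed))
}
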