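#' Expression-constrained diffusion smoothing
#'
#' For gene `g` and cell `c` the smoothed value is a weighted average of the
#' gene's normalized expression over all cells, with weights
#' `M^t[c, k] ^ p[g, c]` renormalized to sum to one. Exponent 1 reproduces
#' ordinary diffusion `XN %*% t(M^t)`; larger exponents concentrate the
#' weight on the cells the Markov chain reaches most easily, so genes with
#' high neighbour-mean expression are smoothed over fewer, more similar
#' cells.
#'
#' @param xn A `cdi_norm` object or genes x cells matrix of normalized
#'   expression.
#' @param tm A `cdi_markov` object (the stabilized power `m_t` supplies the
#'   weights).
#' @param p Genes x cells exponent matrix from [power_matrix()].
#' @return Genes x cells matrix of smoothed normalized expression.
#' @export
constrained_smooth <- function(xn, tm, p) {
  x <- if (inherits(xn, "cdi_norm")) xn$xn else as.matrix(xn)
  m_t <- if (inherits(tm, "cdi_markov")) tm$m_t else as.matrix(tm)
  p <- as.matrix(p)
  if (!all(dim(p) == dim(x)) || nrow(m_t) != ncol(x)) {
    stop("dimension mismatch between expression, exponents and transition matrix",
         call. = FALSE)
  }
  if (any(rowSums(m_t) == 0)) {
    stop("transition matrix has an all-zero row; weights cannot be normalized",
         call. = FALSE)
  }
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (g in seq_len(nrow(x))) {
    # m_t ^ p[g, ] recycles the exponent down columns: entry (c, k) is
    # m_t[c, k] ^ p[g, c], the per-cell exponent of this gene
    w <- m_t ^ p[g, ]
    out[g, ] <- as.vector((w / rowSums(w)) %*% x[g, ])
  }
  out
}

#' Rescale smoothed expression and undo normalization
#'
#' Optionally rescales each gene row so its maximum matches the gene's
#' maximum in the normalized matrix (`"gene-max"`; rows that smoothed to
#' all-zero are left alone), then inverts the size-factor normalization:
#' multiply each column by `size_factor / median_factor`.
#'
#' The default is `"none"`: because only zeros of the observed matrix are
#' replaced by the pipeline, the smoothed values are used directly as
#' estimates at dropout positions, and matching a gene's smoothed maximum to
#' its observed maximum — a noisy extreme order statistic under heavy
#' dropout — systematically inflates those estimates.
#'
#' @param xhat Genes x cells smoothed matrix from [constrained_smooth()].
#' @param norm The `cdi_norm` object carrying size factors; its `xn` provides
#'   the per-gene target maxima.
#' @param rescale `"none"` (default) or `"gene-max"`.
#' @return Genes x cells matrix on the raw count scale.
#' @export
rescale_and_denormalize <- function(xhat, norm,
                                    rescale = c("none", "gene-max")) {
  rescale <- match.arg(rescale)
  stopifnot(inherits(norm, "cdi_norm"))
  xhat <- as.matrix(xhat)
  if (rescale == "gene-max") {
    max_hat <- apply(xhat, 1L, max)
    max_xn <- apply(norm$xn, 1L, max)
    fac <- ifelse(max_hat > 0, max_xn / max_hat, 1)
    xhat <- xhat * fac                    # fac recycles down columns (per gene)
  }
  sweep(xhat, 2L, norm$size_factors / norm$median_factor, `*`)
}

#' Merge imputed values into the observed matrix, replacing zeros only
#'
#' Observed non-zero counts are kept bit-exactly; only zeros receive the
#' imputed value.
#'
#' @param observed Genes x cells matrix of (filtered) observed counts.
#' @param xbar Genes x cells imputed matrix on the raw count scale.
#' @return Genes x cells merged matrix.
#' @export
merge_with_observed <- function(observed, xbar) {
  observed <- as.matrix(observed)
  xbar <- as.matrix(xbar)
  if (!all(dim(observed) == dim(xbar))) {
    stop("observed and imputed matrices have different shapes", call. = FALSE)
  }
  final <- observed
  zero <- observed == 0
  final[zero] <- xbar[zero]
  final
}

#' Impute dropout zeros in a count matrix by constrained diffusion
#'
#' Runs the full pipeline: filter genes/cells, normalize by median library
#' size, select high-variance genes, embed cells with PCA, build the adaptive
#' Gaussian kNN affinity graph, row-normalize it into a Markov chain, choose
#' the diffusion time by stabilization, derive per-gene/per-cell exponents
#' from neighbour-mean expression, smooth with the constrained weights,
#' rescale and reverse the normalization, and finally merge with the observed
#' counts so that only zeros are replaced.
#'
#' @param counts Genes x cells non-negative count matrix (see
#'   [as_count_matrix()]).
#' @param gene_sum_min,min_genes_per_cell Filtering thresholds, see
#'   [filter_matrix()].
#' @param mean_min,cv_quantile High-variance-gene selection, see
#'   [select_hvg()].
#' @param n_pcs Number of principal components (capped at cells - 1 and the
#'   number of high-variance genes).
#' @param k,neighbor_multiplier Adaptive kernel parameters, see
#'   [adaptive_affinity()].
#' @param t_max,r2_threshold Diffusion-time selection, see
#'   [select_diffusion_time()].
#' @param n_neighbors Neighbours for the expression constraint; default is
#'   the [neighbor_count()] rule on the filtered cell count.
#' @param power_lo,power_hi Exponent range, see [power_matrix()].
#' @param xa_source `"xn"` (default) computes neighbour means from the full
#'   normalized matrix, so every gene gets its own exponent;
#'   `"xh_default_lo"` computes them from the high-variance genes only and
#'   assigns the minimum exponent `power_lo` to all other genes.
#' @param rescale Passed to [rescale_and_denormalize()].
#' @param seed Random seed; the pipeline is deterministic given the seed.
#' @param verbose Emit progress messages with the data-driven choices
#'   (diffusion time, neighbour count, gene/cell filtering).
#' @return An object of class `cdi_imputed`: list with
#'   \describe{
#'     \item{final}{merged genes x cells matrix on the raw count scale
#'       (observed non-zeros preserved exactly);}
#'     \item{xbar}{imputed matrix on the raw count scale before merging;}
#'     \item{xhat}{smoothed matrix on the normalized scale;}
#'     \item{observed}{the filtered observed counts the output aligns with;}
#'     \item{markov}{the `cdi_markov` object (one-step matrix, stabilized
#'       power, diffusion time);}
#'     \item{t, r2_trace}{selected diffusion time and its stabilization
#'       trace;}
#'     \item{n_neighbors, n_hvg}{neighbour count and number of
#'       high-variance genes;}
#'     \item{dropped_genes, dropped_cells}{identifiers removed by
#'       filtering;}
#'     \item{params}{the parameter values used.}
#'   }
#' @examples
#' sim <- simulate_counts(genes = 120, cells = 40, clusters = 2, seed = 1)
#' res <- impute_counts(sim$observed, n_pcs = 10, verbose = FALSE)
#' res$t
#' @export
impute_counts <- function(counts,
                          gene_sum_min = 0.001, min_genes_per_cell = 3,
                          mean_min = 0.01, cv_quantile = 0.25,
                          n_pcs = 50, k = 5, neighbor_multiplier = 3,
                          t_max = 12, r2_threshold = 0.95,
                          n_neighbors = NULL,
                          power_lo = 1, power_hi = 3,
                          xa_source = c("xn", "xh_default_lo"),
                          rescale = c("none", "gene-max"),
                          seed = 1L, verbose = TRUE) {
  xa_source <- match.arg(xa_source)
  rescale <- match.arg(rescale)
  set.seed(seed)
  say <- function(...) if (verbose) message(sprintf(...))

  counts <- as_count_matrix(counts)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) stop_stage(stage, e))
  }

  filt <- run("filter", filter_matrix(counts, gene_sum_min, min_genes_per_cell))
  say("filter: kept %d/%d genes, %d/%d cells",
      nrow(filt), nrow(counts), ncol(filt), ncol(counts))

  norm <- run("normalize", normalize_counts(filt))
  hvg <- run("select_hvg", select_hvg(norm, mean_min, cv_quantile))
  say("select_hvg: %d high-variance genes", nrow(hvg$xh))

  d <- min(n_pcs, ncol(filt) - 1L, nrow(hvg$xh))
  emb <- run("embed_pca", embed_pca(hvg, d = d, seed = seed))
  aff <- run("adaptive_affinity", adaptive_affinity(emb, k, neighbor_multiplier))
  tm <- run("to_markov", to_markov(aff))
  tm <- run("select_diffusion_time",
            select_diffusion_time(tm, hvg, t_max, r2_threshold))
  say("select_diffusion_time: t = %d (R^2 trace: %s)",
      tm$t, paste(sprintf("%.4f", tm$r2_trace), collapse = ", "))

  if (is.null(n_neighbors)) n_neighbors <- neighbor_count(ncol(filt))
  say("neighbor_count: n = %d", n_neighbors)

  if (xa_source == "xn") {
    nm <- run("neighbor_mean", neighbor_mean(tm, norm, n_neighbors))
    p <- run("power_matrix", power_matrix(nm, power_lo, power_hi))
  } else {
    nm <- run("neighbor_mean", neighbor_mean(tm, hvg$xh, n_neighbors))
    p_h <- run("power_matrix", power_matrix(nm, power_lo, power_hi))
    p <- matrix(power_lo, nrow(filt), ncol(filt), dimnames = dimnames(filt))
    p[hvg$selected, ] <- p_h
  }

  xhat <- run("constrained_smooth", constrained_smooth(norm, tm, p))
  xbar <- run("rescale_and_denormalize",
              rescale_and_denormalize(xhat, norm, rescale))
  final <- run("merge_with_observed", merge_with_observed(filt, xbar))

  structure(list(
    final = final, xbar = xbar, xhat = xhat, observed = filt,
    markov = tm,
    t = tm$t, r2_trace = tm$r2_trace,
    n_neighbors = as.integer(n_neighbors), n_hvg = nrow(hvg$xh),
    dropped_genes = setdiff(rownames(counts), rownames(filt)),
    dropped_cells = setdiff(colnames(counts), colnames(filt)),
    params = list(
      gene_sum_min = gene_sum_min, min_genes_per_cell = min_genes_per_cell,
      mean_min = mean_min, cv_quantile = cv_quantile,
      n_pcs = d, k = k, neighbor_multiplier = neighbor_multiplier,
      t_max = t_max, r2_threshold = r2_threshold,
      power_lo = power_lo, power_hi = power_hi,
      xa_source = xa_source, rescale = rescale, seed = seed
    )
  ), class = "cdi_imputed")
}

#' @export
print.cdi_imputed <- function(x, ...) {
  cat(sprintf("Constrained-diffusion imputation: %d genes x %d cells\n",
              nrow(x$final), ncol(x$final)))
  cat(sprintf("  diffusion time t = %d, constraint neighbours n = %d, %d HVGs\n",
              x$t, x$n_neighbors, x$n_hvg))
  cat(sprintf("  zeros imputed: %d of %d entries\n",
              sum(x$observed == 0), length(x$observed)))
  if (length(x$dropped_genes) || length(x$dropped_cells)) {
    cat(sprintf("  filtered out: %d genes, %d cells\n",
                length(x$dropped_genes), length(x$dropped_cells)))
  }
  invisible(x)
}
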