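#' Filter lowly covered genes and cells
#'
#' Keeps genes whose total expression across cells is strictly greater than
#' `gene_sum_min`, then (on the gene-filtered matrix) cells expressing
#' strictly more than `min_genes_per_cell` genes. The gene pass runs first,
#' so a cell's expressed-gene count is taken over the retained genes.
#'
#' More than 15 cells must survive: the neighbour-count rule used downstream
#' ([neighbor_count()]) is only defined for datasets larger than 15 cells.
#'
#' @param raw Genes x cells count matrix.
#' @param gene_sum_min Strict lower bound on per-gene total expression.
#' @param min_genes_per_cell Strict lower bound on the number of genes with
#'   positive expression per cell.
#' @return The filtered submatrix (dimnames subset accordingly).
#' @export
filter_matrix <- function(raw, gene_sum_min = 0.001, min_genes_per_cell = 3) {
  raw <- as_count_matrix(raw)
  keep_genes <- rowSums(raw) > gene_sum_min
  out <- raw[keep_genes, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("filtering removed every gene", call. = FALSE)
  }
  keep_cells <- colSums(out > 0) > min_genes_per_cell
  out <- out[, keep_cells, drop = FALSE]
  if (ncol(out) <= 15L) {
    stop(sprintf(
      "only %d cells remain after filtering; more than 15 are required",
      ncol(out)), call. = FALSE)
  }
  out
}

#' Median-of-library-size normalization
#'
#' Divides each cell's counts by that cell's total (its size factor) and
#' multiplies by the median size factor, so every normalized column sums to
#' the median library size. The size factors and the median are stored so the
#' transform can be inverted exactly; see [rescale_and_denormalize()].
#'
#' @param counts Genes x cells count matrix; every column sum must be positive.
#' @return An object of class `cdi_norm`: list with `xn` (normalized matrix),
#'   `size_factors` (per-cell column sums, named) and `median_factor`.
#' @export
normalize_counts <- function(counts) {
  counts <- as_count_matrix(counts)
  size_factors <- colSums(counts)
  if (any(size_factors <= 0)) {
    bad <- colnames(counts)[which(size_factors <= 0)[1L]]
    stop("cell has zero total count and cannot be normalized: ", bad,
         call. = FALSE)
  }
  median_factor <- stats::median(size_factors)
  xn <- sweep(counts, 2L, size_factors, `/`) * median_factor
  structure(
    list(xn = xn, size_factors = size_factors, median_factor = median_factor),
    class = "cdi_norm"
  )
}

#' @export
print.cdi_norm <- function(x, ...) {
  cat(sprintf("Normalized expression matrix: %d genes x %d cells\n",
              nrow(x$xn), ncol(x$xn)))
  cat(sprintf("  median size factor: %g\n", x$median_factor))
  invisible(x)
}

# population (denominator n) standard deviation per row
row_sd_pop <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowMeans(m * m) - mu * mu)
}

#' Select high-variance genes by coefficient of variation
#'
#' On the normalized matrix, genes with mean expression at least `mean_min`
#' are eligible; among those, genes whose coefficient of variation (population
#' standard deviation divided by mean) is at least the `cv_quantile` quantile
#' of the eligible genes' CVs are retained. With the defaults this keeps the
#' mean-eligible genes in the upper three CV quartiles (ties at the quartile
#' included).
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param norm A `cdi_norm` object from [normalize_counts()].
#' @param mean_min Minimum per-gene mean (computed on the normalized matrix).
#' @param cv_quantile Quantile of eligible-gene CVs used as the cut-off.
#' @return An object of class `cdi_hvg`: list with `xh` (selected genes x
#'   cells submatrix of the normalized matrix) and `selected` (integer indices
#'   into the normalized matrix rows).
#' @export
select_hvg <- function(norm, mean_min = 0.01, cv_quantile = 0.25) {
  stopifnot(inherits(norm, "cdi_norm"))
  xn <- norm$xn
  mu <- rowMeans(xn)
  eligible <- mu >= mean_min
  if (!any(eligible)) {
    stop(sprintf("no gene has mean expression >= %g", mean_min), call. = FALSE)
  }
  cv <- rep(0, nrow(xn))
  cv[eligible] <- row_sd_pop(xn[eligible, , drop = FALSE]) / mu[eligible]
  q1 <- stats::quantile(cv[eligible], cv_quantile, names = FALSE, type = 7L)
  selected <- which(eligible & cv >= q1)
  structure(
    list(xh = xn[selected, , drop = FALSE], selected = selected),
    class = "cdi_hvg"
  )
}

#' @export
print.cdi_hvg <- function(x, ...) {
  cat(sprintf("High-variance gene matrix: %d genes x %d cells\n",
              nrow(x$xh), ncol(x$xh)))
  invisible(x)
}
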