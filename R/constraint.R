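#' Number of neighbouring cells used for the expression constraint
#'
#' Datasets with 1000 or more cells use 100 neighbours. Below that the count
#' is interpolated linearly between the minimum usable dataset size (more
#' than 15 cells) and 1000 cells: `round((n_cells - 15) / 985 * 100)` with
#' half-up rounding, clamped to at least 1 and at most `n_cells - 1`.
#'
#' @param n_cells Number of cells in the (filtered) dataset; must exceed 15.
#' @return Integer neighbour count.
#' @export
neighbor_count <- function(n_cells) {
  if (n_cells <= 15) {
    stop("the neighbour-count rule requires more than 15 cells, got ",
         n_cells, call. = FALSE)
  }
  if (n_cells >= 1000) {
    return(100L)
  }
  n <- floor((n_cells - 15) / (1000 - 15) * 100 + 0.5)
  as.integer(min(max(n, 1), n_cells - 1))
}

#' Neighbour-mean expression matrix
#'
#' For every cell, takes the `n` cells with the highest transition
#' probability in that cell's row of the stabilized Markov matrix (self
#' excluded, ties broken by ascending cell index) and averages the
#' normalized expression of those neighbours gene-wise. The result measures,
#' for each gene in each cell, how strongly the gene is expressed among the
#' cell's most similar neighbours.
#'
#' @param tm A `cdi_markov` object after [select_diffusion_time()] (its
#'   `m_t` is used).
#' @param xn A `cdi_norm` object or genes x cells matrix whose columns are
#'   averaged.
#' @param n Neighbours per cell, between 1 and cells - 1; see
#'   [neighbor_count()].
#' @return An object of class `cdi_neighbor_mean`: list with `xa`
#'   (genes x cells neighbour-mean matrix), `neighbor_sets` (list of integer
#'   index vectors per cell) and `n`.
#' @export
neighbor_mean <- function(tm, xn, n) {
  stopifnot(inherits(tm, "cdi_markov"))
  x <- if (inherits(xn, "cdi_norm")) xn$xn else as.matrix(xn)
  m_t <- tm$m_t
  n_cells <- nrow(m_t)
  if (n < 1 || n > n_cells - 1) {
    stop(sprintf("n must be between 1 and %d, got %s", n_cells - 1, n),
         call. = FALSE)
  }
  n <- as.integer(n)
  xa <- matrix(0, nrow(x), n_cells, dimnames = dimnames(x))
  sets <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    row <- m_t[c, ]
    row[c] <- -Inf                     # self is never a neighbour
    ord <- order(row, seq_len(n_cells), decreasing = c(TRUE, FALSE),
                 method = "radix")
    sets[[c]] <- ord[seq_len(n)]
    xa[, c] <- rowMeans(x[, sets[[c]], drop = FALSE])
  }
  structure(list(xa = xa, neighbor_sets = sets, n = n),
            class = "cdi_neighbor_mean")
}

#' Power-exponent matrix from neighbour-mean expression
#'
#' Min-max scales the neighbour-mean matrix globally (one minimum and one
#' maximum over all entries) onto `[lo, hi]`. The result is the per-gene,
#' per-cell exponent applied to transition probabilities during smoothing:
#' genes highly expressed among a cell's neighbours get exponents near `hi`,
#' which concentrates the smoothing weights on the most similar cells and
#' restrains diffusion. A constant input (no dynamic range) maps to all-`lo`,
#' i.e. plain unconstrained diffusion.
#'
#' @param xa A `cdi_neighbor_mean` object or genes x cells matrix.
#' @param lo,hi Exponent range, default 1 to 3.
#' @return Genes x cells matrix of exponents in `[lo, hi]`.
#' @export
power_matrix <- function(xa, lo = 1, hi = 3) {
  x <- if (inherits(xa, "cdi_neighbor_mean")) xa$xa else as.matrix(xa)
  if (hi <= lo) {
    stop("power range is empty: hi must exceed lo", call. = FALSE)
  }
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    p <- matrix(lo, nrow(x), ncol(x), dimnames = dimnames(x))
    return(p)
  }
  (x - rng[1L]) / (rng[2L] - rng[1L]) * (hi - lo) + lo
}
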