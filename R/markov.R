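#' PCA embedding of cells
#'
#' Principal-component scores of the cells (rows = cells) computed from the
#' high-variance-gene matrix, with genes centred. The solver is exact and
#' deterministic; component signs are fixed by forcing the largest-magnitude
#' loading of each component to be positive, so results are reproducible
#' across platforms.
#'
#' @param xh A `cdi_hvg` object or a genes x cells matrix.
#' @param d Number of components; default `min(50, cells - 1, genes)`.
#' @param seed Accepted for interface stability; the exact solver does not
#'   consume randomness.
#' @return An object of class `cdi_embedding`: list with `coords`
#'   (cells x d score matrix, rownames = cell ids) and `d`.
#' @export
embed_pca <- function(xh, d = NULL, seed = 1L) {
  m <- if (inherits(xh, "cdi_hvg")) xh$xh else as.matrix(xh)
  n_cells <- ncol(m)
  d_max <- min(n_cells - 1L, nrow(m))
  if (is.null(d)) d <- min(50L, d_max)
  if (d < 2L || d > d_max) {
    stop(sprintf("d must be between 2 and %d (cells - 1, genes)", d_max),
         call. = FALSE)
  }
  set.seed(seed)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = d)
  scores <- pc$x
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(scores))) {
    load_j <- pc$rotation[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(m)
  structure(list(coords = scores, d = d), class = "cdi_embedding")
}

#' Adaptive Gaussian kNN affinity matrix
#'
#' For each cell `i` the kernel bandwidth `sigma_i` is the Euclidean distance
#' to its `k`-th nearest neighbour (self excluded). Affinities
#' `exp(-(dist/sigma_i)^2)` are computed for the `neighbor_multiplier * k`
#' nearest neighbours of `i` and are zero elsewhere; the diagonal is zero.
#' The asymmetric kernel is then symmetrized additively, `(A + t(A)) / 2`.
#'
#' If a cell has `k` or more exact duplicates (`sigma_i = 0`), the bandwidth
#' falls back to the cell's smallest positive neighbour distance; a cell whose
#' whole neighbour list is at distance zero is an error.
#'
#' @param emb A `cdi_embedding` or a cells x d coordinate matrix.
#' @param k Index of the neighbour that sets the bandwidth.
#' @param neighbor_multiplier Neighbour list length as a multiple of `k`.
#' @return Symmetric cells x cells affinity matrix with entries in `[0, 1]`
#'   and zero diagonal.
#' @export
adaptive_affinity <- function(emb, k = 5L, neighbor_multiplier = 3L) {
  coords <- if (inherits(emb, "cdi_embedding")) emb$coords else as.matrix(emb)
  n <- nrow(coords)
  n_nbr <- as.integer(neighbor_multiplier * k)
  if (n <= n_nbr) {
    stop(sprintf("need more than %d cells for k = %d with multiplier %d",
                 n_nbr, k, neighbor_multiplier), call. = FALSE)
  }
  dd <- as.matrix(stats::dist(coords))
  a <- matrix(0, n, n, dimnames = dimnames(dd))
  for (i in seq_len(n)) {
    d_i <- dd[i, ]
    ord <- order(d_i, seq_len(n))
    ord <- ord[ord != i][seq_len(n_nbr)]
    sigma <- d_i[ord[k]]
    if (sigma == 0) {
      pos <- d_i[ord][d_i[ord] > 0]
      if (!length(pos)) {
        stop(sprintf(
          "cell %s has an all-zero neighbour distance list; bandwidth undefined",
          rownames(dd)[i]), call. = FALSE)
      }
      sigma <- min(pos)
    }
    a[i, ord] <- exp(-(d_i[ord] / sigma)^2)
  }
  (a + t(a)) / 2
}

#' Row-normalize an affinity matrix into a Markov transition matrix
#'
#' @param a Non-negative cells x cells affinity matrix; every row must have a
#'   positive sum.
#' @return An object of class `cdi_markov`: list with `m` (the one-step
#'   row-stochastic matrix), `m_t` (its current power, initially `m`), `t`
#'   (diffusion time, initially 1) and `r2_trace` (empty until
#'   [select_diffusion_time()] runs).
#' @export
to_markov <- function(a) {
  a <- as.matrix(a)
  rs <- rowSums(a)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)[1L]
    id <- if (is.null(rownames(a))) bad else rownames(a)[bad]
    stop("cell is isolated in the affinity graph (zero row sum): ", id,
         call. = FALSE)
  }
  m <- a / rs
  structure(list(m = m, m_t = m, t = 1L, r2_trace = numeric(0)),
            class = "cdi_markov")
}

#' @export
print.cdi_markov <- function(x, ...) {
  cat(sprintf("Markov transition matrix over %d cells, diffusion time t = %d\n",
              nrow(x$m), x$t))
  if (length(x$r2_trace) > 1L) {
    cat(sprintf("  final stabilization R^2: %.6f\n",
                x$r2_trace[length(x$r2_trace)]))
  }
  invisible(x)
}

# R^2 between successive diffusion results: squared Pearson correlation of
# the flattened matrices; exact equality of degenerate (zero-variance)
# inputs counts as 1.
diffusion_r2 <- function(s_t, s_prev) {
  v_t <- as.vector(s_t)
  v_p <- as.vector(s_prev)
  if (stats::sd(v_t) == 0 || stats::sd(v_p) == 0) {
    return(as.numeric(isTRUE(all.equal(v_t, v_p))))
  }
  stats::cor(v_t, v_p)^2
}

#' Select the diffusion time by stabilization of the smoothed data
#'
#' Raises the transition matrix to successive powers and smooths the
#' high-variance-gene matrix with each power (`S_t = Xh %*% t(M^t)`). The
#' coefficient of determination between successive smoothed matrices
#' (squared Pearson correlation of the flattened values) measures how much
#' another diffusion step still changes the data; the smallest `t >= 2` whose
#' R-squared reaches `r2_threshold` is selected, or `t_max` if the threshold
#' is never reached.
#'
#' @param tm A `cdi_markov` object from [to_markov()].
#' @param xh A `cdi_hvg` object or genes x cells matrix diffused to monitor
#'   stabilization.
#' @param t_max Largest diffusion time considered (must be at least 2).
#' @param r2_threshold Stabilization threshold.
#' @return The input `cdi_markov` with `m_t = M^t`, `t`, and `r2_trace`
#'   filled in; `r2_trace[1]` is 0 by convention (no predecessor at t = 1)
#'   and `r2_trace[s]` compares diffusion `s` with `s - 1`.
#' @export
select_diffusion_time <- function(tm, xh, t_max = 12L, r2_threshold = 0.95) {
  stopifnot(inherits(tm, "cdi_markov"))
  if (t_max < 2L) {
    stop("t_max must be at least 2 (stabilization compares t with t - 1)",
         call. = FALSE)
  }
  x <- if (inherits(xh, "cdi_hvg")) xh$xh else as.matrix(xh)
  m <- tm$m
  m_t <- m
  s_prev <- x %*% t(m)
  trace <- 0
  t_sel <- 1L
  for (t in 2:t_max) {
    m_t <- m_t %*% m
    s_t <- x %*% t(m_t)
    r2 <- diffusion_r2(s_t, s_prev)
    trace <- c(trace, r2)
    t_sel <- t
    if (r2 >= r2_threshold) break
    s_prev <- s_t
  }
  tm$m_t <- m_t
  tm$t <- as.integer(t_sel)
  tm$r2_trace <- trace
  tm
}
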