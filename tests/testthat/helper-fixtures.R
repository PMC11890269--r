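# Small deterministic fixtures shared across test files.

# random non-negative matrix with dimnames
rand_counts <- function(genes, cells, seed, max_count = 20) {
  set.seed(seed)
  matrix(as.double(rpois(genes * cells, lambda = max_count / 4)),
         genes, cells,
         dimnames = list(paste0("g", seq_len(genes)),
                         paste0("c", seq_len(cells))))
}

# random row-stochastic matrix
rand_markov <- function(cells, seed) {
  set.seed(seed)
  a <- matrix(runif(cells * cells), cells, cells)
  a / rowSums(a)
}

# a cdi_markov object with a prescribed stabilized power
as_markov_fixture <- function(m_t) {
  structure(list(m = m_t, m_t = m_t, t = 2L, r2_trace = c(0, 1)),
            class = "cdi_markov")
}

# a cdi_norm wrapper around a plain matrix with unit size factors
as_norm_fixture <- function(x) {
  structure(list(xn = x,
                 size_factors = stats::setNames(rep(1, ncol(x)), colnames(x)),
                 median_factor = 1),
            class = "cdi_norm")
}

# small simulated dataset for pipeline-level tests (cheap: ~1 s)
small_sim <- function(seed = 7, genes = 200, cells = 50, clusters = 2) {
  simulate_counts(genes = genes, cells = cells, clusters = clusters,
                  seed = seed, verbose = FALSE)
}

shannon_entropy <- function(w) {
  w <- w[w > 0]
  -sum(w * log(w))
}

# per-entry triple-loop oracle for constrained smoothing
smooth_oracle <- function(xn, m_t, p) {
  out <- matrix(0, nrow(xn), ncol(xn))
  for (g in seq_len(nrow(xn))) {
    for (c in seq_len(ncol(xn))) {
      w <- m_t[c, ]^p[g, c]
      w <- w / sum(w)
      acc <- 0
      for (k in seq_len(ncol(xn))) acc <- acc + w[k] * xn[g, k]
      out[g, c] <- acc
    }
  }
  out
}
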