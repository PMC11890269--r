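#' Correlation between gene expression level and dropout rate, per cell type
#'
#' Within each cell type, every gene contributes one point: its total
#' expression over the type's cells and its dropout rate (fraction of zero
#' entries among those cells). The Pearson correlation across genes is
#' computed per type and the unweighted mean over types is returned. In real
#' single-cell data this correlation is negative: lowly expressed genes drop
#' out more often.
#'
#' Genes whose counts are constant across a type's cells (including genes
#' that are entirely zero there) carry no within-type signal and are excluded
#' from that type's correlation. Types with fewer than 3 cells, or in which
#' either vector is constant, are skipped with a warning; if every type is
#' skipped this is an error.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Cell-type labels, one per column of `counts` (named vectors
#'   are matched by cell id).
#' @return Mean correlation over usable cell types, with the per-type values
#'   in attribute `"per_type"`.
#' @export
expression_dropout_correlation <- function(counts, labels) {
  counts <- as_count_matrix(counts)
  labels <- align_labels(labels, colnames(counts))
  per_type <- c()
  for (ty in unique(labels)) {
    sub <- counts[, labels == ty, drop = FALSE]
    if (ncol(sub) < 3L) {
      warning("cell type ", ty, " has fewer than 3 cells; skipped")
      next
    }
    expr <- rowSums(sub)
    drate <- rowMeans(sub == 0)
    keep <- apply(sub, 1L, max) > apply(sub, 1L, min)
    expr <- expr[keep]
    drate <- drate[keep]
    if (length(expr) < 2L || stats::sd(expr) == 0 || stats::sd(drate) == 0) {
      warning("cell type ", ty,
              " has a degenerate expression/dropout vector; skipped")
      next
    }
    per_type[ty] <- stats::cor(expr, drate)
  }
  if (!length(per_type)) {
    stop("no cell type yielded a defined expression-dropout correlation",
         call. = FALSE)
  }
  structure(mean(per_type), per_type = per_type)
}

align_labels <- function(labels, cell_ids) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels)) && !is.null(cell_ids)) {
    if (!all(cell_ids %in% names(labels))) {
      missing <- setdiff(cell_ids, names(labels))
      stop("labels missing for cells: ", paste(utils::head(missing, 3),
                                               collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[cell_ids]
  } else if (length(labels) != length(cell_ids)) {
    stop(sprintf("got %d labels for %d cells", length(labels),
                 length(cell_ids)), call. = FALSE)
  }
  unname(labels)
}

#' Clustering agreement scores: ARI, NMI and purity
#'
#' Computes three agreement measures between a predicted and a reference
#' partition from their contingency table:
#' \describe{
#'   \item{ARI}{the adjusted Rand index under the permutation model
#'     (chance-corrected pair agreement, 1 for identical partitions, about 0
#'     for random ones);}
#'   \item{NMI}{mutual information normalized by the arithmetic mean of the
#'     two partition entropies;}
#'   \item{purity}{the fraction of cells assigned to the majority reference
#'     class of their predicted cluster.}
#' }
#' If both vectors are named they are aligned by cell id first.
#'
#' @param pred,truth Label vectors of equal length.
#' @return Object of class `cdi_scores`: list with `ari`, `nmi`, `purity`.
#' @export
clustering_scores <- function(pred, truth) {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth))) {
      stop("predicted and reference labels cover different cells",
           call. = FALSE)
    }
    pred <- pred[names(truth)]
  }
  if (length(pred) != length(truth)) {
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(pred), length(truth)), call. = FALSE)
  }
  if (length(pred) < 2L) stop("need at least 2 cells", call. = FALSE)
  tab <- table(as.character(pred), as.character(truth))
  n <- sum(tab)

  # ARI via the pair-counting formula on the contingency table
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)

  # NMI with arithmetic-mean normalization
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  nz <- p_ij > 0
  mi <- sum(p_ij[nz] * log(p_ij[nz] / outer(p_i, p_j)[nz]))
  h_i <- -sum(p_i[p_i > 0] * log(p_i[p_i > 0]))
  h_j <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  nmi <- if (h_i + h_j == 0) 1 else mi / ((h_i + h_j) / 2)

  purity <- sum(apply(tab, 1L, max)) / n

  structure(list(ari = ari, nmi = nmi, purity = purity),
            class = "cdi_scores")
}

#' @export
print.cdi_scores <- function(x, ...) {
  cat(sprintf("ARI = %.4f, NMI = %.4f, purity = %.4f\n",
              x$ari, x$nmi, x$purity))
  invisible(x)
}

#' Per-cell correlation to a reference expression profile
#'
#' Correlates every cell's expression profile (across the genes shared with
#' the reference) with its matched reference profile. Matching order: an
#' explicit `mapping` (cell id to reference column), then identical cell ids
#' in both matrices, then — if the reference has a single column — that
#' column for every cell.
#'
#' @param m Genes x cells matrix (e.g. observed or imputed expression).
#' @param reference Genes x columns reference matrix (e.g. bulk profiles or
#'   known concentrations); gene sets are intersected by id and at least 3
#'   shared genes are required.
#' @param method `"pearson"` or `"spearman"`.
#' @param mapping Optional named character vector: `mapping[cell_id]` is the
#'   reference column for that cell.
#' @return Named numeric vector of per-cell correlations.
#' @export
correlation_to_reference <- function(m, reference,
                                     method = c("pearson", "spearman"),
                                     mapping = NULL) {
  method <- match.arg(method)
  m <- as_count_matrix(m, what = "matrix")
  reference <- as_count_matrix(reference, what = "reference")
  shared <- intersect(rownames(m), rownames(reference))
  if (length(shared) < 3L) {
    stop(sprintf("only %d genes shared with the reference; need at least 3",
                 length(shared)), call. = FALSE)
  }
  m <- m[shared, , drop = FALSE]
  reference <- reference[shared, , drop = FALSE]
  ref_col <- function(cell) {
    if (!is.null(mapping)) {
      if (is.na(mapping[cell])) {
        stop("no reference mapping for cell ", cell, call. = FALSE)
      }
      return(mapping[[cell]])
    }
    if (cell %in% colnames(reference)) return(cell)
    if (ncol(reference) == 1L) return(1L)
    stop("cannot match cell ", cell,
         " to a reference column (no mapping, no matching id)", call. = FALSE)
  }
  vapply(colnames(m), function(cell) {
    stats::cor(m[, cell], reference[, ref_col(cell)], method = method)
  }, numeric(1))
}
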