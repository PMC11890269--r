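#' Validate and coerce a gene-by-cell count matrix
#'
#' The whole package works on dense numeric matrices with genes in rows and
#' cells in columns. Row names are gene identifiers, column names are cell
#' identifiers; both must be present, unique, and match the matrix dimensions.
#' All values must be finite and non-negative (normalized expression values
#' are allowed, not just integer counts).
#'
#' @param x A numeric matrix (genes x cells) or an object coercible to one.
#' @param what Label used in error messages.
#' @return The validated matrix, invisibly unchanged.
#' @export
as_count_matrix <- function(x, what = "count matrix") {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    stop(what, ": values must be numeric", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, ": contains missing or non-finite values", call. = FALSE)
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s: negative value at gene %s, cell %s",
      what,
      if (is.null(rownames(x))) bad[1L] else rownames(x)[bad[1L]],
      if (is.null(colnames(x))) bad[2L] else colnames(x)[bad[2L]]
    ), call. = FALSE)
  }
  if (is.null(rownames(x))) {
    rownames(x) <- paste0("gene", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("cell", seq_len(ncol(x)))
  }
  if (anyDuplicated(rownames(x))) {
    stop(what, ": duplicated gene identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(what, ": duplicated cell identifiers", call. = FALSE)
  }
  x
}

#' @keywords internal
stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}
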