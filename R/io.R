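#' Read a gene-by-cell expression matrix
#'
#' Supports two on-disk layouts:
#' \describe{
#'   \item{dense}{Delimited text with gene identifiers in the first column and
#'     cell identifiers in the header row. The delimiter is inferred from the
#'     file extension: comma for `.csv`, tab otherwise.}
#'   \item{mtx}{MatrixMarket coordinate format (1-based indices, zeros
#'     implicit) with sidecar files `genes.tsv` and `barcodes.tsv` in the same
#'     directory, one identifier per line (first column used if the sidecars
#'     have several).}
#' }
#'
#' @param path Path to the dense file or the `.mtx` file.
#' @param format `"auto"` (from extension), `"dense"`, or `"mtx"`.
#' @param transpose If `TRUE`, the file is cells x genes and is transposed
#'   after reading.
#' @return A validated genes x cells numeric matrix with dimnames.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, format = c("auto", "dense", "mtx"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  x <- if (format == "mtx") read_matrix_mtx(path) else read_matrix_dense(path)
  if (transpose) x <- t(x)
  as_count_matrix(x, what = basename(path))
}

read_matrix_dense <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header in ", path,
         ": expected gene-id column followed by cell ids", call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  x <- as.matrix(df)
  if (!is.numeric(x)) {
    stop("non-numeric entries in ", path, call. = FALSE)
  }
  x
}

read_matrix_mtx <- function(path) {
  dir <- dirname(path)
  genes_f <- file.path(dir, "genes.tsv")
  cells_f <- file.path(dir, "barcodes.tsv")
  for (f in c(genes_f, cells_f)) {
    if (!file.exists(f)) {
      stop("missing sidecar file: ", f, call. = FALSE)
    }
  }
  m <- as.matrix(Matrix::readMM(path))
  genes <- utils::read.table(genes_f, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(cells_f, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m)) {
    stop(sprintf("genes.tsv has %d entries but %s has %d rows",
                 length(genes), basename(path), nrow(m)), call. = FALSE)
  }
  if (length(cells) != ncol(m)) {
    stop(sprintf("barcodes.tsv has %d entries but %s has %d columns",
                 length(cells), basename(path), ncol(m)), call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a gene-by-cell expression matrix
#'
#' The inverse of [read_matrix()]: `read_matrix(write_matrix(m, f), ...)`
#' reproduces `m` exactly, including every decimal value (numbers are written
#' with 17 significant digits, enough to round-trip doubles). For `mtx` the
#' triplet file stores only non-zeros and the `genes.tsv` / `barcodes.tsv`
#' sidecars are written next to it.
#'
#' @param m Genes x cells matrix with dimnames.
#' @param path Destination file.
#' @param format `"auto"` (from extension), `"dense"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("auto", "dense", "mtx")) {
  format <- match.arg(format)
  m <- as_count_matrix(m, what = "matrix to write")
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") write_matrix_mtx(m, path) else write_matrix_dense(m, path)
  invisible(path)
}

num_repr <- function(x) {
  out <- formatC(x, digits = 17L, format = "g", mode = "double")
  gsub(" ", "", out, fixed = TRUE)
}

write_matrix_dense <- function(m, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = sep), con)
  body <- matrix(num_repr(m), nrow = nrow(m))
  lines <- paste(rownames(m),
                 apply(body, 1L, paste, collapse = sep),
                 sep = sep)
  writeLines(lines, con)
}

# MatrixMarket writer kept in-package so real values round-trip at full
# precision; reading goes through Matrix::readMM.
write_matrix_mtx <- function(m, path) {
  nz <- which(m != 0)
  i <- ((nz - 1L) %% nrow(m)) + 1L
  j <- ((nz - 1L) %/% nrow(m)) + 1L
  con <- file(path, open = "wt")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               paste(nrow(m), ncol(m), length(nz))), con)
  if (length(nz)) {
    writeLines(paste(i, j, num_repr(m[nz])), con)
  }
  close(con)
  dir <- dirname(path)
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
}

#' Read / write a cell label file
#'
#' Labels are stored as two-column tab-separated text (`cell_id`, `label`),
#' no header.
#'
#' @param path File path.
#' @return `read_labels`: a named character vector (names are cell ids).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    stop("label file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) != 2L) {
    stop("label file must have two tab-separated columns (cell_id, label): ",
         path, call. = FALSE)
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname read_labels
#' @param labels Named character vector (names = cell ids) or unnamed vector
#'   plus `cell_ids`.
#' @param cell_ids Cell identifiers, used when `labels` is unnamed.
#' @export
write_labels <- function(labels, path, cell_ids = names(labels)) {
  if (is.null(cell_ids)) {
    stop("cell ids are required to write labels", call. = FALSE)
  }
  utils::write.table(data.frame(cell_id = cell_ids, label = as.character(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
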