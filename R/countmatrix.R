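#' Construct a CountMatrix
#'
#' A `CountMatrix` holds sparse non-negative integer counts with genes in rows
#' and cells in columns, plus an optional log-normalized view filled in by
#' [log_normalize()]. Gene symbols are upper-cased on construction and
#' duplicates are rejected, because downstream marker panels are matched by
#' symbol.
#'
#' @param counts a matrix or `Matrix::sparseMatrix` of non-negative integer
#'   counts, genes x cells.
#' @param genes character vector of gene symbols (length `nrow(counts)`).
#' @param cells character vector of cell barcodes (length `ncol(counts)`).
#' @return an object of class `CountMatrix` with elements `counts`
#'   (a `dgCMatrix`), `genes`, `cells` and `normalized` (`NULL` until
#'   [log_normalize()] is called).
#' @export
count_matrix <- function(counts, genes, cells) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (nrow(counts) != length(genes))
    stop("count_matrix: ", nrow(counts), " rows but ", length(genes), " genes")
  if (ncol(counts) != length(cells))
    stop("count_matrix: ", ncol(counts), " columns but ", length(cells), " cells")
  genes <- toupper(as.character(genes))
  cells <- as.character(cells)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("count_matrix: duplicate gene symbol(s) after upper-casing: ",
         paste(unique(dup), collapse = ", "))
  dupc <- cells[duplicated(cells)]
  if (length(dupc))
    stop("count_matrix: duplicate cell barcode(s): ",
         paste(unique(dupc), collapse = ", "))
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("count_matrix: counts must be non-negative integers")
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts, genes = genes, cells = cells,
                 normalized = NULL),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%s normalized view)\n",
              length(x$genes), length(x$cells),
              if (is.null(x$normalized)) "no" else "with"))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Library-size log-normalization
#'
#' Computes `normalized[g, c] = ln(1 + scale * counts[g, c] / libsize[c])`
#' where `libsize[c]` is the total count of cell `c` — the standard
#' counts-per-`scale` log1p transform. Cells with zero total counts carry no
#' information and are dropped with a warning.
#'
#' @param cm a [count_matrix()].
#' @param scale positive scale factor (default 1e4, i.e. counts per ten
#'   thousand).
#' @return `cm` with the `normalized` element filled in (a sparse matrix of
#'   the same shape, minus any dropped all-zero cells).
#' @export
log_normalize <- function(cm, scale = 1e4) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("log_normalize: scale must be a positive number")
  libsize <- Matrix::colSums(cm$counts)
  zero <- libsize == 0
  if (any(zero)) {
    warning("log_normalize: dropping ", sum(zero), " all-zero cell(s): ",
            paste(utils::head(cm$cells[zero], 5), collapse = ", "))
    cm$counts <- cm$counts[, !zero, drop = FALSE]
    cm$cells <- cm$cells[!zero]
    libsize <- libsize[!zero]
  }
  norm <- cm$counts %*% Matrix::Diagonal(x = scale / libsize)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- list(cm$genes, cm$cells)
  cm$normalized <- norm
  cm
}

# Internal: fetch the normalized view or fail loudly.
norm_view <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(cm$normalized))
    stop("normalized view absent: call log_normalize() first")
  cm$normalized
}
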