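#' Cell-by-gene count matrix container
#'
#' A lightweight container holding a sparse non-negative integer count matrix
#' with cells as rows and genes as columns, a per-cell metadata table, and an
#' optional list of derived layers (`normalized`, `centered`, `scaled`) of
#' identical shape.
#'
#' @param counts A cells x genes matrix (dense or sparse) of non-negative
#'   integer counts. Must carry unique row (cell) and column (gene) names.
#' @param cell_meta Optional `data.frame` of per-cell metadata. Row names (or a
#'   `cell` column) must match the rows of `counts`.
#' @param layers Optional named list of numeric matrices with the same
#'   dimensions and dimnames as `counts`.
#'
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `cell_meta` and `layers`.
#' @examples
#' m <- CountMatrix(matrix(rpois(12, 2), 3, 4,
#'   dimnames = list(paste0("c", 1:3), paste0("g", 1:4))))
#' dim(m)
#' @export
CountMatrix <- function(counts, cell_meta = NULL, layers = list()) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have cell (row) and gene (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate cell names")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene names")
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = rownames(counts))
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (!is.null(cell_meta$cell) && is.null(rownames(cell_meta)) ||
        identical(rownames(cell_meta), as.character(seq_len(nrow(cell_meta))))) {
      if (!is.null(cell_meta$cell)) rownames(cell_meta) <- cell_meta$cell
    }
    if (!all(rownames(counts) %in% rownames(cell_meta)))
      stop("cell_meta must cover every cell in `counts`")
    cell_meta <- cell_meta[rownames(counts), , drop = FALSE]
  }
  for (nm in names(layers)) {
    if (!identical(dim(layers[[nm]]), dim(counts)))
      stop("layer '", nm, "' shape differs from counts")
  }
  structure(list(counts = counts, cell_meta = cell_meta, layers = layers),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
dimnames.CountMatrix <- function(x) dimnames(x$counts)

#' Gene and cell name accessors
#' @param x A `CountMatrix`.
#' @return Character vector of names.
#' @export
gene_names <- function(x) colnames(x$counts)

#' @rdname gene_names
#' @export
cell_names <- function(x) rownames(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  if (length(x$layers))
    cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (ncol(x$cell_meta))
    cat("cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a CountMatrix by cells and/or genes
#'
#' @param x A `CountMatrix`.
#' @param i Cell index (logical, integer or character).
#' @param j Gene index.
#' @param ... Ignored.
#' @param drop Ignored; result is always a `CountMatrix`.
#' @export
`[.CountMatrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  layers <- lapply(x$layers, function(l) l[i, j, drop = FALSE])
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 cell_meta = x$cell_meta[i, , drop = FALSE],
                 layers = layers),
            class = "CountMatrix")
}

#' Retrieve a layer as a dense base matrix
#'
#' @param x A `CountMatrix`.
#' @param name Layer name; `"counts"` returns the count matrix itself.
#' @return A dense numeric matrix (cells x genes).
#' @export
get_layer <- function(x, name = "normalized") {
  if (name == "counts") return(as.matrix(x$counts))
  if (is.null(x$layers[[name]]))
    stop("layer '", name, "' not present; run the producing step first")
  as.matrix(x$layers[[name]])
}

#' Write a CountMatrix to plain-text fixture files
#'
#' Emits a Matrix-Market triplet file (`matrix.mtx`), gene and barcode name
#' files (`features.tsv`, `barcodes.tsv`) and the cell metadata
#' (`metadata.tsv`). A round trip through [read_fixture()] reproduces the
#' count matrix exactly.
#'
#' @param m A `CountMatrix`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(m, dir) {
  stopifnot(inherits(m, "CountMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "metadata.tsv"))
  Matrix::writeMM(m$counts, paths[1])
  writeLines(colnames(m$counts), paths[2])
  writeLines(rownames(m$counts), paths[3])
  meta <- data.frame(cell = rownames(m$counts), m$cell_meta,
                     check.names = FALSE)
  utils::write.table(meta, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a CountMatrix fixture directory
#'
#' @param dir Directory previously written by [write_fixture()] (or any
#'   directory with `matrix.mtx`, `features.tsv`, `barcodes.tsv` and an
#'   optional `metadata.tsv`).
#' @return A `CountMatrix`.
#' @export
read_fixture <- function(dir) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::readMM(file.path(dir, "matrix.mtx")),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(cells, genes)
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              check.names = FALSE)
    rownames(meta) <- meta$cell
    meta$cell <- NULL
  }
  CountMatrix(counts, cell_meta = meta)
}
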