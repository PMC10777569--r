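#' Quality-control filtering of cells and genes
#'
#' Removes low-complexity and high-mitochondrial cells first, then genes
#' detected in too few of the remaining cells. Boundaries are strict: a cell
#' expressing fewer than `min_genes_per_cell` genes, or with mitochondrial
#' fraction strictly above `max_mito_fraction`, is removed; a gene detected
#' in fewer than `min_cells_per_gene` retained cells is removed. The filter
#' order (cells, then genes) is fixed so that gene detection counts refer to
#' retained cells; counts removed per rule are reported via `message()`.
#'
#' @param m A [CountMatrix].
#' @param min_genes_per_cell Minimum detected genes per retained cell.
#' @param min_cells_per_gene Minimum retained cells in which a gene must be
#'   detected.
#' @param max_mito_fraction Maximum mitochondrial count fraction.
#' @param mito_pattern Regular expression identifying mitochondrial genes.
#' @return The filtered `CountMatrix`.
#' @export
qc_filter <- function(m, min_genes_per_cell = 300, min_cells_per_gene = 3,
                      max_mito_fraction = 0.08, mito_pattern = "^MT-") {
  stopifnot(inherits(m, "CountMatrix"))
  counts <- m$counts
  detected <- Matrix::rowSums(counts > 0)
  mito <- grepl(mito_pattern, colnames(counts))
  total <- Matrix::rowSums(counts)
  mito_frac <- if (any(mito))
    Matrix::rowSums(counts[, mito, drop = FALSE]) / pmax(total, 1)
  else rep(0, nrow(counts))
  low_complexity <- detected < min_genes_per_cell
  high_mito <- mito_frac > max_mito_fraction
  keep_cells <- !(low_complexity | high_mito)
  if (!any(keep_cells))
    stop("qc_filter removed every cell; thresholds too strict for this matrix")
  message(sprintf("qc_filter: removed %d cells with < %d detected genes, %d with mito fraction > %g",
                  sum(low_complexity), min_genes_per_cell,
                  sum(high_mito & !low_complexity), max_mito_fraction))
  m2 <- m[keep_cells, ]
  gene_cells <- Matrix::colSums(m2$counts > 0)
  keep_genes <- gene_cells >= min_cells_per_gene
  message(sprintf("qc_filter: removed %d genes detected in < %d cells",
                  sum(!keep_genes), min_cells_per_gene))
  m2[, keep_genes]
}

#' Log-normalize counts
#'
#' Adds a `normalized` layer with
#' `ln(1 + scale_factor * count / cell_total)`, the standard library-size
#' log-normalization for UMI counts.
#'
#' @param m A [CountMatrix] (post-QC; zero-total cells are an error).
#' @param scale_factor Target per-cell total before `log1p`.
#' @return `m` with a sparse `normalized` layer added.
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "CountMatrix"))
  total <- Matrix::rowSums(m$counts)
  if (any(total == 0))
    stop("cell(s) with zero total counts; run qc_filter first")
  norm <- methods::as(Matrix::Diagonal(x = scale_factor / total) %*% m$counts,
                      "CsparseMatrix")
  dimnames(norm) <- dimnames(m$counts)
  norm@x <- log1p(norm@x)
  m$layers$normalized <- norm
  m
}

#' Select highly variable genes
#'
#' Ranks genes by the variance-stabilized standardized variance: a loess fit
#' (span 0.3) of log10 variance on log10 mean of the raw counts predicts each
#' gene's expected standard deviation; counts are standardized by it, clipped
#' at `sqrt(n_cells)`, and the variance of the clipped values is the gene's
#' variability score.
#'
#' @param m A [CountMatrix].
#' @param n Number of genes to return (default 2000).
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of `n` gene names, ordered by score descending.
#' @export
select_hvg <- function(m, n = 2000, loess_span = 0.3) {
  stopifnot(inherits(m, "CountMatrix"))
  if (n <= 0) stop("n must be positive")
  n <- min(n, ncol(m$counts))
  x <- as.matrix(m$counts)
  nc <- nrow(x)
  mu <- colMeans(x)
  v <- col_sds(x)^2
  ok <- v > 0 & mu > 0
  score <- rep(0, ncol(x))
  if (sum(ok) >= 2) {
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = loess_span,
                        degree = 2)
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(nc)
    z <- sweep(sweep(x[, ok, drop = FALSE], 2, mu[ok]), 2, sd_exp, "/")
    z <- pmin(pmax(z, -clip), clip)
    score[ok] <- colSums(z^2) / (nc - 1)
  }
  names(score) <- colnames(x)
  ord <- order(score, decreasing = TRUE)
  colnames(x)[ord][seq_len(n)]
}

#' Center and scale genes
#'
#' Adds a `centered` layer (normalized minus per-gene mean) and a `scaled`
#' layer (centered divided by per-gene standard deviation, clipped to
#' `±clip`). Genes with zero variance scale to 0.
#'
#' @param m A [CountMatrix] with a `normalized` layer.
#' @param clip Symmetric clip bound for the scaled layer.
#' @return `m` with `centered` and `scaled` layers added (dense).
#' @export
scale_genes <- function(m, clip = 10) {
  stopifnot(inherits(m, "CountMatrix"))
  norm <- get_layer(m, "normalized")
  mu <- colMeans(norm)
  centered <- sweep(norm, 2, mu)
  sds <- col_sds(norm)
  sds[is.na(sds) | sds == 0] <- Inf   # zero-variance genes scale to 0
  scaled <- sweep(centered, 2, sds, "/")
  scaled <- pmin(pmax(scaled, -clip), clip)
  m$layers$centered <- centered
  m$layers$scaled <- scaled
  m
}
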