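#' Infer a smoothed copy-number profile from expression
#'
#' Orders genes by genomic coordinate, subtracts the reference-cell mean per
#' gene from the normalized expression, clips to `±clip`, smooths along each
#' chromosome with a centered moving average of `window` genes (truncated at
#' chromosome edges), and re-centers each cell by its median window value.
#' Malignant cells carrying real copy-number shifts show contiguous
#' deviations; diploid reference cells hover near zero.
#'
#' @param m A [CountMatrix] with a `normalized` layer.
#' @param coords BED-like `data.frame` with columns `chrom`, `start`, `end`,
#'   `gene` (0-based half-open; strand ignored).
#' @param reference_cells Character vector of cell ids to use as the diploid
#'   reference (typically declared non-epithelial cells).
#' @param window Odd moving-average length in genes.
#' @param clip Symmetric clip bound on relative expression before smoothing.
#' @return A `CNVProfile` list: `values` (cells x windows, one window per
#'   retained gene), `windows` (ordered gene/coordinate table), `cnv_score`
#'   (per-cell quadratic sum) and `reference_cells`.
#' @export
infer_cnv_profile <- function(m, coords, reference_cells, window = 101,
                              clip = 1.0) {
  stopifnot(inherits(m, "CountMatrix"))
  if (!length(reference_cells)) stop("no reference cells supplied")
  if (!all(reference_cells %in% rownames(m$counts)))
    stop("reference cells absent from matrix")
  norm <- get_layer(m, "normalized")
  coords <- coords[coords$gene %in% colnames(norm), , drop = FALSE]
  coords <- coords[order(coords$chrom, coords$start), , drop = FALSE]
  if (!nrow(coords)) stop("no matrix gene has coordinates")
  x <- norm[, coords$gene, drop = FALSE]
  ref_mean <- colMeans(x[reference_cells, , drop = FALSE])
  rel <- sweep(x, 2, ref_mean)
  rel <- pmin(pmax(rel, -clip), clip)
  smoothed <- matrix(0, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  for (ch in unique(coords$chrom)) {
    idx <- which(coords$chrom == ch)
    if (length(idx) < window)
      warning(sprintf("chromosome %s has %d genes (< window); truncated windows used",
                      ch, length(idx)))
    smoothed[, idx] <- t(running_mean(t(rel[, idx, drop = FALSE]), window))
  }
  med <- apply(smoothed, 1, stats::median)
  values <- smoothed - med
  structure(list(values = values, windows = coords,
                 cnv_score = cnv_score_from_values(values),
                 reference_cells = reference_cells),
            class = "CNVProfile")
}

cnv_score_from_values <- function(values) rowSums(values^2)

#' Quadratic-sum CNV score
#'
#' Per-cell sum of squared smoothed relative-expression window values; high
#' values indicate copy-number-like expression distortion.
#'
#' @param profile A `CNVProfile`.
#' @return Named non-negative numeric vector, one value per cell.
#' @export
cnv_score <- function(profile) {
  stopifnot(inherits(profile, "CNVProfile"))
  cnv_score_from_values(profile$values)
}

#' Epithelial identity score
#'
#' Background-corrected gene-set score over epithelial marker genes,
#' delegating to [score_gene_set()]; combined with CNV evidence to call
#' malignant cells.
#'
#' @param m A [CountMatrix] with a `normalized` layer.
#' @param marker_set Epithelial marker gene symbols (>= 2 present).
#' @param ... Passed to [score_gene_set()] (`n_bins`, `n_samplings`, `seed`,
#'   `exact`).
#' @return A `ScoreVector`.
#' @export
epithelial_score <- function(m, marker_set, ...) {
  score_gene_set(m, marker_set, ...)
}

#' Call malignant cells from CNV and epithelial evidence
#'
#' A cell is called malignant when its CNV score exceeds the reference mean
#' by more than `k` reference standard deviations AND its epithelial score
#' exceeds the median over all cells. Cutoffs are reported via `message()`.
#'
#' @param cnv Named per-cell CNV score (e.g. from [cnv_score()]).
#' @param epi A `ScoreVector` (or named numeric) of epithelial scores for the
#'   same cells.
#' @param reference_cells Cell ids defining the null CNV distribution.
#' @param k Number of reference standard deviations above the mean.
#' @return Named logical vector of malignancy flags.
#' @export
call_malignant <- function(cnv, epi, reference_cells, k = 2.0) {
  epi_s <- if (inherits(epi, "ScoreVector"))
    stats::setNames(epi$score, rownames(epi)) else epi
  if (!setequal(names(cnv), names(epi_s)))
    stop("cnv and epithelial scores must cover the same cells")
  epi_s <- epi_s[names(cnv)]
  ref <- cnv[names(cnv) %in% reference_cells]
  if (length(ref) < 2 || stats::sd(ref) == 0)
    stop("reference CNV scores have zero variance")
  thr <- mean(ref) + k * stats::sd(ref)
  epi_thr <- stats::median(epi_s)
  message(sprintf("call_malignant: cnv threshold %.4g (ref mean + %g sd), epithelial threshold %.4g (median)",
                  thr, k, epi_thr))
  cnv > thr & epi_s > epi_thr
}
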