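#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  do.call(c, out)
}

# Raw ssGSEA enrichment score of one set for one ranked observation.
# r: per-gene rank values (ties averaged, top gene = largest), in_set:
# logical aligned with r.
ssgsea_es_one <- function(r, in_set, alpha) {
  ord <- order(r, decreasing = TRUE)
  in_ord <- in_set[ord]
  w <- r[ord]^alpha
  w_in <- w * in_ord
  denom_in <- sum(w_in)
  n_out <- sum(!in_set)
  p_in <- cumsum(w_in) / denom_in
  p_out <- cumsum(!in_ord) / n_out
  sum(p_in - p_out)
}

#' Single-sample gene set enrichment scores
#'
#' Per observation, genes are ranked by normalized expression (descending,
#' average ranks for ties); the enrichment score is the running-sum integral
#' of the difference between the rank-weighted in-set ECDF (weights
#' `rank^alpha`) and the unweighted out-of-set ECDF. Raw scores are
#' normalized by the global range (max - min) of the score matrix, mapping
#' them into `[-1, 1]`. Deterministic given the matrix.
#'
#' @param m A [CountMatrix] with a `normalized` layer, or a numeric
#'   observations x genes matrix.
#' @param gene_sets Named list of gene symbol vectors (e.g. [read_gmt()]).
#'   Sets with fewer than 2 genes present are dropped with a warning.
#' @param alpha Rank weighting exponent.
#' @param normalize Divide by the global score range (`TRUE`) or return raw
#'   running sums.
#' @return An `EnrichmentResult` list: `es` (observations x sets matrix),
#'   `alpha`, `normalized`, `contrast` (filled by
#'   [differential_enrichment()]).
#' @export
ssgsea_scores <- function(m, gene_sets, alpha = 0.25, normalize = TRUE) {
  x <- if (inherits(m, "CountMatrix")) get_layer(m, "normalized") else as.matrix(m)
  genes <- colnames(x)
  sets <- lapply(gene_sets, intersect, y = genes)
  usable <- vapply(sets, length, integer(1)) >= 2
  if (!all(usable))
    warning(sprintf("%d gene set(s) with < 2 genes present dropped",
                    sum(!usable)))
  sets <- sets[usable]
  if (!length(sets)) stop("no gene set overlaps the matrix")
  n_obs <- nrow(x)
  ranks <- t(apply(x, 1, rank))           # top gene = largest rank
  es <- matrix(NA_real_, n_obs, length(sets),
               dimnames = list(rownames(x), names(sets)))
  in_mat <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  for (i in seq_len(n_obs)) {
    r <- ranks[i, ]
    for (j in seq_along(sets))
      es[i, j] <- ssgsea_es_one(r, in_mat[, j], alpha)
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  structure(list(es = es, alpha = alpha, normalized = normalize,
                 contrast = NULL),
            class = "EnrichmentResult")
}

#' Two-group contrast of enrichment scores
#'
#' Wilcoxon rank-sum test (via [compare_groups()]) of each gene set's
#' enrichment scores between two groups, with Benjamini-Hochberg adjustment
#' across sets; direction is the sign of the median difference (first group
#' level minus second).
#'
#' @param res An `EnrichmentResult`.
#' @param labels Two-level grouping aligned to the observation axis.
#' @return The result with `contrast` filled: `data.frame` (gene_set,
#'   direction, statistic, p, p_adj).
#' @export
differential_enrichment <- function(res, labels) {
  stopifnot(inherits(res, "EnrichmentResult"))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  es <- res$es
  rows <- lapply(colnames(es), function(gs) {
    v <- es[, gs]
    cg <- compare_groups(v, labels)
    d <- stats::median(v[labels == levels(labels)[1]]) -
      stats::median(v[labels == levels(labels)[2]])
    data.frame(gene_set = gs, direction = sign(d),
               statistic = cg$statistic, p = cg$p.value)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  res$contrast <- tab
  res
}
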