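#' Ligand-receptor mean statistic between cell types
#'
#' For every ordered (sender, receiver) cell-type pair and every
#' ligand-receptor gene pair, the statistic is the average of the ligand's
#' mean normalized expression in sender cells and the receptor's mean in
#' receiver cells, together with the fraction of cells on each side
#' expressing the gene (count > 0 on the normalized layer).
#'
#' @param m A [CountMatrix] with a `normalized` layer.
#' @param labels Cell-type label per cell (aligned to rows of `m`).
#' @param pairs Data frame with columns `ligand` and `receptor`; pairs whose
#'   genes are absent from the matrix are dropped with a warning.
#' @return Data frame with `ligand`, `receptor`, `sender_type`,
#'   `receiver_type`, `mean_stat`, `frac_sender`, `frac_receiver`.
#' @export
lr_mean_statistic <- function(m, labels, pairs) {
  stopifnot(inherits(m, "CountMatrix"))
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(m$counts))
  keep <- pairs$ligand %in% gene_names(m) & pairs$receptor %in% gene_names(m)
  if (!all(keep))
    warning(sprintf("%d pair(s) with genes absent from matrix dropped",
                    sum(!keep)))
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) stop("no usable ligand-receptor pairs")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  x <- get_layer(m, "normalized")[, genes, drop = FALSE]
  type_means <- type_gene_means(x, labels)
  type_fracs <- type_gene_means((x > 0) * 1, labels)
  types <- rownames(type_means)
  grid <- expand.grid(pair = seq_len(nrow(pairs)),
                      sender_type = types, receiver_type = types,
                      stringsAsFactors = FALSE)
  data.frame(
    ligand = pairs$ligand[grid$pair],
    receptor = pairs$receptor[grid$pair],
    sender_type = grid$sender_type,
    receiver_type = grid$receiver_type,
    mean_stat = (type_means[cbind(grid$sender_type, pairs$ligand[grid$pair])] +
                 type_means[cbind(grid$receiver_type, pairs$receptor[grid$pair])]) / 2,
    frac_sender = type_fracs[cbind(grid$sender_type, pairs$ligand[grid$pair])],
    frac_receiver = type_fracs[cbind(grid$receiver_type, pairs$receptor[grid$pair])],
    stringsAsFactors = FALSE)
}

# types x genes matrix of per-type means of a cells x genes matrix.
type_gene_means <- function(x, labels) {
  cnt <- table(labels)
  s <- rowsum(x, labels)
  s / as.vector(cnt[rownames(s)])
}

#' Permutation p-values for ligand-receptor interactions
#'
#' Cell-type labels are permuted across cells `n_perm` times; each pair's
#' p-value is `(1 + #\{perm >= observed\}) / (n_perm + 1)`. A pair is
#' significant when `p < alpha` and at least `min_frac` of cells on both
#' sides express the gene.
#'
#' @param m A [CountMatrix] with a `normalized` layer.
#' @param labels Cell-type label per cell (>= 2 types).
#' @param pairs Data frame with `ligand`, `receptor` columns.
#' @param n_perm Number of label permutations (a warning below 100).
#' @param seed Integer seed.
#' @param min_frac Minimum expressed-cell fraction on both sides.
#' @param alpha Significance threshold (strict `<`).
#' @return Data frame of `LRPairResult` rows: the [lr_mean_statistic()]
#'   columns plus `p_value` and `significant`.
#' @export
permutation_pvalues <- function(m, labels, pairs, n_perm = 1000, seed = 1L,
                                min_frac = 0.1, alpha = 0.05) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 cell types")
  if (n_perm < 100) warning("n_perm < 100 gives coarse p-values")
  obs <- lr_mean_statistic(m, labels, pairs)
  keep <- pairs$ligand %in% gene_names(m) & pairs$receptor %in% gene_names(m)
  pairs <- pairs[keep, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  x <- get_layer(m, "normalized")[, genes, drop = FALSE]
  set.seed(as.integer(seed))
  exceed <- numeric(nrow(obs))
  lig_i <- match(obs$ligand, genes)
  rec_i <- match(obs$receptor, genes)
  snd <- obs$sender_type
  rcv <- obs$receiver_type
  for (p in seq_len(n_perm)) {
    perm <- sample(labels)
    tm <- type_gene_means(x, perm)
    stat_p <- (tm[cbind(snd, genes[lig_i])] + tm[cbind(rcv, genes[rec_i])]) / 2
    exceed <- exceed + (stat_p >= obs$mean_stat)
  }
  obs$p_value <- (1 + exceed) / (n_perm + 1)
  obs$significant <- obs$p_value < alpha &
    obs$frac_sender >= min_frac & obs$frac_receiver >= min_frac
  attr(obs, "n_perm") <- n_perm
  attr(obs, "alpha") <- alpha
  attr(obs, "min_frac") <- min_frac
  obs
}

#' Filter and sort significant ligand-receptor results
#'
#' @param results Output of [permutation_pvalues()].
#' @param alpha Significance threshold (strict `<`).
#' @param min_frac Minimum expressed-cell fraction on both sides.
#' @return Rows with `p_value < alpha` and both fractions `>= min_frac`,
#'   sorted by p-value then mean statistic descending (stable).
#' @export
filter_significant <- function(results, alpha = 0.05, min_frac = 0.1) {
  keep <- results$p_value < alpha &
    results$frac_sender >= min_frac & results$frac_receiver >= min_frac
  out <- results[keep, , drop = FALSE]
  out[order(out$p_value, -out$mean_stat), , drop = FALSE]
}
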