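#' Background-corrected gene-set score per observation
#'
#' The score contrasts a gene set's centered expression against
#' expression-matched random control genes. With the normalized layer `X`
#' (observations x genes):
#'
#' 1. per-gene averages over all observations are computed;
#' 2. genes are partitioned into `n_bins` equal-frequency bins by that
#'    average;
#' 3. `S_center(obs)` is the mean over set genes of `X - gene mean`;
#' 4. for each of `n_samplings` rounds, every set gene is replaced by one
#'    gene drawn uniformly from its bin (excluding the set gene itself when
#'    the bin has another member) and the centered mean recomputed;
#'    `S_random(obs)` is the average over rounds;
#' 5. the score is `S_center - S_random`, so a higher score means higher
#'    set expression than expression-matched background.
#'
#' With `exact = TRUE` the Monte-Carlo average in step 4 is replaced by its
#' closed form (each set gene's control expectation is the mean of its
#' allowed bin members), which equals the exhaustive average over all
#' control-gene assignments.
#'
#' @param m A [CountMatrix] with a `normalized` layer, or a plain numeric
#'   observations x genes matrix already on a log scale (bulk mode).
#' @param gene_set Character vector of gene symbols; members absent from the
#'   matrix are dropped with a warning, and fewer than 2 usable genes is an
#'   error.
#' @param n_bins Number of expression bins (reduced with a warning if it
#'   exceeds the gene count).
#' @param n_samplings Monte-Carlo rounds for the random score.
#' @param seed Integer seed fully determining the draws.
#' @param exact Replace sampling by the exact control expectation.
#' @return A `ScoreVector`: data frame with `score` and `subgroup`
#'   ("high"/"low" by median split), row names = observation ids, and
#'   attributes `gene_set_used`, `n_bins`, `n_samplings`, `seed`.
#' @export
score_gene_set <- function(m, gene_set, n_bins = 25, n_samplings = 1000,
                           seed = 1L, exact = FALSE) {
  x <- if (inherits(m, "CountMatrix")) get_layer(m, "normalized") else as.matrix(m)
  genes <- colnames(x)
  if (is.null(genes)) stop("matrix must carry gene names")
  use <- intersect(gene_set, genes)
  if (length(use) < length(gene_set))
    warning(sprintf("%d gene-set members absent from matrix; dropped",
                    length(gene_set) - length(use)))
  if (length(use) < 2) stop("fewer than 2 usable gene-set genes")
  n_genes <- length(genes)
  if (n_bins > n_genes) {
    warning("n_bins exceeds gene count; reduced")
    n_bins <- n_genes
  }
  gene_avg <- colMeans(x)
  ## equal-frequency bins by average expression (ties broken by gene order)
  rk <- rank(gene_avg, ties.method = "first")
  bin <- ceiling(rk * n_bins / n_genes)
  centered <- sweep(x, 2, gene_avg)
  set_idx <- match(use, genes)
  s_center <- rowMeans(centered[, set_idx, drop = FALSE])

  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- numeric(n_genes)          # expected draw count per control gene
  for (g in set_idx) {
    members <- which(bin == bin[g])
    cand <- setdiff(members, g)
    if (!length(cand)) cand <- g          # singleton bin: gene is its own control
    if (exact) {
      w[cand] <- w[cand] + 1 / length(cand)
    } else {
      draws <- cand[sample.int(length(cand), n_samplings, replace = TRUE)]
      tb <- tabulate(draws, nbins = n_genes)
      w <- w + tb / n_samplings
    }
  }
  s_random <- as.vector(centered %*% w) / length(set_idx)
  score <- s_center - s_random
  sv <- data.frame(score = score, row.names = rownames(x))
  sv$subgroup <- median_split(score)
  attr(sv, "gene_set_used") <- use
  attr(sv, "n_bins") <- n_bins
  attr(sv, "n_samplings") <- if (exact) Inf else n_samplings
  attr(sv, "seed") <- seed
  class(sv) <- c("ScoreVector", "data.frame")
  sv
}

#' Median split into high and low subgroups
#'
#' Observations with score strictly above the median are `"high"`; scores at
#' or below the median are `"low"` (fixed tie rule). All-identical scores
#' yield all-`"low"` with a warning.
#'
#' @param scores A `ScoreVector` or numeric vector (length >= 2).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(scores) {
  s <- if (inherits(scores, "ScoreVector")) scores$score else as.numeric(scores)
  if (length(s) < 2) stop("need at least 2 observations")
  med <- stats::median(s)
  if (all(s == s[1])) {
    warning("all scores identical; every observation labelled 'low'")
    return(rep("low", length(s)))
  }
  ifelse(s > med, "high", "low")
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Exact enumeration for small samples, the normal approximation with tie
#' correction otherwise. With no ties and both groups of size <= 20 the
#' exact Wilcoxon distribution is used; with ties, the full permutation
#' distribution is enumerated when there are at most ~200,000 group
#' assignments; otherwise the tie-corrected normal approximation applies.
#'
#' @param values Numeric vector of observations.
#' @param labels Two-level grouping vector (both groups nonempty).
#' @return List with `statistic` (rank-sum `W` of the first group, as in
#'   [stats::wilcox.test()]) and `p.value` (two-sided).
#' @export
compare_groups <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  g1 <- values[labels == levels(labels)[1]]
  g2 <- values[labels == levels(labels)[2]]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(g1, g2)) > 0
  if (!ties && n1 <= 20 && n2 <= 20) {
    ht <- stats::wilcox.test(g1, g2, exact = TRUE)
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value))
  }
  r <- rank(c(g1, g2))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2    # Mann-Whitney U
  if (ties && choose(n1 + n2, n1) <= 2e5) {
    combos <- utils::combn(n1 + n2, n1)
    rs <- colSums(matrix(r[combos], nrow = n1))
    u <- rs - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(u - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = w_obs, p.value = p))
  }
  ht <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
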