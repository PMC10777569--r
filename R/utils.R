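## Internal numeric helpers shared across modules.

# Rank-based AUC of `score` for separating positives (label TRUE) from
# negatives; equals the Mann-Whitney U / (n1*n0) probability.
auc_score <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative labels")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Column standard deviations of a dense matrix without densifying per column.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  sqrt((colSums(x * x) - n * mu^2) / (n - 1))
}

# Moving average along the rows of `x` (one series per column) with a
# centered window of odd length `window`; edges use truncated windows.
running_mean <- function(x, window) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- (window - 1L) %/% 2L
  cs <- apply(x, 2L, cumsum)
  if (n == 1L) cs <- matrix(cs, nrow = 1L)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  top <- cs[hi, , drop = FALSE]
  bot <- rbind(0, cs)[lo, , drop = FALSE]
  (top - bot) / (hi - lo + 1L)
}
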