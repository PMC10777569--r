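## Independent oracles used across the suite. Each reimplements the target
## quantity from first principles (enumeration, closed form, or hand
## formula) without touching the package's code paths.

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(score, positive) {
  pos <- score[as.logical(positive)]
  neg <- score[!as.logical(positive)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive-enumeration background score: every assignment of one control
# gene (from its bin, excluding the set gene when possible) per set gene is
# enumerated over the full product space; returns per-observation
# S_center - mean_over_assignments(S_control).
oracle_score_enumeration <- function(x, set_genes, bin) {
  genes <- colnames(x)
  centered <- sweep(x, 2, colMeans(x))
  set_idx <- match(set_genes, genes)
  cand <- lapply(set_idx, function(g) {
    b <- which(bin == bin[g])
    out <- setdiff(b, g)
    if (!length(out)) g else out
  })
  combos <- expand.grid(cand)
  s_rand <- rowMeans(apply(combos, 1, function(ctrl)
    rowMeans(centered[, as.integer(ctrl), drop = FALSE])))
  rowMeans(centered[, set_idx, drop = FALSE]) - s_rand
}

# Direct running-sum ssGSEA score for one observation (loop form).
oracle_ssgsea_es <- function(expr_row, set_genes, alpha = 0.25) {
  genes <- names(expr_row)
  r <- rank(expr_row)                      # top gene = largest rank
  ord <- order(expr_row, decreasing = TRUE)
  in_set <- genes[ord] %in% set_genes
  w <- r[ord]^alpha
  denom_in <- sum(w[in_set])
  n_out <- sum(!in_set)
  run_in <- run_out <- 0
  es <- 0
  for (i in seq_along(ord)) {
    if (in_set[i]) run_in <- run_in + w[i] / denom_in
    else run_out <- run_out + 1 / n_out
    es <- es + (run_in - run_out)
  }
  es
}

# Closed-form Benjamini-Hochberg: adjusted p_i = min over j with
# rank_j >= rank_i of p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(ord)]
}

# Exhaustive ligand-receptor permutation p-value: enumerates every distinct
# assignment of the label multiset to cells.
oracle_lr_exhaustive <- function(norm, labels, ligand, receptor,
                                 sender, receiver) {
  stat_for <- function(lab) {
    (mean(norm[lab == sender, ligand]) + mean(norm[lab == receiver, receptor])) / 2
  }
  obs <- stat_for(labels)
  n <- length(labels)
  n_s <- sum(labels == sender)
  combos <- utils::combn(n, n_s)
  stats <- apply(combos, 2, function(idx) {
    lab <- rep(setdiff(unique(labels), sender)[1], n)
    lab[idx] <- sender
    stat_for(lab)
  })
  mean(stats >= obs - 1e-12)
}

# Hand-computed two-group log-rank O, E, V (hypergeometric variance).
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(O = O, E = E, V = V, chi2 = chi2)
}

# Breslow partial log-likelihood for a single covariate, maximized on a
# grid + golden-section refinement (independent of survival::coxph).
oracle_cox_breslow <- function(time, event, x) {
  loglik <- function(b) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      dead <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + sum(x[dead] * b) -
        length(dead) * log(sum(exp(x[risk] * b)))
    }
    ll
  }
  stats::optimize(loglik, c(-10, 10), maximum = TRUE, tol = 1e-12)$maximum
}

# Hand product-limit table (no variance) for a single group.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out$surv[i] <- s
  }
  out
}

# Small null CountMatrix built directly from seeded NB draws (no planted
# structure at all), for calibration checks that must not depend on the
# generator's planted blocks.
null_count_matrix <- function(n_cells = 100, n_genes = 60, seed = 1,
                              mu = 2, size = 2) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = size),
                   n_cells, n_genes,
                   dimnames = list(sprintf("c%04d", seq_len(n_cells)),
                                   sprintf("g%04d", seq_len(n_genes))))
  counts[cbind(which(rowSums(counts) == 0), 1L)] <- 1L  # avoid empty cells
  CountMatrix(counts)
}

# Compact simulator configuration for tests that only need a small matrix
# without the full planted layout (no CNV block, tiny modules, no LR pairs).
small_sim <- function(n_cells, n_genes, seed, ...) {
  args <- utils::modifyList(
    list(n_cells = n_cells, n_genes = n_genes, seed = seed,
         n_modules = 2, module_size = 5, cnv_block = NULL,
         n_extra_regulators = 10, lr_pairs_planted = data.frame()),
    list(...))
  generate_counts(do.call(sim_config, args))
}
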