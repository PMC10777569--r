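#' Signed adjacency for a weighted coexpression network
#'
#' `a_ij = ((1 + cor(i, j)) / 2)^beta`, with the diagonal set to 0 so that
#' connectivity is the sum over other genes. Constant genes get correlation 0
#' (adjacency `0.5^beta`) against every other gene.
#'
#' @param expr Observations x genes numeric matrix.
#' @param beta Soft-thresholding power (>= 1).
#' @return Genes x genes adjacency matrix in `[0, 1]`, zero diagonal.
#' @export
signed_adjacency <- function(expr, beta) {
  stopifnot(beta >= 1)
  cc <- suppressWarnings(stats::cor(expr))
  cc[!is.finite(cc)] <- 0
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

# Scale-free topology fit: R^2 of log10(freq) vs log10(mean k) over
# connectivity bins, signed negative if the slope is positive.
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(c(rsq = 0, slope = 0))
  cut_pts <- seq(min(k), max(k), length.out = n_breaks + 1)
  bin <- cut(k, cut_pts, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(c(rsq = 0, slope = 0))
  x <- log10(mean_k[keep]); y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[2]
  rsq <- summary(fit)$r.squared
  c(rsq = unname(if (slope > 0) -rsq else rsq), slope = unname(slope))
}

#' Pick the soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power the signed adjacency is built and the scale-free
#' fit index computed: the squared correlation of `log10(freq(k-bin))` with
#' `log10(mean k in bin)`, counted only when the slope is negative. Returns
#' the smallest power whose fit reaches `r2_target`; if none qualifies, the
#' power with the best fit is returned with a warning.
#'
#' @param expr Observations x genes matrix (>= 2 genes, >= 3 observations).
#' @param powers Candidate integer powers.
#' @param r2_target Scale-free fit threshold (default 0.85).
#' @return Integer power with attributes `fit_table` (power, rsq, slope,
#'   mean_k) and `reached` (logical).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, r2_target = 0.85) {
  if (ncol(expr) < 2 || nrow(expr) < 3)
    stop("need >= 2 genes and >= 3 observations")
  cc <- suppressWarnings(stats::cor(expr))
  cc[!is.finite(cc)] <- 0
  s <- (1 + cc) / 2
  diag(s) <- 0
  tab <- t(vapply(powers, function(b) {
    k <- colSums(s^b)
    f <- scale_free_fit(k)
    c(power = b, rsq = f[["rsq"]], slope = f[["slope"]], mean_k = mean(k))
  }, numeric(4)))
  tab <- as.data.frame(tab)
  ok <- tab$rsq >= r2_target
  if (any(ok)) {
    beta <- tab$power[which(ok)[1]]
    reached <- TRUE
  } else {
    beta <- tab$power[which.max(tab$rsq)]
    reached <- FALSE
    warning("no power reached the scale-free fit target; returning best fit")
  }
  structure(as.integer(beta), fit_table = tab, reached = reached)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' diagonal 1; values lie in `[0, 1]` and combine direct adjacency with
#' shared-neighbor similarity.
#'
#' @param expr Observations x genes matrix.
#' @param beta Soft power (>= 1).
#' @param signed Use the signed adjacency (only supported mode).
#' @return Genes x genes TOM similarity matrix.
#' @export
build_tom <- function(expr, beta, signed = TRUE) {
  if (!signed) stop("only the signed network is implemented")
  a <- signed_adjacency(expr, beta)
  tom_from_adjacency(a)
}

# TOM from a zero-diagonal adjacency matrix.
tom_from_adjacency <- function(a) {
  k <- colSums(a)
  shared <- a %*% a
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- as.matrix(num / den)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  (tom + t(tom)) / 2
}

# Recursive "tree" dynamic cut on an hclust object: start from the static
# cut at `cut_frac` of the height range, then keep splitting a branch at its
# top merge while both pieces still hold >= min_size leaves.
tree_dynamic_cut <- function(hc, min_size, cut_frac = 0.99) {
  n <- length(hc$order)
  h0 <- cut_frac * max(hc$height)
  static <- stats::cutree(hc, h = h0)

  # leaves under each internal merge node
  leaves <- vector("list", n - 1L)
  node_leaves <- function(i) {
    if (i < 0) return(-i)
    leaves[[i]]
  }
  for (i in seq_len(n - 1L)) {
    leaves[[i]] <- c(node_leaves(hc$merge[i, 1]), node_leaves(hc$merge[i, 2]))
  }
  # top internal node of each static cluster = highest merge whose leaf set
  # is contained in the cluster
  labels <- rep(0L, n)
  next_label <- 0L
  assign_cluster <- function(members) {
    # find highest merge node whose leaves == members
    if (length(members) == 1L) return(list(node = -members))
    cand <- which(vapply(leaves, function(l)
      length(l) == length(members) && all(l %in% members), logical(1)))
    list(node = cand[length(cand)])
  }
  split_rec <- function(node) {
    # returns list of leaf vectors (accepted modules/branches)
    if (node < 0) return(list(-node))
    kids <- hc$merge[node, ]
    sizes <- vapply(kids, function(k) if (k < 0) 1L else length(leaves[[k]]),
                    integer(1))
    if (all(sizes >= min_size)) {
      c(split_rec(kids[1]), split_rec(kids[2]))
    } else {
      list(node_leaves(node))
    }
  }
  out <- rep(0L, n)
  lab <- 0L
  for (cl in unique(static)) {
    members <- which(static == cl)
    top <- assign_cluster(members)$node
    pieces <- split_rec(top)
    for (p in pieces) {
      if (length(p) >= min_size) {
        lab <- lab + 1L
        out[p] <- lab
      }                                   # else stays 0 = unassigned/grey
    }
  }
  out
}

# First principal component of a module's standardized expression, unit norm,
# sign-oriented so its correlation with the module mean expression is >= 0.
module_eigengene <- function(expr_mod) {
  z <- scale(expr_mod)
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 1, nv = 0)
  e <- sv$u[, 1]
  avg <- rowMeans(z)
  if (stats::sd(avg) > 0 && suppressWarnings(stats::cor(e, avg)) < 0) e <- -e
  e
}

#' Detect coexpression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, branch labelling by
#' a recursive tree-variant dynamic cut (static cut at 99 percent of the dendrogram
#' height range, branches split while both pieces hold at least
#' `minModuleSize` genes), clusters below `minModuleSize` assigned to
#' `"grey"`, and iterative merging of modules whose eigengene dissimilarity
#' `1 - cor` falls below `merge_height`.
#'
#' @param tom Square symmetric TOM similarity matrix (dimnames = genes).
#' @param expr Observations x genes matrix used for eigengenes (same genes
#'   as `tom`).
#' @param minModuleSize Smallest allowed module.
#' @param merge_height Eigengene dissimilarity below which modules merge.
#' @param min_kme Module-membership filter: genes whose correlation with
#'   their module eigengene falls below this are released to `"grey"`
#'   (the standard kME criterion that keeps loosely attached genes out of
#'   modules); a module dropping below `minModuleSize` dissolves.
#' @return A `ModuleAssignment` list: `module` (named gene labels, `"grey"`
#'   = unassigned), `eigengenes` (observations x modules, unit-norm columns),
#'   `dendrogram` (the hclust), and slots `beta`/`trait_stats` filled by the
#'   callers that know them.
#' @export
detect_modules <- function(tom, expr, minModuleSize = 10, merge_height = 0.25,
                           min_kme = 0.3) {
  stopifnot(nrow(tom) == ncol(tom), ncol(expr) == ncol(tom))
  genes <- colnames(tom)
  if (is.null(genes)) genes <- colnames(expr)
  if (nrow(tom) < minModuleSize) {
    warning("fewer genes than minModuleSize; all genes unassigned")
    return(structure(list(
      module = stats::setNames(rep("grey", nrow(tom)), genes),
      eigengenes = matrix(numeric(0), nrow(expr), 0),
      dendrogram = NULL, beta = NA_integer_, trait_stats = NULL),
      class = "ModuleAssignment"))
  }
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- tree_dynamic_cut(hc, minModuleSize)
  labels <- ifelse(raw == 0L, "grey", paste0("module", raw))
  names(labels) <- genes

  compute_eigengenes <- function(labels) {
    mods <- setdiff(sort(unique(labels)), "grey")
    if (!length(mods))
      return(matrix(numeric(0), nrow(expr), 0))
    e <- vapply(mods, function(mm)
      module_eigengene(expr[, labels == mm, drop = FALSE]),
      numeric(nrow(expr)))
    colnames(e) <- mods
    rownames(e) <- rownames(expr)
    e
  }
  eg <- compute_eigengenes(labels)

  ## iterative eigengene merging
  repeat {
    if (ncol(eg) < 2) break
    ec <- suppressWarnings(stats::cor(eg))
    ec[!is.finite(ec)] <- 0
    ediss <- 1 - ec
    diag(ediss) <- Inf
    if (min(ediss) >= merge_height) break
    idx <- which(ediss == min(ediss), arr.ind = TRUE)[1, ]
    m1 <- colnames(eg)[idx[1]]; m2 <- colnames(eg)[idx[2]]
    labels[labels == m2] <- m1
    eg <- compute_eigengenes(labels)
  }

  ## kME membership filter: release loosely attached genes to grey
  if (min_kme > 0 && ncol(eg)) {
    repeat {
      changed <- FALSE
      for (mm in setdiff(unique(labels), "grey")) {
        members <- which(labels == mm)
        kme <- suppressWarnings(
          as.vector(stats::cor(expr[, members, drop = FALSE], eg[, mm])))
        kme[!is.finite(kme)] <- 0
        drop <- members[kme < min_kme]
        if (length(drop)) {
          labels[drop] <- "grey"
          changed <- TRUE
        }
        if (sum(labels == mm) < minModuleSize) {
          labels[labels == mm] <- "grey"
          changed <- TRUE
        }
      }
      if (!changed) break
      eg <- compute_eigengenes(labels)
      if (!ncol(eg)) break
    }
  }

  ## stable renaming by module size
  mods <- setdiff(unique(labels), "grey")
  if (length(mods)) {
    sizes <- vapply(mods, function(mm) sum(labels == mm), integer(1))
    new_names <- stats::setNames(paste0("module", seq_along(mods)),
                                 mods[order(-sizes, mods)])
    labels[labels != "grey"] <- new_names[labels[labels != "grey"]]
    eg <- compute_eigengenes(labels)
  }
  structure(list(module = labels, eigengenes = eg, dendrogram = hc,
                 beta = NA_integer_, trait_stats = NULL),
            class = "ModuleAssignment")
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  tab <- table(x$module)
  cat("ModuleAssignment:", sum(names(tab) != "grey"), "modules\n")
  print(tab)
  invisible(x)
}

#' Module-trait Pearson correlation
#'
#' Pearson `r` and the two-sided t-test p-value between each module eigengene
#' and each numeric-coded trait column (binary traits coded 0/1, ordered
#' stage 1..4). Missing trait values are pairwise-deleted; a constant trait
#' yields `NA`.
#'
#' @param assignment A `ModuleAssignment` with eigengenes.
#' @param traits Data frame of numeric covariates aligned to the eigengene
#'   observation axis.
#' @return The assignment with `trait_stats` filled: a `data.frame`
#'   (module, trait, r, p).
#' @export
module_trait_correlation <- function(assignment, traits) {
  eg <- assignment$eigengenes
  if (!ncol(eg)) {
    assignment$trait_stats <- data.frame(module = character(0),
                                         trait = character(0),
                                         r = numeric(0), p = numeric(0))
    return(assignment)
  }
  stopifnot(nrow(traits) == nrow(eg))
  rows <- list()
  for (mod in colnames(eg)) for (tr in colnames(traits)) {
    x <- eg[, mod]; y <- as.numeric(traits[[tr]])
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(module = mod, trait = tr,
                                              r = NA_real_, p = NA_real_)
    } else {
      ct <- stats::cor.test(x[ok], y[ok])
      rows[[length(rows) + 1L]] <- data.frame(module = mod, trait = tr,
                                              r = unname(ct$estimate),
                                              p = ct$p.value)
    }
  }
  assignment$trait_stats <- do.call(rbind, rows)
  assignment
}

#' Select score genes from trait-associated modules
#'
#' Returns the union of genes in non-grey modules whose eigengene correlates
#' with at least one of the listed traits at `p < alpha`.
#'
#' @param assignment A `ModuleAssignment` with `trait_stats` computed.
#' @param alpha Significance threshold.
#' @param traits Trait names to consider; default all traits present.
#' @return Character vector of gene names (possibly empty, with a warning).
#' @export
select_score_genes <- function(assignment, alpha = 0.05, traits = NULL) {
  ts <- assignment$trait_stats
  if (is.null(ts)) stop("run module_trait_correlation first")
  if (!is.null(traits)) ts <- ts[ts$trait %in% traits, , drop = FALSE]
  sig <- unique(ts$module[!is.na(ts$p) & ts$p < alpha])
  sig <- setdiff(sig, "grey")
  if (!length(sig)) {
    warning("no module significantly associated with the listed traits")
    return(character(0))
  }
  names(assignment$module)[assignment$module %in% sig]
}
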