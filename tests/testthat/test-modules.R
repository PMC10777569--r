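test_that("signed adjacency and TOM obey their closed forms and bounds", {
  set.seed(1)
  expr <- matrix(rnorm(200), 20, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  a <- signed_adjacency(expr, beta = 6)
  expect_true(all(a >= 0 & a <= 1))
  expect_true(all(diag(a) == 0))
  tom <- build_tom(expr, beta = 6)
  expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom))
  # elementwise lower bound TOM >= a / (min k + 1)
  k <- colSums(a)
  lower <- a / (outer(k, k, pmin) + 1)
  diag(lower) <- 1
  expect_true(all(tom >= lower - 1e-12))

  # 2-gene network: TOM_12 = a_12
  e2 <- expr[, 1:2]
  a2 <- signed_adjacency(e2, beta = 3)
  expect_equal(build_tom(e2, beta = 3)[1, 2], a2[1, 2])

  # identical genes in a 2-gene network have perfect overlap
  e_dup <- cbind(g1 = expr[, 1], g2 = expr[, 1])
  expect_equal(build_tom(e_dup, beta = 3)[1, 2], 1)

  # permutation equivariance
  perm <- sample(10)
  expect_equal(build_tom(expr[, perm], beta = 6),
               tom[perm, perm], ignore_attr = TRUE)
})

test_that("soft threshold picks the smallest qualifying power", {
  # a fit table that already qualifies at beta = 1 returns 1
  sim <- simulate_module_matrix(n_obs = 300, n_modules = 3, module_size = 40,
                                within_cor = 0.5, loading_range = c(0.02, 0.95),
                                seed = 7)
  b <- pick_soft_threshold(sim$expr, r2_target = -1)
  expect_identical(as.integer(b), 1L)
  # hub-structured data reach the scale-free criterion at some power
  b2 <- pick_soft_threshold(sim$expr, r2_target = 0.8)
  tab <- attr(b2, "fit_table")
  expect_true(attr(b2, "reached"))
  expect_true(all(tab$rsq[tab$power < as.integer(b2)] < 0.8))
  expect_gte(tab$rsq[tab$power == as.integer(b2)], 0.8)
  # equal-loading modular data cannot look scale-free: fallback with warning
  eq <- simulate_module_matrix(n_obs = 200, n_modules = 4, module_size = 25,
                               within_cor = 0.7, seed = 3)
  expect_warning(b3 <- pick_soft_threshold(eq$expr), "best fit")
  expect_false(attr(b3, "reached"))
  expect_error(pick_soft_threshold(sim$expr[1:2, ]), ">= 3 observations")
})

test_that("two perfectly separated blocks give exactly their two modules", {
  set.seed(2)
  n <- 100
  f1 <- rnorm(n)
  f2 <- residuals(lm(rnorm(n) ~ f1))   # exactly orthogonal to f1
  expr <- cbind(matrix(f1, n, 15), matrix(f2, n, 15))
  colnames(expr) <- paste0("g", 1:30)
  tom <- build_tom(expr, beta = 6)
  ma <- detect_modules(tom, expr)
  expect_length(setdiff(unique(ma$module), "grey"), 2)
  expect_length(unique(ma$module[1:15]), 1)
  expect_length(unique(ma$module[16:30]), 1)
  expect_false(ma$module[1] == ma$module[16])
})

test_that("clusters below minModuleSize fall to grey", {
  set.seed(3)
  f <- rnorm(50)
  expr <- sapply(1:5, function(i) f + 0.1 * rnorm(50))
  colnames(expr) <- paste0("g", 1:5)
  tom <- build_tom(expr, beta = 6)
  expect_warning(ma <- detect_modules(tom, expr, minModuleSize = 10),
                 "fewer genes")
  expect_true(all(ma$module == "grey"))
})

test_that("modules with eigengene dissimilarity below 0.25 are merged", {
  set.seed(4)
  n <- 400
  f1 <- rnorm(n)
  f2 <- 0.85 * f1 + sqrt(1 - 0.85^2) * rnorm(n)   # eigengene cor ~ 0.85
  f3 <- rnorm(n)
  mk <- function(f, size, rho = 0.9)
    sapply(seq_len(size), function(i) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
  expr <- cbind(mk(f1, 15), mk(f2, 15), mk(f3, 15))
  colnames(expr) <- paste0("g", 1:45)
  tom <- build_tom(expr, beta = 6)
  ma <- detect_modules(tom, expr, merge_height = 0.25)
  mods <- setdiff(unique(ma$module), "grey")
  expect_length(mods, 2)
  # the two correlated blocks share a label; oracle: their eigengene cor
  e1 <- prcomp(scale(expr[, 1:15]))$x[, 1]
  e2 <- prcomp(scale(expr[, 16:30]))$x[, 1]
  expect_gt(abs(cor(e1, e2)), 1 - 0.25)
  expect_identical(unname(ma$module[1]), unname(ma$module[16]))
  expect_false(ma$module[1] == ma$module[31])
})

test_that("module labels are invariant to gene input order", {
  sim <- simulate_module_matrix(n_obs = 300, n_modules = 3, module_size = 15,
                                within_cor = 0.8, n_noise_genes = 10, seed = 5)
  tom <- build_tom(sim$expr, beta = 8)
  ma <- detect_modules(tom, sim$expr)
  perm <- sample(ncol(sim$expr))
  tom_p <- build_tom(sim$expr[, perm], beta = 8)
  ma_p <- detect_modules(tom_p, sim$expr[, perm])
  # same partition up to label renaming
  expect_equal(mclust::adjustedRandIndex(ma$module[perm], ma_p$module), 1)
})

test_that("eigengenes are unit norm and oriented with module expression", {
  sim <- simulate_module_matrix(n_obs = 200, n_modules = 2, module_size = 15,
                                within_cor = 0.8, seed = 6)
  ma <- detect_modules(build_tom(sim$expr, beta = 8), sim$expr)
  for (j in seq_len(ncol(ma$eigengenes))) {
    e <- ma$eigengenes[, j]
    expect_equal(sum(e^2), 1, tolerance = 1e-8)
    avg <- rowMeans(scale(sim$expr[, ma$module == colnames(ma$eigengenes)[j]]))
    expect_gte(cor(e, avg), 0)
  }
})

test_that("module-trait correlation matches closed-form Pearson", {
  sim <- simulate_module_matrix(n_obs = 150, n_modules = 2, module_size = 15,
                                within_cor = 0.8, seed = 8)
  ma <- detect_modules(build_tom(sim$expr, beta = 8), sim$expr)
  # trait equal to an eigengene: r = 1, p ~ 0
  traits <- data.frame(t_self = ma$eigengenes[, 1],
                       t_binary = rep(c(0, 1), 75),
                       t_const = rep(1, 150))
  ma <- module_trait_correlation(ma, traits)
  ts <- ma$trait_stats
  self_row <- ts[ts$module == colnames(ma$eigengenes)[1] & ts$trait == "t_self", ]
  expect_equal(self_row$r, 1, tolerance = 1e-10)
  expect_lt(self_row$p, 1e-100)
  expect_true(all(is.na(ts$r[ts$trait == "t_const"])))
  # closed-form check on 5 printed pairs
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1); y <- c(0.5, 1.1, 0.7, 2.0, 1.3)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cor(x, y), r_closed, tolerance = 1e-12)
})

test_that("score genes come exactly from trait-linked modules", {
  set.seed(9)
  sim <- simulate_module_matrix(n_obs = 400, n_modules = 3, module_size = 15,
                                within_cor = 0.8, n_noise_genes = 10, seed = 9)
  ma <- detect_modules(build_tom(sim$expr, beta = 8), sim$expr)
  # trait tied to planted module1's mean expression; others independent
  m1_genes <- names(sim$module)[sim$module == "module1"]
  traits <- data.frame(linked = rowMeans(sim$expr[, m1_genes]) + 0.2 * rnorm(400),
                       free = rnorm(400))
  ma <- module_trait_correlation(ma, traits)
  sel <- select_score_genes(ma, alpha = 1e-6, traits = "linked")
  # the trait-linked selection returns exactly the detected module that
  # carries the planted genes (detection may absorb a stray noise gene)
  lab1 <- names(which.max(table(ma$module[m1_genes])))
  expect_setequal(sel, names(ma$module)[ma$module == lab1])
  expect_true(all(m1_genes %in% sel))
  # no qualifying module -> empty with warning
  ma2 <- module_trait_correlation(ma, data.frame(pure_noise = rnorm(400)))
  expect_warning(out <- select_score_genes(ma2, alpha = 1e-12), "no module")
  expect_length(out, 0)
})
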