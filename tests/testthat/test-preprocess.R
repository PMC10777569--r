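make_qc_matrix <- function() {
  # 5 cells x 400 genes incl. one mito gene; crafted detection counts
  n_genes <- 400
  genes <- c("MT-1", sprintf("g%03d", seq_len(n_genes - 1)))
  counts <- matrix(0L, 5, n_genes,
                   dimnames = list(paste0("c", 1:5), genes))
  counts[1, 2:300] <- 1L            # 299 detected genes -> removed
  counts[2, 2:301] <- 1L            # 300 detected genes -> retained
  counts[3, 2:301] <- 1L
  counts[4, 2:301] <- 1L
  counts[5, 2:301] <- 1L
  CountMatrix(counts)
}

test_that("cell filters use strict boundaries from the stated thresholds", {
  m <- make_qc_matrix()
  out <- suppressMessages(qc_filter(m, min_cells_per_gene = 0))
  expect_setequal(cell_names(out), c("c2", "c3", "c4", "c5"))

  # mito fraction boundary: > 0.08 removed, exactly 0.08 retained
  counts <- matrix(0L, 2, 1000,
                   dimnames = list(c("a", "b"), c("MT-1", sprintf("g%03d", 1:999))))
  counts["a", "MT-1"] <- 80L; counts["a", 1 + 1:920] <- 1L  # 80/1000 = 0.080
  counts["b", "MT-1"] <- 81L; counts["b", 1 + 1:919] <- 1L  # 81/1000 = 0.081
  m2 <- CountMatrix(counts)
  out2 <- suppressMessages(qc_filter(m2, min_genes_per_cell = 0,
                                     min_cells_per_gene = 0))
  expect_identical(cell_names(out2), "a")
})

test_that("gene filter keeps genes detected in >= 3 retained cells", {
  counts <- matrix(0L, 4, 320,
                   dimnames = list(paste0("c", 1:4), sprintf("g%03d", 1:320)))
  counts[, 1:318] <- 1L
  counts[1:2, 319] <- 1L            # detected in 2 cells -> removed
  counts[1:3, 320] <- 1L            # detected in 3 cells -> retained
  m <- CountMatrix(counts)
  out <- suppressMessages(qc_filter(m, min_genes_per_cell = 0))
  expect_false("g319" %in% gene_names(out))
  expect_true("g320" %in% gene_names(out))
})

test_that("qc_filter errors when nothing survives and is idempotent", {
  m <- make_qc_matrix()
  expect_error(suppressMessages(qc_filter(m, min_genes_per_cell = 1000)),
               "every cell")
  sim <- small_sim(400, 400, seed = 3)
  once <- suppressMessages(qc_filter(sim$matrix))
  twice <- suppressMessages(qc_filter(once))
  expect_identical(dim(twice), dim(once))
})

test_that("lognormalize matches its closed form and preserves rank order", {
  counts <- matrix(c(1L, 3L, 0L, 0L, 2L, 2L), 2, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  m <- lognormalize(CountMatrix(counts))
  norm <- get_layer(m, "normalized")
  expect_equal(norm["c1", "g1"], log(1 + 1e4 * 1 / 4))
  expect_equal(norm["c1", "g3"], 0)
  # monotone within cell: order of values matches order of counts
  expect_identical(order(norm["c2", ]), order(counts["c2", ]))
  empty_cell <- CountMatrix(matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE,
                                   dimnames = list(c("c1", "c2"), c("g1", "g2"))))
  expect_error(lognormalize(empty_cell), "zero total")
})

test_that("scale_genes centers, unit-scales, clips, zeroes constant genes", {
  sim <- small_sim(100, 120, seed = 5)
  m <- scale_genes(lognormalize(sim$matrix))
  centered <- get_layer(m, "centered")
  scaled <- get_layer(m, "scaled")
  expect_lt(max(abs(colMeans(centered))), 1e-10)
  sds <- apply(scaled, 2, sd)
  nonclipped <- apply(abs(scaled) < 10, 2, all) & apply(centered, 2, sd) > 0
  expect_equal(unname(sds[nonclipped]), rep(1, sum(nonclipped)),
               tolerance = 1e-8)
  # a gene constant after normalization is centered and scaled to exactly 0
  counts <- matrix(c(2L, 1L, 3L,
                     4L, 2L, 6L), 2, 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
  mm <- scale_genes(lognormalize(CountMatrix(counts)))
  expect_equal(unname(get_layer(mm, "centered")[, "g3"]), c(0, 0))
  expect_equal(unname(get_layer(mm, "scaled")[, "g3"]), c(0, 0))
})

test_that("normalization and scaling commute with cell/gene permutation", {
  sim <- small_sim(60, 80, seed = 9)
  m <- sim$matrix
  pc <- sample(nrow(m$counts)); pg <- sample(ncol(m$counts))
  a <- get_layer(scale_genes(lognormalize(m[pc, pg])), "scaled")
  b <- get_layer(scale_genes(lognormalize(m)), "scaled")[pc, pg]
  expect_equal(a, b)
})

test_that("variable-gene selection ranks planted high-variance genes first", {
  sim <- small_sim(500, 500, seed = 11, n_modules = 4, module_size = 25)
  m <- suppressMessages(qc_filter(sim$matrix))
  hvg <- select_hvg(m, n = 150)
  markers <- intersect(sim$truth$epithelial_markers, gene_names(m))
  expect_gt(mean(markers %in% hvg), 0.8)
  # full ranking returns every gene exactly once
  all_genes <- select_hvg(m, n = ncol(m$counts))
  expect_setequal(all_genes, gene_names(m))
  expect_error(select_hvg(m, n = 0), "positive")
  # a constant gene never outranks a variable one
  counts <- matrix(rpois(600, 5), 30, 20,
                   dimnames = list(sprintf("c%02d", 1:30), sprintf("g%02d", 1:20)))
  counts[, 1] <- 3L
  ranked <- suppressWarnings(select_hvg(CountMatrix(counts), n = 20))
  expect_identical(ranked[20], "g01")
})
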