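#' Configuration for the synthetic single-cell data generator
#'
#' Collects every knob of the simulator into a validated list. The defaults
#' describe the conditions the downstream validation suite assumes: a
#' moderately deep negative-binomial count matrix with four planted regulator
#' modules correlated with per-cell traits, a malignant epithelial subclone
#' carrying a contiguous copy-number gain, a low-score subpopulation with
#' down-shifted regulator expression, planted ligand-receptor pairs, and a
#' flagged mitochondrial gene block so QC is exercisable.
#'
#' @param n_cells,n_genes Matrix dimensions (cells include all types).
#' @param n_cell_types Number of cell types; type 1 is `"Epithelial"`.
#' @param nb_mean Baseline negative-binomial mean per gene before per-gene
#'   and per-cell variation.
#' @param nb_dispersion Negative-binomial `size` parameter (smaller = more
#'   overdispersed).
#' @param n_modules,module_size Number and size of planted regulator modules.
#' @param module_trait_cor Target correlation between each module's latent
#'   factor and its emitted per-cell trait, in `[-1, 1]`.
#' @param module_amplitude Log2-scale standard deviation of the latent-factor
#'   effect on module gene means.
#' @param malignant_fraction Fraction of all cells flagged malignant (drawn
#'   from the epithelial type).
#' @param cnv_block List `(chrom, start_gene_index, n_genes, log2_fold)`
#'   describing a contiguous copy-number shift applied to malignant cells;
#'   `start_gene_index` is 1-based within the chromosome.
#' @param score_shift Log2 down-shift applied to regulator genes in the
#'   planted "low" subpopulation (0 disables the shift).
#' @param lr_pairs_planted Data frame with columns `ligand`, `receptor`,
#'   `sender_type`, `receiver_type` naming genes (by index into the gene
#'   vector via `"G%04d"` symbols) elevated in the designated types; `NULL`
#'   plants the single default pair.
#' @param n_extra_regulators Regulator-list padding: non-module genes added to
#'   the emitted regulator list so module selection is non-trivial.
#' @param n_marker_genes Number of epithelial marker genes elevated in the
#'   epithelial type (0 makes cell-type labels fully exchangeable, the null
#'   condition for interaction-test calibration).
#' @param survival_hr Hazard ratio of the "low" vs "high" group used by
#'   [generate_survival()] defaults and stored in the truth.
#' @param censor_rate Probability that a subject is censored.
#' @param mito_fraction_shape Beta shape parameters `c(a, b)` for healthy-cell
#'   mitochondrial fractions.
#' @param dying_fraction Fraction of cells given a high mitochondrial load
#'   (Beta(8, 10)) so the 8 percent QC cut removes a known set.
#' @param library_size_sd Log-normal sigma of per-cell library-size factors.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 1000, n_cell_types = 4,
                       nb_mean = 2, nb_dispersion = 2,
                       n_modules = 4, module_size = 30,
                       module_trait_cor = 0.6, module_amplitude = 0.8,
                       malignant_fraction = 0.15,
                       cnv_block = list(chrom = 3L, start_gene_index = 11L,
                                        n_genes = 150L, log2_fold = 1),
                       score_shift = 1.0, lr_pairs_planted = NULL,
                       n_extra_regulators = 100, n_marker_genes = 20,
                       survival_hr = 2, censor_rate = 0.3,
                       mito_fraction_shape = c(2, 30), dying_fraction = 0.05,
                       library_size_sd = 0.3, seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_cells >= 1, n_genes >= 1, n_cell_types >= 1,
              nb_mean > 0, nb_dispersion > 0,
              n_modules >= 0, module_size >= 1,
              module_trait_cor >= -1, module_trait_cor <= 1,
              malignant_fraction >= 0, malignant_fraction <= 1,
              score_shift >= 0, survival_hr > 0,
              censor_rate >= 0, censor_rate <= 1,
              dying_fraction >= 0, dying_fraction <= 1)
  })
  n_mito <- 13L
  if (cfg$n_modules * cfg$module_size + n_mito > cfg$n_genes)
    stop("module_size * n_modules exceeds available genes")
  if (is.null(cfg$lr_pairs_planted)) {
    cfg$lr_pairs_planted <- data.frame(
      ligand = "G0901", receptor = "G0902",
      sender_type = "Epithelial", receiver_type = "Type2",
      stringsAsFactors = FALSE)
    if (cfg$n_genes - 13L < 902) cfg$lr_pairs_planted <- cfg$lr_pairs_planted[0, ]
  }
  cfg$seed <- as.integer(seed)
  class(cfg) <- "SimConfig"
  cfg
}

#' Gene coordinate table for simulated genes
#'
#' Genes are laid out sequentially over 5 pseudo-chromosomes, 1 kb per gene,
#' 0-based half-open intervals, in matrix column order.
#'
#' @param gene_names Character vector of gene symbols in matrix order.
#' @return BED-like `data.frame` with `chrom`, `start`, `end`, `gene`.
#' @export
simulated_gene_coords <- function(gene_names) {
  n <- length(gene_names)
  per_chrom <- ceiling(n / 5)
  chrom_id <- (seq_len(n) - 1L) %/% per_chrom + 1L
  within <- (seq_len(n) - 1L) %% per_chrom
  data.frame(chrom = paste0("chr", chrom_id),
             start = within * 1000L, end = within * 1000L + 1000L,
             gene = gene_names, stringsAsFactors = FALSE)
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws a cells x genes negative-binomial count matrix under the structure
#' described by [sim_config()]: per-gene baseline means with log-normal
#' spread, log-normal library-size factors, planted coexpression modules
#' whose latent factors correlate with emitted per-cell traits, a "low"
#' subpopulation with regulator genes scaled by `2^-score_shift`, malignant
#' epithelial cells with a contiguous `2^log2_fold` copy-number block,
#' type-restricted ligand/receptor elevation, epithelial marker genes, and a
#' 13-gene `MT-` block whose per-cell fraction follows a Beta mixture.
#'
#' @param config A `SimConfig` from [sim_config()].
#' @return A list with elements `matrix` (a [CountMatrix]) and `truth`
#'   (class `SyntheticTruth`): per-cell `group` ("high"/"low"), per-gene
#'   `gene_module` labels, `malignant` flags, `regulators`,
#'   `epithelial_markers`, `cnv_genes`, `planted_pairs`, `dying_cells`, and
#'   per-cell `hazard_multiplier`.
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  set.seed(cfg$seed)
  n_mito <- 13L
  gene_names <- c(paste0("MT-", seq_len(n_mito)),
                  sprintf("G%04d", seq_len(cfg$n_genes - n_mito)))
  cell_names <- sprintf("cell%05d", seq_len(cfg$n_cells))
  coords <- simulated_gene_coords(gene_names)

  ## gene layout: MT block first, then a contiguous CNV block on its
  ## chromosome; module and marker genes are scattered across the genome
  ## (coexpression modules and marker panels are not genomically clustered,
  ## and contiguous placement would mimic copy-number signal)
  cnv_idx <- integer(0)
  if (!is.null(cfg$cnv_block)) {
    blk <- cfg$cnv_block
    chrom_genes <- which(coords$chrom == paste0("chr", blk$chrom))
    if (length(chrom_genes) < blk$start_gene_index + blk$n_genes - 1L)
      stop("cnv_block out of gene range for its chromosome")
    cnv_idx <- chrom_genes[blk$start_gene_index + seq_len(blk$n_genes) - 1L]
  }
  lr_idx <- if (NROW(cfg$lr_pairs_planted))
    match(unique(c(cfg$lr_pairs_planted$ligand, cfg$lr_pairs_planted$receptor)),
          gene_names)
  else integer(0)
  free <- setdiff(seq_len(cfg$n_genes), c(seq_len(n_mito), cnv_idx, lr_idx))
  picked <- sample(free, cfg$n_modules * cfg$module_size)
  module_idx <- split(picked, rep(seq_len(cfg$n_modules),
                                  each = cfg$module_size))
  module_genes <- unlist(module_idx)
  free <- setdiff(free, module_genes)
  n_marker <- min(cfg$n_marker_genes, length(free))
  marker_idx <- sort(sample(free, n_marker))
  gene_module <- rep("grey", cfg$n_genes)
  for (m in seq_len(cfg$n_modules))
    gene_module[module_idx[[m]]] <- paste0("module", m)
  names(gene_module) <- gene_names

  non_module <- setdiff(free, marker_idx)
  extra_reg <- if (cfg$n_extra_regulators > 0 && length(non_module))
    sort(sample(non_module, min(cfg$n_extra_regulators, length(non_module))))
  else integer(0)
  regulators <- gene_names[c(module_genes, extra_reg)]

  ## cell structure
  type_names <- c("Epithelial", paste0("Type", seq_len(max(cfg$n_cell_types - 1L, 0L)) + 1L))
  type_prob <- c(0.4, rep(0.6 / max(cfg$n_cell_types - 1L, 1L),
                          max(cfg$n_cell_types - 1L, 0L)))
  if (cfg$n_cell_types == 1L) { type_names <- "Epithelial"; type_prob <- 1 }
  cell_type <- sample(type_names, cfg$n_cells, replace = TRUE, prob = type_prob)
  group <- sample(rep(c("high", "low"), length.out = cfg$n_cells))
  epi_cells <- which(cell_type == "Epithelial")
  n_mal <- min(round(cfg$malignant_fraction * cfg$n_cells), length(epi_cells))
  malignant <- rep(FALSE, cfg$n_cells)
  if (n_mal > 0) malignant[sample(epi_cells, n_mal)] <- TRUE
  dying <- stats::runif(cfg$n_cells) < cfg$dying_fraction

  ## mean construction on the log2 scale
  gene_base <- cfg$nb_mean * stats::rlnorm(cfg$n_genes, 0, 1)
  libsize <- stats::rlnorm(cfg$n_cells, 0, cfg$library_size_sd)
  log2mu <- matrix(0, cfg$n_cells, cfg$n_genes)

  traits <- matrix(NA_real_, cfg$n_cells, cfg$n_modules,
                   dimnames = list(cell_names,
                                   if (cfg$n_modules) paste0("trait", seq_len(cfg$n_modules))))
  rho <- cfg$module_trait_cor
  for (m in seq_len(cfg$n_modules)) {
    z <- stats::rnorm(cfg$n_cells)
    traits[, m] <- rho * z + sqrt(max(0, 1 - rho^2)) * stats::rnorm(cfg$n_cells)
    log2mu[, module_idx[[m]]] <- log2mu[, module_idx[[m]], drop = FALSE] +
      cfg$module_amplitude * z
  }
  if (cfg$score_shift > 0 && length(regulators)) {
    reg_idx <- match(regulators, gene_names)
    low <- group == "low"
    log2mu[low, reg_idx] <- log2mu[low, reg_idx, drop = FALSE] - cfg$score_shift
  }
  if (n_marker > 0) {
    epi <- cell_type == "Epithelial"
    log2mu[epi, marker_idx] <- log2mu[epi, marker_idx, drop = FALSE] + 2
  }
  cnv_genes <- character(0)
  if (length(cnv_idx) && any(malignant)) {
    log2mu[malignant, cnv_idx] <- log2mu[malignant, cnv_idx, drop = FALSE] +
      cfg$cnv_block$log2_fold
    cnv_genes <- gene_names[cnv_idx]
  }
  pairs <- cfg$lr_pairs_planted
  if (NROW(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      li <- match(pairs$ligand[r], gene_names)
      ri <- match(pairs$receptor[r], gene_names)
      if (is.na(li) || is.na(ri)) stop("planted pair gene not in gene list")
      snd <- cell_type == pairs$sender_type[r]
      rcv <- cell_type == pairs$receiver_type[r]
      log2mu[snd, li] <- log2mu[snd, li] + 2.5
      log2mu[rcv, ri] <- log2mu[rcv, ri] + 2.5
    }
  }

  mu <- 2^log2mu * rep(gene_base, each = cfg$n_cells) * libsize

  ## mitochondrial load: scale MT means to hit a drawn per-cell fraction
  mito_frac <- stats::rbeta(cfg$n_cells, cfg$mito_fraction_shape[1],
                            cfg$mito_fraction_shape[2])
  mito_frac[dying] <- stats::rbeta(sum(dying), 8, 10)
  mito_cols <- seq_len(n_mito)
  non_mito_total <- rowSums(mu[, -mito_cols, drop = FALSE])
  mt_base <- gene_base[mito_cols] / sum(gene_base[mito_cols])
  target_mt_total <- mito_frac / (1 - mito_frac) * non_mito_total
  mu[, mito_cols] <- outer(target_mt_total, mt_base)

  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                  size = cfg$nb_dispersion),
                   cfg$n_cells, cfg$n_genes,
                   dimnames = list(cell_names, gene_names))

  meta <- data.frame(sample = paste0("S", 1L + (seq_len(cfg$n_cells) %% 4L)),
                     condition = ifelse(malignant, "tumor", "normal"),
                     cell_type = cell_type, group = group,
                     row.names = cell_names, stringsAsFactors = FALSE)
  meta <- cbind(meta, as.data.frame(traits))

  truth <- structure(list(
    group = stats::setNames(group, cell_names),
    gene_module = gene_module,
    malignant = stats::setNames(malignant, cell_names),
    regulators = regulators,
    epithelial_markers = gene_names[marker_idx],
    cnv_genes = cnv_genes,
    planted_pairs = pairs,
    dying_cells = cell_names[dying],
    mito_fraction = stats::setNames(mito_frac, cell_names),
    hazard_multiplier = stats::setNames(
      ifelse(group == "low", cfg$survival_hr, 1), cell_names),
    traits = traits,
    coords = coords), class = "SyntheticTruth")

  list(matrix = CountMatrix(counts, cell_meta = meta), truth = truth)
}

#' Gaussian matrix with planted coexpression modules
#'
#' Generates an observations x genes matrix where each module's genes load on
#' a shared standard-normal factor so that the pairwise within-module
#' correlation equals `within_cor` in expectation; noise genes are
#' independent. Used to validate module detection against a known partition.
#'
#' @param n_obs,n_modules,module_size Dimensions of the planted structure.
#' @param within_cor Expected within-module pairwise correlation in `[0, 1)`
#'   when `loading_range` is `NULL`.
#' @param n_noise_genes Additional independent genes labelled `"grey"`.
#' @param loading_range Optional length-2 range; when given, each module
#'   gene's squared factor loading is drawn uniformly from it, producing the
#'   hub-dominated connectivity heterogeneity that scale-free network fits
#'   presume (with equal loadings the degree distribution is near-uniform
#'   and no soft power yields a scale-free fit).
#' @param seed Integer seed.
#' @return List with `expr` (matrix) and `module` (character truth labels).
#' @export
simulate_module_matrix <- function(n_obs = 500, n_modules = 4,
                                   module_size = 25, within_cor = 0.7,
                                   n_noise_genes = 0, loading_range = NULL,
                                   seed = 1L) {
  stopifnot(within_cor >= 0, within_cor < 1)
  set.seed(as.integer(seed))
  n_genes <- n_modules * module_size + n_noise_genes
  expr <- matrix(stats::rnorm(n_obs * n_genes), n_obs, n_genes)
  module <- rep("grey", n_genes)
  for (m in seq_len(n_modules)) {
    idx <- (m - 1L) * module_size + seq_len(module_size)
    f <- stats::rnorm(n_obs)
    rho <- if (is.null(loading_range)) rep(within_cor, length(idx))
           else stats::runif(length(idx), loading_range[1], loading_range[2])
    expr[, idx] <- sweep(matrix(f, n_obs, length(idx)), 2, sqrt(rho), "*") +
      sweep(expr[, idx, drop = FALSE], 2, sqrt(1 - rho), "*")
    module[idx] <- paste0("module", m)
  }
  colnames(expr) <- sprintf("G%04d", seq_len(n_genes))
  rownames(expr) <- sprintf("obs%04d", seq_len(n_obs))
  names(module) <- colnames(expr)
  list(expr = expr, module = module)
}

#' Simulate a survival table for labelled subjects
#'
#' Event times are exponential with baseline rate `baseline_rate` scaled by
#' `hr` for the `"low"` group. Censoring times are independent exponentials
#' whose rate is set per subject so that the probability of being censored
#' is exactly `censor_rate` (conditionally independent censoring, so Cox
#' estimates stay unbiased); the observed time is the minimum of the two.
#'
#' @param groups Character/factor vector of per-subject labels containing
#'   `"low"` for the elevated-hazard group.
#' @param hr Hazard ratio (> 0) of `"low"` vs the rest.
#' @param censor_rate Censoring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param baseline_rate Baseline exponential hazard rate.
#' @return `data.frame` with `id`, `time`, `event` (0/1) and `group`.
#' @export
generate_survival <- function(groups, hr = 2, censor_rate = 0.3, seed = 1L,
                              baseline_rate = 0.1) {
  if (!length(groups)) stop("empty group vector")
  stopifnot(hr > 0, censor_rate >= 0, censor_rate < 1)
  set.seed(as.integer(seed))
  n <- length(groups)
  rate <- baseline_rate * ifelse(groups == "low", hr, 1)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    c_rate <- rate * censor_rate / (1 - censor_rate)  # P(C < T) = censor_rate
    t_cens <- stats::rexp(n, c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(id = if (!is.null(names(groups))) names(groups)
             else sprintf("s%04d", seq_len(n)),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = as.character(groups), stringsAsFactors = FALSE)
}
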