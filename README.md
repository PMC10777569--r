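# rloopscore

Quantifying R-loop regulator activity in single-cell and bulk transcriptomes,
and carrying that quantity through the downstream analyses a tumor
single-cell study needs.

R-loops — three-stranded nucleic-acid structures (RNA:DNA hybrid plus a
displaced single strand) formed during transcription — influence genome
stability and tumor progression, but leave no direct footprint in RNA-seq.
What is measurable is the expression program of the genes that regulate
R-loop formation and resolution. `rloopscore` turns a cells × genes count
matrix and a regulator gene list into:

1. **QC / normalization / variable genes** — strict-boundary cell and gene
   filters (≥ 300 detected genes, ≤ 8% mitochondrial counts, genes in ≥ 3
   cells), library-size log-normalization, variance-stabilized
   variable-gene ranking, per-gene scaling.
2. **Regulator modules** — a signed weighted coexpression network over the
   regulator list: soft threshold by the scale-free topology criterion,
   topological overlap, dynamic tree-cut module detection with eigengene
   merging, module–trait correlation, and selection of the score gene set
   from trait-associated modules.
3. **The R-loop score** — for gene set *S* with per-cell centered mean
   expression *S*<sub>center</sub> and expression-bin-matched random
   control genes giving *S*<sub>random</sub>,

   score = *S*<sub>center</sub> − *S*<sub>random</sub>,

   so higher score ⇔ higher regulator-program expression relative to
   expression-matched background. Cells (or samples) split into **high** /
   **low** subgroups at the median score.
4. **Malignancy calling** — expression-inferred copy-number profiles
   (reference-centered, clipped, 101-gene moving average), the per-cell
   quadratic-sum CNV score Σ<sub>w</sub> v², and a transparent CNV ×
   epithelial-score conjunction rule.
5. **Cell–cell communication** — ligand–receptor mean statistics between
   annotated cell types with a label-permutation null
   (p = (1 + #{perm ≥ obs})/(n<sub>perm</sub> + 1), significance at
   p < 0.05 with ≥ 10% expressing cells on both sides).
6. **Enrichment** — deterministic per-observation ssGSEA (rank-weighted
   running sum, α = 0.25) with Wilcoxon high-vs-low contrasts and
   Benjamini–Hochberg adjustment.
7. **Survival** — Kaplan–Meier, log-rank, Cox proportional hazards
   (Breslow/Efron), and the spline ln HR(score) curve anchored at the
   median score.

A first-class synthetic-data generator (`sim_config()`,
`generate_counts()`, `generate_survival()`, `simulate_module_matrix()`)
plants modules, score-shifted subpopulations, CNV-bearing malignant
subclones, communicating cell-type pairs and score-linked hazards with
known ground truth, so every stage is validated end-to-end.

## Worked example

```r
library(rloopscore)
sim <- generate_counts(sim_config(seed = 42))          # 2000 cells x 1000 genes
m   <- lognormalize(qc_filter(sim$matrix))
#> qc_filter: removed 0 cells with < 300 detected genes, 629 with mito fraction > 0.08
#> qc_filter: removed 0 genes detected in < 3 cells

sv <- score_gene_set(m, sim$truth$regulators, seed = 42001)
head(sv, 3)
#>                score subgroup
#> cell00001 -0.1159179      low
#> cell00002  0.3754354     high
#> cell00003 -0.1458190      low
```

The planted "low" subpopulation (regulator genes halved) is recovered by
the median split — `mean(sv$subgroup == sim$truth$group[rownames(sv)])` is
0.972 here — and the two subgroups differ sharply (Wilcoxon W = 467956,
p = 9.4e-222). Tying the subgroups to simulated survival with a planted
hazard ratio of 2 for the low-score group:

```r
surv <- generate_survival(sv$subgroup, hr = 2, censor_rate = 0.3, seed = 42002)
surv$low <- as.integer(surv$group == "low")
cox_ph(surv, "low")
#>   term      coef       hr    lower    upper           p
#> 1  low 0.7764016 2.173637 1.903852 2.481651 1.60714e-30
logrank_test(surv, "group")
#> log-rank chi2 = 137.48, p = 9.48e-32
```

The low-score group carries roughly twice the mortality hazard, matching
the planted value. See `vignette("rloop-scoring-methods")` for the model,
its assumptions and every default's rationale.

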