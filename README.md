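# cardiostrat

Genotype-stratified analysis of single-nucleus RNA-seq from multi-patient,
two-chamber heart cohorts — the setting of dilated and arrhythmogenic
cardiomyopathy studies where patients are stratified by their causal gene
(e.g. *LMNA*, *TTN*, *RBM20*, *PKP2*), variant-negative patients form their
own arm, and left- and right-ventricle samples exist per patient.

The package implements, as one tested R pipeline:

1. **Synthetic cohorts with ground truth.** A seeded generator emulating the
   cohort design: multinomial cell-type mixtures with genotype-specific
   multiplicative composition shifts, and negative-binomial counts
   `NB(mean = libsize · p_g · 2^Δ, dispersion φ_g)` with shared and
   genotype-private log2 fold-change programs, per-(patient, gene) random
   intercepts, and log-normal library sizes. Real cohorts of this kind sit
   behind controlled access; the generator makes every stage testable
   offline.
2. **Compositional statistics.** Centered log-ratio transform
   `clr(x)_c = ln(x_c + δ) − mean_k ln(x_k + δ)`, covariate-adjusted OLS
   abundance tests with BH correction, pairwise abundance-ratio Welch tests
   (`log2((A+0.5)/(B+0.5))`), and replicate Pearson correlations.
3. **Pseudobulk differential expression.** Per-(sample, cell type) summed
   counts, CPM filtering, trimmed-mean-of-M normalization factors, grid-based
   Cox–Reid dispersion estimation with shrinkage toward a common value, and a
   per-gene NB likelihood-ratio test — plus DEG-sharing partitions across
   genotypes, control-standardised gene-set activation scores, and one-sided
   hypergeometric enrichment of candidate gene lists among DEGs.
4. **Ligand–receptor interactions.** Tukey-trimean group expression, Hill
   interaction probabilities `P = LR/(K + LR)`, label-permutation p-values,
   and disease-vs-control pathway contrasts with an explicit `n/a` rule for
   signals absent from both cohorts.
5. **Genotype classification.** PCA embeddings, kNN graphs, and a
   from-scratch graph attention network (multi-head attention
   `α_ij = softmax_j LeakyReLU(aᵀ[Wh_i ‖ Wh_j])`) trained with patient-held-out
   cross-validation, whose per-nucleus genotype probabilities are averaged
   into patient-level calls.

Everything is data-frame-first and pipe-friendly: results come back as
tibbles, fitted objects have `tidy()`/`glance()` methods, and each result
type has a `plot_*()`/`autoplot()` helper.

## Worked example

```r
library(cardiostrat)

cfg <- generator_config(patients_per_genotype = 3, nuclei_per_sample = 300,
                        n_genes = 600, seed = 42)
sim <- simulate_dataset(cfg)
sim$data
#> <sn_dataset> 10800 nuclei x 600 genes | 36 samples, 18 patients
#> genotypes: control=6 LMNA=6 PKP2=6 PVneg=6 RBM20=6 TTN=6

comp <- compute_composition(sim$data)
clr  <- clr_transform(comp)
test_abundance(clr, "RBM20", covariates = "age", region = "LV") |>
  dplyr::arrange(p.value)
#>   category contrast         estimate std.error statistic p.value    fdr
#> 1 CM       RBM20_vs_control   -0.942    0.133     -7.08  0.00580 0.0348
#> 2 EC       RBM20_vs_control    0.361    0.0785     4.60  0.0193  0.0503
#> 3 FB       RBM20_vs_control   -0.235    0.0564    -4.17  0.0251  0.0503
#> ...
```

The generator planted a 0.45-fold cardiomyocyte depletion and endothelial /
immune expansion in the RBM20 arm; the age-adjusted CLR model recovers the
CM loss (negative CLR coefficient, FDR 0.035) with EC/FB shifts at the
margin of the 6-category FDR. Pairwise ratios quantify the same shifts as
fold-changes:

```r
pairwise_ratio_test(comp, "PVneg", region = "LV",
                    pairs = data.frame(a = c("EC", "Myeloid"), b = c("CM", "CM")))
#>   category_a category_b difference fold_change      fdr
#> 1 EC         CM               1.98        3.96 0.000168
#> 2 Myeloid    CM               2.47        5.54 0.00100
```

i.e. the EC:CM abundance ratio is ~4-fold higher in variant-negative LVs
than in controls here, the myeloid:CM ratio ~5.5-fold. Downstream stages
chain the same way:

```r
pb <- aggregate_pseudobulk(sim$data, "type")       # units × genes
de <- de_test(pb, "TTN", "CM", region = "LV")      # NB LRT per gene
cv <- classify_genotype(sim$data, optimizer = "adam")  # GAT, patient-held-out
glance(cv)
```

or run all five stages at once, writing TSVs and a run log:

```r
res <- run_pipeline(pipeline_config(outdir = "out", seed = 1))
```

On the default cohort (≈19,800 nuclei) this takes about 3 minutes on one
CPU; at seed 1 it ends with a cardiomyocyte nucleus-level accuracy of 0.95,
patient-level accuracy 1.00 after aggregation, and ~40% of each genotype's
cardiomyocyte DEGs genotype-specific (39.7% at seed 1) — matching the
generator's planted 40%.

A thin CLI wrapper is installed at `inst/cli/cardiostrat`
(`Rscript inst/cli/cardiostrat all --seed 1 --outdir out`).

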