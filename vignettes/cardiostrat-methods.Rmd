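---
title: "Methods: genotype-stratified snRNA-seq analysis with cardiostrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-stratified snRNA-seq analysis with cardiostrat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cardiostrat analyses single-nucleus RNA-seq from genotype-stratified heart
cohorts: patients carrying pathogenic variants in different cardiomyopathy
genes (here labelled LMNA, TTN, RBM20, PKP2), variant-negative patients
(PVneg), and controls, each sampled in left and right ventricle. This
vignette explains the models behind each stage, the tunable parameters, the
synthetic cohorts the package generates for validation, and the numerical
choices and limitations a careful user should know about.

## The synthetic cohort generator

Real cohorts of this design are controlled-access; the generator produces
seeded datasets with the same statistical structure plus a ground-truth
ledger, so every downstream stage can be validated against known effects.

A `generator_config()` describes the cohort: genotype arms with one control,
`patients_per_genotype` patients per arm, one sample per (patient, region),
and `nuclei_per_sample` nuclei per sample. For each sample the cell-type
mixture is multinomial around expected proportions; a genotype's
`composition_effects` multiply the baseline proportions and are renormalised,
so a fold of 2 on cardiomyocytes in a two-type mixture of (0.5, 0.5) yields
(2/3, 1/3), not (1, 0.5). Gene counts are negative binomial:

* a per-nucleus library size, log-normal with parameters
  `libsize_log_mean` (default `log(2000)` counts) and `libsize_log_sd`
  (0.35), matching typical single-nucleus depth for a 1,000-gene panel;
* a cell-type expression profile built from gamma-distributed gene weights
  with a marker block per type (fold `marker_strength`, default 8) and,
  within each type, two cell states that differ by a small dedicated marker
  program (fold `state_marker_strength`, 6) — states exist so state-level
  operations are exercisable, while genotype effects are defined at type
  level;
* disease effects as log2 fold-changes: a `shared_deg` program applied in
  every disease genotype and genotype-private `specific_deg` programs,
  optionally restricted to named cell types;
* a per-(patient, gene) normal random intercept on the log scale
  (`patient_effect_sd`, default 0.15), shared by both regions of a patient.
  This makes the two chambers of one patient correlated and gives
  pseudobulk replicates a biological coefficient of variation of about 15%,
  the main driver of realistic dispersion after aggregation. We draw the
  intercept per gene rather than as a single global scalar: a global
  intercept is absorbed by library-size normalisation and would leave
  pseudobulk replicates unrealistically clean;
* per-gene NB dispersion `nb_dispersion` (default 0.3, typical of
  single-nucleus counts).

Every patient and every sample derives its own RNG stream by hashing
(seed, id), so generation is order-independent and byte-identical across
reruns. The default cohort (6 genotypes x 3 patients x 2 regions x 550
nuclei, 1,000 genes, ~19,800 nuclei) is the configuration exercised by the
end-to-end tests.

What the generator does **not** emulate: ambient RNA, doublets, batch or
chemistry effects, UMI saturation, and cross-patient heterogeneity of effect
sizes. Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under a faithful null and realistic effect structure
— not that any biological conclusion transfers to a particular real
dataset. Effect sizes are chosen for testability: the source cohorts report
no closed-form per-genotype fold-changes to copy.

## Compositional analysis

Cell-type (or state) counts per sample are compositional: proportions sum
to one, so raw-proportion tests confound which categories actually changed.
We use the centered log-ratio transform,
\(\mathrm{clr}(x)_c = \ln(x_c + \delta) - \frac{1}{C}\sum_k \ln(x_k + \delta)\),
with an additive pseudocount \(\delta = 0.5\) on counts. The pseudocount
handles zeros simply and reproducibly; multiplicative zero replacement was
rejected as needlessly complex for nucleus counts in the hundreds. Each CLR
row sums to zero by construction, and CLR values are invariant to scaling a
sample's counts when the pseudocount is scaled along.

Abundance testing fits, per category, an ordinary least squares model
`clr ~ condition + covariates` (age, sex and/or region; the left-ventricle
regions are pooled as LV, so region is binary) and reports the two-sided
t-test of the condition coefficient, with Benjamini–Hochberg adjustment
across categories within one contrast. The BH family is one
(contrast, region, level) set of categories — a choice we fix because the
source analyses print FDRs without defining the family. With no covariates
the test reduces exactly to the equal-variance two-sample t-test, which is
how it is validated.

Pairwise abundance ratios use per-sample `log2((A + 0.5)/(B + 0.5))` and a
Welch t-test between disease and control, reporting the disease-minus-
control difference and its `2^difference` fold-change. Welch rather than
pooled variance because arm sizes and spreads differ; degenerate
zero-variance ratios return a missing p-value rather than an error.
Replicate agreement is summarised as the Pearson correlation of proportion
vectors; constant vectors have no defined correlation and are reported
missing.

Under the generator's null the abundance test's type-I error is calibrated
(checked over 200 simulated cohorts at n = 10 vs 10), and a 2-fold effect
on one cell type at that size is detected at FDR 0.05 in at least 95 of 100
seeds.

## Pseudobulk differential expression

Counts are summed over nuclei within each (sample, cell category) unit;
units under `min_nuclei = 10` nuclei are dropped. Treating units as bulk
replicates sidesteps the pseudoreplication of nucleus-level tests: the
relevant replication is patients, not nuclei.

Genes with CPM above 1 in fewer than `min(arm sizes)` units are filtered.
Normalisation factors are trimmed means of M-values against a reference
unit (the one whose upper-quartile count proportion is closest to the
mean), with 30% trimming on log-ratios, 5% on average abundance,
inverse-variance weights, and a rescaling so the log factors average zero.
The factors are validated against an independent reference implementation
on compositionally shifted simulations.

Dispersion is estimated on a fixed grid of 50 points spanning
\(2^{-15}\) to \(2^5\) by maximising the Cox–Reid adjusted profile
likelihood of the one-way NB model; grid maximisation avoids fragile
univariate optimisers at the cost of grid-resolution granularity (about
28% spacing between neighbouring grid points, immaterial for testing).
Each gene's estimate is shrunk toward the common (summed-profile) maximiser
by adding `prior_df = 10` times the average profile to its own before
maximising, and is clamped between its raw and the common estimate.

Testing uses the likelihood-ratio chi-square of the condition coefficient
in the NB log-linear model with `offset = log(lib_size x factor)`, fitted
by Fisher scoring (step-capped, 100 iterations; non-converged genes are
flagged with missing p-values). We use the LRT rather than a
quasi-likelihood F-test deliberately: it is well defined without QL
dispersion machinery, and the validation targets are calibration-based
(type-I error, sensitivity, empirical FDR, log-fold-change recovery), not
equivalence with any particular external tool. At dispersion zero the test
coincides with the Poisson GLM LRT to numerical precision, which is one of
the test suite's oracles.

DEG sharing across genotypes uses `fdr <= 0.05`: the shared set is the
intersection over all disease genotypes, and a genotype's "specific"
percentage is the share of its DEGs found in no other genotype. Gene-set
activation scores are means of per-gene z-scores (log1p counts-per-10k,
standardised on control nuclei of the same cell type), so control cohorts
score zero by construction. Candidate-list enrichment among DEGs uses the
one-sided hypergeometric tail with a cross-product odds ratio
(Haldane 0.5 correction only when a cell is zero).

## Ligand–receptor interactions

Group-level expression is the Tukey trimean \((Q_1 + 2Q_2 + Q_3)/4\) of
log1p counts-per-10k values, with quartiles by linear interpolation
(type-7) so the summary is deterministic; expression is zeroed when fewer
than `min_frac = 0.1` of the group's nuclei express the gene, and groups
under 10 nuclei are excluded. The interaction probability of a
(sender, receiver, ligand–receptor pair) triplet is the Hill form
\(P = LR/(K + LR)\) with \(K = 0.5\): zero when either side is undetected,
strictly below one, increasing in both inputs. Significance comes from
permuting group labels over nuclei, \(p = (1 + \#\{P^{perm} \ge P\})/(n_{perm}+1)\)
with `nperm = 100`, so p-values are bounded below by 1/101 and an observed
zero probability yields p = 1. None of K, `min_frac` or `nperm` is printed
in the source analyses; the values here are the package's fixed defaults,
and only single-gene ligands and receptors are supported (multi-subunit
complexes and cofactors are out of scope).

Disease-vs-control contrasts keep scores with p at or below 0.05, map
states to their cell type, sum probabilities within (pathway, sender type,
receiver type), and report `log2((S_dis + 1e-3)/(S_ctrl + 1e-3))`;
combinations silent in both cohorts are emitted as n/a rather than zero,
distinguishing "unchanged" from "undetected".

## Genotype classification with a graph attention network

Per cell type, nuclei are embedded by PCA: log1p counts-per-10k, the 1,000
highest-dispersion genes, z-scaling clipped at +/-10, top 30 components
with a deterministic sign convention (the largest-magnitude loading of each
component is positive). A Euclidean k-nearest-neighbour graph (k = 15,
ties broken by node index) is symmetrised by union and given self-loops.
These choices — features, k, and the architecture below — follow common
single-cell and GAT practice; the source describes none of them.

The GAT has one hidden layer of 8 heads x 8 dimensions and an output
layer whose heads are averaged. Per head, edge scores
\(e_{ij} = \mathrm{LeakyReLU}_{0.2}(a^\top [W h_i \| W h_j])\) are
softmax-normalised over each node's neighbourhood (including itself),
neighbour messages \(W h_j\) are averaged with those attention weights,
hidden heads are concatenated through an ELU, and the output layer applies
a class softmax. Forward and backward passes are written directly from
these equations, so the analytic gradient can be (and is) verified against
central finite differences to 1e-4 relative error.

Training minimises cross-entropy on training nuclei, full-batch, with
gradient-norm clipping at 5, early stopping on validation loss
(patience 20, at most 200 epochs), and seeded Glorot initialisation. Plain
fixed-step gradient descent is the default optimizer because it keeps the
update rule trivially auditable; Adam is available behind
`optimizer = "adam"` and is what the cross-validation driver and the
pipeline use in practice, since it reaches the early-stopping plateau in
far fewer epochs on these graphs.

Cross-validation is grouped by patient: all nuclei of a patient are
entirely in train or test (the only leakage-safe choice when nuclei of one
patient are strongly correlated), with folds assigned round-robin within
genotype. Early-stopping validation nuclei are drawn from training
patients at nucleus level — a documented compromise; they never overlap
test patients. Patient-level genotype calls average the per-nucleus softmax
vectors pooled across the informative cell types (an unweighted convex
combination), take the argmax, and also report per-cell-type sub-means.
Aggregation across cell types and nuclei is what turns imperfect
nucleus-level accuracy into near-perfect patient-level accuracy, and the
test suite checks this gain holds in at least 90 of 100 simulated
classifier regimes.

## Numerical choices, problem sizes, degenerate inputs

* Fisher scoring steps are capped at +/-5 per iteration; all-zero groups
  run to the iteration cap and yield large negative, but finite,
  coefficients.
* The dispersion grid's lowest point stands in for "Poisson"; the LRT path
  accepts an exact dispersion of 0 as well.
* Attention softmaxes subtract per-node maxima; probabilities are floored
  at 1e-300 inside logs.
* Empty samples, undersized pseudobulk units, undersized interaction
  groups, constant replicate vectors, and patients without test nuclei are
  excluded with messages, never silently.
* Validation problem sizes were fixed a priori to what the statistics need,
  not tuned: 200 null cohorts and 100 detection seeds for composition;
  one 8 vs 8-unit cohort with 100 planted DEGs at |log2FC| = 1.5 for DE
  power/FDR/recovery; 500 independent null permutation tests (each with its
  own data and permutation draws, so the uniformity check's independence
  assumption holds) and 100 planted-ligand seeds for interactions; 6 x 3-patient separable cohorts, 50
  (tests) or 25 (acceptance script) label shuffles, and 100 aggregation
  regimes for the classifier; the full default cohort for the end-to-end
  run.

## Known limitations

* The abundance model is OLS on CLR values; it does not model
  multinomial sampling noise explicitly (no Dirichlet-multinomial or
  neighbourhood-level differential abundance).
* DE is two-group per contrast; continuous covariates enter the
  compositional stage but not the NB model, whose fast path is the one-way
  layout.
* The interaction model is deliberately minimal relative to full
  mass-action frameworks: no complexes, cofactors, or network centrality.
* The GAT is transductive (the graph includes test nuclei; labels never
  leak) and CPU-bound; very large cell types are subsampled
  (`max_nuclei`) before graph construction in the pipeline defaults.
* Generator realism bounds what green tests mean; see the generator
  section.
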