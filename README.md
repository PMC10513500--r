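# MethylFuse

Childhood medulloblastoma is routinely stratified into four consensus
molecular subgroups — WNT, SHH, Group 3 and Group 4 — and treatment
decisions depend on getting the call right; Groups 3 and 4 overlap
molecularly and are the hardest to separate. MethylFuse is an R package
for building and interrogating DNA-methylation-based subgroup
classifiers, aimed at computational biologists working with Illumina
450K-style beta values and a matched gene-expression view.

The pipeline it implements:

* **Preprocessing** — beta values β = M/(M + U + 100) from
  methylated/unmethylated intensities, detection-p probe filtering
  (removed if p > 0.05 in over 5% of samples), sex-chromosome/SNP probe
  blacklisting, quantile normalization.
* **Label fusion** — similarity network fusion of the methylation and
  expression sample-affinity networks (kernel
  W(i,j) = exp(−d²(i,j)/(μ·ε(i,j))), cross-diffusion with K = 51
  neighbors, μ = 0.85, 120 iterations), spectral clustering into k = 4
  groups, NMI scoring, and maximum-agreement relabeling. Models train on
  fused labels, and are always scored against the original ones.
* **Feature selection** — MAD top 5,000 probes, then a 300-tree random
  forest ranks them by per-subgroup importance; the top 399 form the
  biomarker panel.
* **Imbalance correction** — SMOTE interpolation x + u·(x′ − x) among
  k = 5 minority nearest neighbors (a 70-sample minority at 200%
  becomes 210).
* **Classification** — RF, SVM, KNN, naive Bayes, XGBoost, LDA, and a
  feed-forward network (dense 40/30/10/4, leaky ReLU + softmax, dropout
  0.5/0.4/0.1, L2 0.009 on layer 2, SGD with Nesterov momentum, early
  stopping), all behind one train/predict contract.
* **Evaluation** — one-vs-rest confusion metrics, Hand–Till multiclass
  AUC, PCA decision grids, exact t-SNE embeddings.
* **Interpretation** — permutation-sampling Shapley values per feature
  and subgroup, with Monte-Carlo standard errors.
* **Gene networks** — Pearson correlation graphs (edges kept iff
  r > 0.6, degree ≥ 2), Prim minimum spanning trees under weight 1 − r,
  edge-betweenness communities, greedy cluster augmentation.
* **Survival** — per-biomarker dichotomization at the best of
  mean/median/quartile cut-offs (maximal |log HR|, 10% group floor),
  Cox models adjusted for age/sex/subgroup, log-rank tests,
  Kaplan–Meier curves.

A synthetic-cohort generator (`generateOmics()`) with known subgroup
blocks, view coupling, imbalance and subgroup-dependent hazards makes
every stage testable without any external download. See the methods
vignette (`vignettes/methylfuse-methods.Rmd`) for the full model
descriptions and design rationale.

## Worked example

```r
library(MethylFuse)

spec <- syntheticSpec(
  classCounts = c(WNT = 20, SHH = 50, Group3 = 40, Group4 = 90),
  nProbes = 2000, nInformative = 200, delta = 0.4, noiseSd = 0.3,
  nGenes = 500, coupling = 0.8, seed = 42)
omics <- generateOmics(spec)
omics
#> MethylOmics container
#>   methylation: 2000 probes x 200 samples (beta)
#>   expression : 500 genes x 200 samples
#>   subgroups  : WNT=20, SHH=50, Group3=40, Group4=90

fusion <- integrateOmics(omics, snfParams(K = 51, mu = 0.85, t = 120,
                                          kClusters = 4), seed = 1)
fusion$nmi
#> [1] 1
```

The fused network's spectral partition agrees perfectly with the
recorded subgroups (NMI 1), so the relabeled training labels coincide
with the originals here. Select a biomarker panel and train a
classifier:

```r
beta <- betaValues(omics)
panel <- rfImportanceSelect(beta[madSelect(beta, 1000), ],
                            fusion$labels, nSelect = 100, seed = 1)

x <- t(beta[panel, ]); y <- subgroups(omics)
split <- splitData(y, trainFrac = 0.8, seed = 1)
model <- trainModel(x[split$train, ], y[split$train], "SVM", seed = 1)
pred  <- predictSubgroups(model, x[split$test, ])

confusionCounts(as.character(y[split$test]),
                as.character(pred$class), levels(y))
#> ConfusionMatrix (rows = truth, columns = predicted)
#>         predicted
#> true     WNT SHH Group3 Group4
#>   WNT      4   0      0      0
#>   SHH      0  10      0      0
#>   Group3   0   0      8      0
#>   Group4   0   0      0     18
```

Every held-out sample lands on the diagonal, so all one-vs-rest metrics
(accuracy, precision, sensitivity, specificity, F1) and the Hand–Till
AUC equal 1 — the behavior expected on a cohort simulated with a clean
0.4 beta-value separation. `classMetrics()` tabulates the per-subgroup
and macro rows; on noisier or real data the off-diagonal counts and the
per-class rows are where Group 3/4 confusion shows up.

A command-line front end wrapping the same functions ships with the
package (`system.file("scripts", "methylfuse.R", package =
"MethylFuse")`) with subcommands `simulate`, `preprocess`, `integrate`,
`select-features`, `balance`, `train`, `predict`, `evaluate`,
`explain`, `network`, `survival` and `run-all`; `runPipeline()` is the
in-R orchestrator.

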