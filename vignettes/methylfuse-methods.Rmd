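---
title: "MethylFuse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MethylFuse: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

MethylFuse classifies childhood medulloblastoma samples into the four
consensus molecular subgroups (WNT, SHH, Group 3, Group 4) from Illumina
450K-style DNA methylation beta values, with an optional gene-expression
view used only to refine the training labels. This vignette explains the
statistical machinery stage by stage, states every tunable parameter
with its default and rationale, and records the design decisions made
where the design was genuinely open.

## Beta values and probe quality

Methylation at a CpG is summarized as the beta value
$\beta = M / (M + U + 100)$, where $M$ and $U$ are the methylated and
unmethylated probe intensities. The offset of 100 stabilizes
low-intensity probes and keeps $\beta$ strictly below 1 for finite
intensities; it is exposed as `offset` in `computeBeta()` but 100 is the
only value used anywhere in the package.

Quality filtering removes a probe when its detection p-value exceeds
0.05 in *over* 5% of samples — the boundary case (exactly 5%) is kept,
and `detectionFilter()` is monotone in the tolerated fraction. Probes on
chromosomes X/Y and SNP-associated probes are blacklisted
(`dropBlacklisted()`), since sex-linked methylation and polymorphisms
confound tumor subgrouping.

`quantileNormalize()` performs plain column quantile normalization
(every sample receives the common distribution given by the mean of the
per-sample sorted values; ties are averaged). A cell-type-stratified
normalization would require probe-type metadata the package deliberately
does not consume; for single-tissue cohorts the plain contract — shared
distribution, ranks preserved, idempotent — is what downstream stages
rely on. The implementation delegates to `limma::normalizeQuantiles()`.

## Label fusion: SNF and spectral clustering

Methylation and expression views are integrated by similarity network
fusion. Per view, samples are compared by squared Euclidean distance and
converted to affinities with the locally adaptive kernel

$$W(i,j) = \exp\!\left(-\frac{d^2(i,j)}{\mu\,\varepsilon(i,j)}\right),
\qquad
\varepsilon(i,j) = \frac{\bar d_K(i) + \bar d_K(j) + d^2(i,j)}{3},$$

where $\bar d_K(i)$ is the mean squared distance from $i$ to its $K$
nearest neighbors. Cross-diffusion then iterates
$P^{(v)} \leftarrow S^{(v)} \bar P^{(-v)} S^{(v)\top}$ for $t$ rounds,
where $P$ is the full kernel with off-diagonal row mass $\tfrac12$ and
$S$ the row-normalized $K$-nearest-neighbor mask; after each round the
kernels are renormalized and symmetrized, and the fused network is the
average of the final views.

Defaults are `K = 51` neighbors, kernel scale `mu = 0.85`, and `t = 120`
iterations, with `kClusters = 4` for the four subgroups. `K` is clamped
to $n-1$ with a warning on small cohorts. The fused network is
partitioned by normalized spectral clustering (Ng–Jordan–Weiss): top-$k$
eigenvectors of $D^{-1/2} W D^{-1/2}$, rows normalized to unit length,
k-means with a fixed seed and 50 restarts (restarts make the k-means
step reproducible-by-construction rather than luck; ties in the
eigendecomposition are broken by eigenvalue order).

Partition agreement is scored by normalized mutual information,
$\mathrm{NMI}(a,b) = I(a;b)/\sqrt{H(a)H(b)}$ — the geometric-mean
normalization, one of several in circulation, chosen and documented as a
convention. Two degenerate conventions are fixed: identical partitions
(up to renaming) score exactly 1, and two zero-entropy partitions score
1. Cluster numbers are mapped to subgroup names by the one-to-one
assignment maximizing total overlap, solved exactly by exhaustive search
over assignments (feasible for the at-most-8 clusters this package
handles; a greedy assignment can be wrong when overlaps are
non-dominant).

Classifiers are trained on the *fused* labels but always scored against
the original labels — the asymmetry is enforced by `runPipeline()`.

## Feature selection and class balance

Probes are first ranked by median absolute deviation, computed unscaled
(the 1.4826 consistency factor never changes ranks), ties broken by
probe id so the ranking is total; the top 5,000 enter a random forest of
300 trees. Forest importance is read per class (permutation importance)
and averaged across the four subgroups; Gini importance is available via
`type = "gini"`. The top 399 probes form the default biomarker panel.
Both 5,000 and 399 are configuration defaults mirroring the method the
package implements, not derived quantities; 399 is treated as a fixed
rank cut because no threshold rule would reproduce it.

Class imbalance is corrected by SMOTE: each synthetic minority sample is
$x + u\,(x' - x)$ with $u \sim U(0,1)$ and $x'$ one of the $k = 5$
nearest minority neighbors, so every synthetic coordinate lies within
the segment between its parents. At the default 200% oversampling a
70-sample minority class gains 140 synthetic samples, totalling 210.
`smoteBalance(toMajority = TRUE)` instead lifts every non-majority class
to the majority size exactly (whole SMOTE rounds, last round subset).

By default SMOTE is applied to the training partition only.
The `smoteBeforeSplit = TRUE` pipeline option instead oversamples the
full cohort before splitting; this is provided for comparison and is
leakage-prone, since interpolated copies of test samples then inhabit
the training set.

Splits default to 0.8 train / 0.2 test, stratified; the neural network
uses a 0.6/0.2/0.2 train/validation/test split. Cross-validation uses
k = 10 folds dealt round-robin within class, so fold sizes differ by at
most one.

## Classifier families

All seven families share one contract — probability rows summing to 1,
argmax labels, refusal of unseen features, determinism given the seed:

| family | settings |
|--------|----------|
| RF | 300 trees, at most 6 terminal nodes per tree |
| SVM | radial kernel; library-default cost 1, gamma $1/d$ (recorded) |
| KNN | 3 nearest neighbors; in-package, returns full vote fractions |
| NB | Gaussian naive Bayes; calls with posterior below 0.8 are flagged low-confidence but still labeled (no reject class is defined) |
| XGB | 50 rounds, learning rate 0.3, depth 6 — library defaults, recorded |
| LDA | library defaults, recorded |
| ANN | see below |

The feed-forward network is implemented in-package in base R matrix
code: dense layers of widths 40/30/10/4 (output resized to the class
count), leaky ReLU (slope 0.3) on the first three layers and softmax
output, dropout 0.5/0.4/0.1 after the hidden layers, L2 penalty 0.009 on
the second layer's weights, categorical cross-entropy minimized by
minibatch SGD (batch 16, learning rate 0.03, per-step decay
$6\times10^{-5}$, momentum 0.05, Nesterov), at most 200 epochs with
early stopping after 5 epochs without validation-loss improvement and
restoration of the best weights. Features are standardized with
training-set statistics stored in the model. Two readings were open:
the four stated widths versus the "two hidden layers" phrasing are
reconciled as four dense layers (the dropout triple and the
L2-on-layer-2 statement only fit that reading), and the SGD decay is
applied per optimization step, recorded in the model parameters. A
divergent (NaN) loss raises an error advising a lower learning rate.

## Evaluation

Confusion matrices are reduced to per-class one-vs-rest counts; from
these, accuracy $(TP+TN)/n$, precision $TP/(TP+FP)$, sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$ and F1 $2TP/(2TP+FP+FN)$ are
computed per class, with undefined $0/0$ ratios reported as `NA`, never
as 0. Per-class accuracy is one-vs-rest, which is the only reading under
which per-subgroup accuracy rows can differ. Macro rows are plain means
of the per-class values. Multiclass AUC is the Hand–Till construction:
the mean over unordered class pairs of the averaged one-vs-one rank
AUCs; it reduces to the standard rank AUC in the binary case and is
invariant to monotone score transforms.

The PCA decision grid fits PCA on the training set only, projects both
sets onto the first two components, and paints a `resolution`²
rectangular grid (5% margin) with predictions. Because grid nodes live
in the 2-D PC space, the requested family is refitted on the projected
training coordinates — the honest way to draw decision regions there.

t-SNE is implemented exactly (no Barnes–Hut approximation): per-point
bandwidths calibrated to the target perplexity (default 30) by binary
search, early exaggeration 12 for 100 iterations, momentum 0.5 then 0.8,
learning rate 200, 500 iterations by default. Exact t-SNE is $O(n^2)$
per iteration, which is ample at the package's desk-scale cohort sizes
and deterministic given the seed.

## Shapley interpretation

`shapleyExplain()` implements the permutation-sampling estimator: each
draw picks a random feature permutation and a random background row, and
feature $j$ is credited with the change in the class-probability output
when $j$ flips from background to instance value, features before $j$
(in the permutation) already flipped. Averaging over `mSamples = 1000`
draws estimates the interventional Shapley value against the empirical
background distribution; Monte-Carlo standard errors are reported so
every downstream claim can be stated "within $3\,\mathrm{SE}$".
Explanations are on the probability scale per class — per-subgroup
panels of signed contributions — not the logit scale. The default of
1,000 draws balances the MC error (a few times $10^{-3}$ on probability
outputs) against runtime; it is a package choice, as no canonical count
exists.

## Gene networks

Gene-level matrices (probes collapsed to genes by median, unannotated
probes dropped) yield a Pearson correlation network. Edges are kept iff
$r$ *strictly* exceeds 0.6 (an edge at exactly 0.6 is removed);
self-loops and duplicate edges are removed; then vertices with fewer
than 2 edges are removed in a single pass — deliberately not iterated to
a k-core, since the filters are specified as one pass. Vertex display
sizes are mean beta × 10. The minimum spanning tree uses Prim's
algorithm under the weight transform $1-r$, so the tree retains the
strongest correlations (the untransformed direction would retain the
weakest — the transform direction is a package decision). Communities
are Girvan–Newman edge-betweenness partitions at maximum modularity,
computed on the thresholded graph's unweighted topology: edge weights
would act as distances in the betweenness step but as strengths in the
modularity step, an incoherence avoided by not using them.

`augmentClusters()` grows each community's gene set greedily from a
ranked candidate pool (global RF-importance rank), keeping an addition
iff macro F1 improves by at least `minGain = 0.01`, stopping when every
per-class F1 reaches the target; every trial is recorded in a trace.

## Survival analysis

Each biomarker's beta values are dichotomized at the candidate cut-offs
mean, median, lower and upper quartile; each candidate is fitted in a
Cox proportional hazards model adjusted for age, sex and subgroup
(one-hot against a configurable reference, default WNT), and the winner
maximizes the absolute log hazard ratio of the methylation-group
coefficient — the absolute value also captures protective markers —
subject to both groups holding at least 10% of samples. Ties are handled
by the Efron approximation (a package decision, recorded). Wald and
likelihood-ratio p-values accompany each fit, log-rank tests compare the
dichotomized groups, and Kaplan–Meier curves are exported as step
functions. Raw p-values are reported across marker panels; multiplicity
correction is left to the caller and said so.

## The synthetic generator

`generateOmics()` is a first-class module, not a fixture: it emulates
the structure the pipeline is built for. Informative probes are assigned
a target subgroup round-robin; the target group's mean beta sits `delta`
away from the complement (0.5 ± delta/2, in both hyper- and
hypomethylated directions), background probes get a bimodal baseline
(centers near 0.15 and 0.85), and noise of SD `noiseSd` is added on the
logit scale before the inverse-logit maps values into [0, 1] — giving
the bimodal beta distributions typical of Illumina arrays, with clipping
as a belt-and-braces contract. The expression view shares the latent
subgroup blocks on a proportional share of genes with signal strength
`coupling`; survival times are exponential with per-subgroup hazard
$\lambda_0 e^{\mathrm{logHR}}$ ($\lambda_0 = 0.08$/year) and independent
exponential censoring calibrated to the requested censored fraction;
ages (truncated normal, mean 10.4, SD 9.4 years) and sex (66% male)
match a pediatric cohort's demographics.

The default cohort is {WNT 70, SHH 200, Group3 150, Group4 343},
totalling 763: the minority size and the total are the canonical
figures, while the three-way split of the remainder is an arbitrary
choice documented as such. The generator does **not** simulate array
chemistry, probe-type (I/II) bias, batch effects, cohort shift, or the
molecular overlap that makes real Group 3/4 separation hard. Passing
tests on this generator therefore demonstrate the correctness of the
machinery — formulas, counts, invariants, parameter recovery — not
clinical-grade accuracy on real cohorts.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, chosen as
sizes at which every asserted property is statistically comfortable:
cohorts of 90–255 samples, 300–6,000 probes, 2,000 samples for survival
parameter recovery, 100 random graphs of at most 6 vertices for the
exhaustive MST cross-check, 3,000 Monte-Carlo draws against the full
$2^4$ coalition enumeration, 20 null replicates for hazard calibration
and 200 for log-rank uniformity. Stochastic assertions are stated
against 3 Monte-Carlo standard errors; exact assertions (counts, metric
formulas, NMI identity) are exact. Affinity scales are floored at
machine epsilon, k-means uses 50 restarts, probability rows are
renormalized defensively, and zero-variance features receive unit scale
in the network's standardizer.

## Known limitations

* The SNF forms follow the published cross-diffusion construction; the
  package does not implement multi-view weighting beyond uniform
  averaging, or affinities from categorical/clinical variables.
* IDAT parsing, background/dye-bias correction, age/sex imputation and
  external enrichment databases are out of scope; the package consumes
  matrices.
* Exact t-SNE and the in-package KNN are $O(n^2)$ — appropriate for
  hundreds to a few thousand samples, not for atlas-scale data.
* Survival screening reports raw p-values per marker.
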