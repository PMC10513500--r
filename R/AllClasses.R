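#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Parameters of the synthetic multi-omics generator
#'
#' A `SyntheticSpec` fixes every degree of freedom of the synthetic cohort:
#' the per-subgroup sample counts, the number of probes and of
#' subgroup-discriminating probes, the mean beta separation between
#' hyper- and hypomethylated groups, the logit-scale noise, the coupled
#' expression view, censoring, and per-subgroup log hazard ratios.
#' Identical spec + seed yields bit-identical data.
#'
#' @slot classCounts named integer vector, samples per subgroup.
#' @slot nProbes total number of CpG probes.
#' @slot nInformative number of subgroup-discriminating probes.
#' @slot delta mean beta separation between hyper- and hypomethylated
#'   groups, in (0, 1).
#' @slot noiseSd Gaussian noise SD on the logit scale.
#' @slot nGenes number of genes in the expression view.
#' @slot coupling shared-signal strength between views, in \[0, 1\].
#' @slot censorRate fraction of samples censored, in \[0, 1).
#' @slot logHR named numeric, per-subgroup log hazard ratio.
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticSpec()] for the user-facing constructor.
#' @export
setClass("SyntheticSpec",
  slots = c(
    classCounts = "integer",
    nProbes = "integer",
    nInformative = "integer",
    delta = "numeric",
    noiseSd = "numeric",
    nGenes = "integer",
    coupling = "numeric",
    censorRate = "numeric",
    logHR = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (length(object@classCounts) < 2L || is.null(names(object@classCounts)))
    msg <- c(msg, "classCounts must be a named vector with >= 2 classes")
  if (any(object@classCounts <= 0L)) msg <- c(msg, "all class counts must be > 0")
  if (object@nProbes <= 0L || object@nInformative <= 0L || object@nGenes <= 0L)
    msg <- c(msg, "all counts must be > 0")
  if (object@nInformative > object@nProbes)
    msg <- c(msg, "nInformative cannot exceed nProbes")
  if (object@delta <= 0 || object@delta >= 1) msg <- c(msg, "delta must lie in (0,1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@coupling < 0 || object@coupling > 1) msg <- c(msg, "coupling must lie in [0,1]")
  if (object@censorRate < 0 || object@censorRate >= 1)
    msg <- c(msg, "censorRate must lie in [0,1)")
  if (!all(names(object@classCounts) %in% names(object@logHR)))
    msg <- c(msg, "logHR must name every class in classCounts")
  if (length(msg)) msg else TRUE
})

#' Paired methylation and expression views with subgroup labels
#'
#' The central container of the package: a methylation view (assay
#' `"beta"`, probes x samples, values in \[0, 1\]) and a gene-expression
#' view (assay `"expr"`, genes x samples) over the same samples, each held
#' as a [SummarizedExperiment::SummarizedExperiment]. Sample metadata
#' (subgroup, age, sex, survival) lives in the methylation view's
#' `colData` and is shared.
#'
#' @slot methylation `SummarizedExperiment` with assay `"beta"`.
#' @slot expression `SummarizedExperiment` with assay `"expr"`.
#'
#' @seealso [MethylOmics()], [betaValues()], [exprValues()], [subgroups()],
#'   [generateOmics()]
#' @export
setClass("MethylOmics",
  slots = c(
    methylation = "SummarizedExperiment",
    expression = "SummarizedExperiment"
  )
)

setValidity("MethylOmics", function(object) {
  msg <- character()
  b <- SummarizedExperiment::assay(object@methylation, "beta")
  if (!identical(colnames(object@methylation), colnames(object@expression)))
    msg <- c(msg, "methylation and expression views must share identical sample names")
  if (any(b < 0 | b > 1)) msg <- c(msg, "beta values must lie in [0,1]")
  if (!"subgroup" %in% colnames(SummarizedExperiment::colData(object@methylation)))
    msg <- c(msg, "colData must contain a 'subgroup' column")
  if (length(msg)) msg else TRUE
})

#' Fitted subgroup classifier
#'
#' An opaque handle around one of the seven supported classifier families
#' (`RF`, `SVM`, `KNN`, `NB`, `XGB`, `LDA`, `ANN`). Stores the fitted
#' state, the class order, the feature ids seen at training (prediction
#' refuses anything else), and every resolved hyperparameter.
#'
#' @slot family character, one of the seven family codes.
#' @slot fit fitted state (library object or network weights), opaque.
#' @slot classes class names in fixed order.
#' @slot featureIds feature identifiers used in training.
#' @slot params resolved hyperparameters, including library defaults.
#' @slot seed integer seed used for training.
#' @slot nTrain number of training samples.
#'
#' @seealso [trainModel()], [predictSubgroups()]
#' @export
setClass("SubgroupModel",
  slots = c(
    family = "character",
    fit = "ANY",
    classes = "character",
    featureIds = "character",
    params = "list",
    seed = "integer",
    nTrain = "integer"
  )
)

setValidity("SubgroupModel", function(object) {
  fam <- c("RF", "SVM", "KNN", "NB", "XGB", "LDA", "ANN")
  if (!object@family %in% fam)
    return(sprintf("family must be one of %s", paste(fam, collapse = ", ")))
  if (length(object@classes) < 2L) return("model must know >= 2 classes")
  TRUE
})

#' Multiclass confusion matrix with one-vs-rest counts
#'
#' Rows index true classes, columns predicted classes. The `ovr` slot
#' carries per-class one-vs-rest TP/FP/TN/FN counts; for every class
#' TP + FP + TN + FN equals the total sample count.
#'
#' @slot table k x k integer count matrix (rows = truth).
#' @slot classes class names.
#' @slot ovr k x 4 matrix with columns TP, FP, TN, FN.
#'
#' @seealso [confusionCounts()], [classMetrics()]
#' @export
setClass("ConfusionMatrix",
  slots = c(table = "matrix", classes = "character", ovr = "matrix")
)

setValidity("ConfusionMatrix", function(object) {
  msg <- character()
  if (any(object@table < 0)) msg <- c(msg, "counts must be >= 0")
  n <- sum(object@table)
  if (!all(rowSums(object@ovr) == n))
    msg <- c(msg, "TP+FP+TN+FN must equal n for every class")
  if (length(msg)) msg else TRUE
})

#' Sampling-based Shapley explanation of one prediction
#'
#' Per-feature, per-class marginal contributions (phi) of one explained
#' instance, estimated by the permutation-sampling estimator, together
#' with Monte-Carlo standard errors, the background baseline prediction
#' and the model's prediction for the instance.
#'
#' @slot phi features x classes matrix of Shapley values.
#' @slot se matching matrix of Monte-Carlo standard errors.
#' @slot baseline mean background prediction per class.
#' @slot prediction model output for the explained instance.
#' @slot instance the explained feature vector.
#' @slot nSamples number of Monte-Carlo draws.
#'
#' @seealso [shapleyExplain()], [explainSubgroups()]
#' @export
setClass("ShapleyExplanation",
  slots = c(
    phi = "matrix", se = "matrix", baseline = "numeric",
    prediction = "numeric", instance = "numeric", nSamples = "integer"
  )
)

setValidity("ShapleyExplanation", function(object) {
  msg <- character()
  if (any(!is.finite(object@phi))) msg <- c(msg, "phi must be finite")
  if (any(object@baseline < -1e-8 | object@baseline > 1 + 1e-8))
    msg <- c(msg, "baseline must be valid class probabilities")
  if (length(msg)) msg else TRUE
})

#' Correlation-weighted gene network
#'
#' An undirected gene graph whose edges carry Pearson correlations
#' (kept only above the threshold), whose vertices carry mean beta values
#' and display sizes, and, once [detectCommunities()] has run, a
#' community id per vertex.
#'
#' @slot graph an `igraph` object; edge attribute `r`, vertex attributes
#'   `meanBeta` and `size`.
#' @slot params the [networkParams()] used to build it.
#' @slot membership named integer community ids (empty until detected).
#'
#' @seealso [buildGraph()], [minimumSpanningTree()], [detectCommunities()]
#' @export
setClass("GeneNetwork",
  slots = c(graph = "ANY", params = "list", membership = "integer")
)
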