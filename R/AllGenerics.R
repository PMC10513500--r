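#' @include AllClasses.R
NULL

#' Beta-value matrix of a MethylOmics container
#'
#' @param x a [MethylOmics-class] object.
#' @return probes x samples numeric matrix in \[0, 1\].
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' Expression matrix of a MethylOmics container
#'
#' @param x a [MethylOmics-class] object.
#' @return genes x samples numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Subgroup labels of the samples
#'
#' @param x a [MethylOmics-class] object.
#' @return factor of subgroup labels, one per sample.
#' @export
setGeneric("subgroups", function(x) standardGeneric("subgroups"))

#' Sample metadata table
#'
#' @param x a [MethylOmics-class] object.
#' @return `DataFrame` with subgroup, age, sex, time, event per sample.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylOmics", function(x)
  SummarizedExperiment::assay(x@methylation, "beta"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "MethylOmics", function(x)
  SummarizedExperiment::assay(x@expression, "expr"))

#' @rdname subgroups
#' @export
setMethod("subgroups", "MethylOmics", function(x) {
  cd <- SummarizedExperiment::colData(x@methylation)
  factor(cd$subgroup, levels = unique(cd$subgroup))
})

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "MethylOmics", function(x)
  SummarizedExperiment::colData(x@methylation))

setMethod("show", "MethylOmics", function(object) {
  b <- betaValues(object)
  e <- exprValues(object)
  cat("MethylOmics container\n")
  cat(sprintf("  methylation: %d probes x %d samples (beta)\n", nrow(b), ncol(b)))
  cat(sprintf("  expression : %d genes x %d samples\n", nrow(e), ncol(e)))
  tab <- table(subgroups(object))
  cat("  subgroups  :", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec\n")
  cat("  classes   :", paste(sprintf("%s=%d", names(object@classCounts),
                                     object@classCounts), collapse = ", "), "\n")
  cat(sprintf("  probes    : %d (%d informative), delta=%.2f, noiseSd=%.2f\n",
              object@nProbes, object@nInformative, object@delta, object@noiseSd))
  cat(sprintf("  genes     : %d, coupling=%.2f\n", object@nGenes, object@coupling))
  cat(sprintf("  survival  : censorRate=%.2f, logHR [%s]\n", object@censorRate,
              paste(sprintf("%s=%.2f", names(object@logHR), object@logHR),
                    collapse = ", ")))
  cat(sprintf("  seed      : %d\n", object@seed))
})

setMethod("show", "SubgroupModel", function(object) {
  cat(sprintf("SubgroupModel <%s>\n", object@family))
  cat(sprintf("  classes : %s\n", paste(object@classes, collapse = ", ")))
  cat(sprintf("  features: %d, trained on %d samples (seed %d)\n",
              length(object@featureIds), object@nTrain, object@seed))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, columns = predicted)\n")
  print(object@table)
})

setMethod("show", "ShapleyExplanation", function(object) {
  cat(sprintf("ShapleyExplanation: %d features x %d classes, %d MC draws\n",
              nrow(object@phi), ncol(object@phi), object@nSamples))
  top <- head(order(-apply(abs(object@phi), 1L, max)), 5L)
  print(round(object@phi[top, , drop = FALSE], 4L))
})

setMethod("show", "GeneNetwork", function(object) {
  g <- object@graph
  cat(sprintf("GeneNetwork: %d genes, %d edges", igraph::vcount(g),
              igraph::ecount(g)))
  if (length(object@membership))
    cat(sprintf(", %d communities", length(unique(object@membership))))
  cat("\n")
})

#' Class order of a fitted model
#' @param model a [SubgroupModel-class].
#' @return character vector of class names in prediction column order.
#' @export
modelClasses <- function(model) model@classes

#' Feature ids a model was trained on
#' @param model a [SubgroupModel-class].
#' @return character vector of feature identifiers.
#' @export
modelFeatures <- function(model) model@featureIds

#' Resolved hyperparameters of a fitted model
#'
#' Every hyperparameter actually used in training, including library
#' defaults resolved at run time, so a run log can reproduce the fit.
#'
#' @param model a [SubgroupModel-class].
#' @return named list.
#' @export
modelParams <- function(model) model@params
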