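#' @include AllClasses.R utils.R
NULL

#' Construct a synthetic cohort specification
#'
#' Defaults emulate the structure of a 763-sample medulloblastoma
#' methylation cohort with its minority WNT subgroup of 70 samples; the
#' SHH/Group3/Group4 split is an arbitrary partition of the remainder
#' (only the minority size and the total are canonical). Betas are drawn
#' on the logit scale around subgroup-specific hyper/hypomethylated
#' means and inverse-transformed, giving the bimodal distributions
#' typical of Illumina arrays.
#'
#' @param classCounts named integer vector of samples per subgroup.
#' @param nProbes total probe count.
#' @param nInformative number of subgroup-discriminating probes.
#' @param delta mean beta separation between hyper- and hypomethylated
#'   groups at informative probes, in (0, 1).
#' @param noiseSd Gaussian noise SD on the logit scale.
#' @param nGenes gene count of the coupled expression view.
#' @param coupling shared-signal strength between the views, in \[0, 1\]:
#'   1 means the expression view carries the full subgroup signal,
#'   0 means pure noise.
#' @param censorRate fraction of survival times censored, in \[0, 1).
#' @param logHR named numeric of per-subgroup log hazard ratios; classes
#'   not named default to 0.
#' @param seed integer RNG seed.
#' @return a validated [SyntheticSpec-class].
#' @examples
#' sp <- syntheticSpec(classCounts = c(WNT = 10, SHH = 10, G3 = 10, G4 = 5),
#'                     nProbes = 100, nInformative = 20, seed = 1)
#' sp
#' @export
syntheticSpec <- function(classCounts = c(WNT = 70L, SHH = 200L,
                                          Group3 = 150L, Group4 = 343L),
                          nProbes = 2000L, nInformative = 200L,
                          delta = 0.4, noiseSd = 0.5,
                          nGenes = 1000L, coupling = 0.8,
                          censorRate = 0.3,
                          logHR = NULL, seed = 1L) {
  cc <- as.integer(round(classCounts))
  names(cc) <- names(classCounts)
  hr <- setNames(rep(0, length(cc)), names(cc))
  if (!is.null(logHR)) hr[names(logHR)] <- logHR
  new("SyntheticSpec",
      classCounts = cc, nProbes = as.integer(nProbes),
      nInformative = as.integer(nInformative), delta = delta,
      noiseSd = noiseSd, nGenes = as.integer(nGenes), coupling = coupling,
      censorRate = censorRate, logHR = hr, seed = as.integer(seed))
}

# Subgroup-mean beta for each informative probe: each probe is assigned
# one target subgroup (round-robin) and a direction; the target group sits
# delta away from the others, centred on 0.5.
informativeDesign <- function(spec) {
  groups <- names(spec@classCounts)
  target <- rep(groups, length.out = spec@nInformative)
  hyper <- rep(c(TRUE, FALSE), length.out = spec@nInformative)
  list(target = target, hyper = hyper)
}

#' Generate a labeled synthetic multi-omics cohort
#'
#' Draws a beta-value matrix (probes x samples) and a coupled expression
#' matrix (genes x samples) sharing the same latent subgroup block
#' structure on their informative features; non-informative features are
#' label-independent noise. Informative probes place the target subgroup
#' `delta` away in mean beta (0.5 +/- delta/2 versus the complement),
#' with `noiseSd` Gaussian noise added on the logit scale so betas stay
#' in \[0, 1\] and are bimodal. Sample metadata (age, sex, survival) is
#' attached via [generateSurvival()].
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [MethylOmics-class] container.
#' @examples
#' om <- generateOmics(syntheticSpec(
#'   classCounts = c(A = 10, B = 10, C = 10, D = 5),
#'   nProbes = 60, nInformative = 12, nGenes = 40, seed = 7))
#' om
#' @export
generateOmics <- function(spec) {
  validObject(spec)
  groups <- names(spec@classCounts)
  labels <- factor(rep(groups, times = spec@classCounts), levels = groups)
  n <- length(labels)
  withSeed(deriveSeed(spec@seed, "omics"), {
    des <- informativeDesign(spec)
    eps <- 0.001
    # informative probes: group-specific means on the beta scale
    betaMeans <- matrix(0.5 - spec@delta / 2, spec@nInformative, n)
    for (j in seq_len(spec@nInformative)) {
      hit <- labels == des$target[j]
      betaMeans[j, hit] <- 0.5 + spec@delta / 2
      if (!des$hyper[j]) betaMeans[j, ] <- 1 - betaMeans[j, ]
    }
    # background probes: per-probe bimodal baseline shared by all groups
    nBg <- spec@nProbes - spec@nInformative
    bg <- clip(rbinom(nBg, 1L, 0.5) * 0.7 + 0.15 +
                 rnorm(nBg, sd = 0.05), eps, 1 - eps)
    bgMeans <- matrix(bg, nBg, n)
    mu <- qlogis(clip(rbind(betaMeans, bgMeans), eps, 1 - eps))
    beta <- plogis(mu + matrix(rnorm(length(mu), sd = spec@noiseSd),
                               nrow(mu), ncol(mu)))
    beta <- clip(beta, 0, 1)
    probeIds <- sprintf("cg%07d", seq_len(spec@nProbes))
    sampleIds <- sprintf("S%04d", seq_len(n))
    dimnames(beta) <- list(probeIds, sampleIds)

    # expression view: same latent blocks on a matched share of genes
    nInfG <- max(1L, min(spec@nGenes,
                         as.integer(round(spec@nGenes * spec@nInformative /
                                            spec@nProbes))))
    expr <- matrix(rnorm(spec@nGenes * n), spec@nGenes, n)
    targetG <- rep(groups, length.out = nInfG)
    for (j in seq_len(nInfG)) {
      hit <- labels == targetG[j]
      expr[j, hit] <- expr[j, hit] + spec@coupling * 3
    }
    geneIds <- sprintf("GENE%05d", seq_len(spec@nGenes))
    dimnames(expr) <- list(geneIds, sampleIds)

    surv <- generateSurvival(labels, spec)
    cd <- S4Vectors::DataFrame(
      subgroup = as.character(labels),
      age = surv$age, sex = surv$sex,
      time = surv$time, event = surv$event,
      row.names = sampleIds)
    methSE <- SummarizedExperiment::SummarizedExperiment(
      assays = list(beta = beta), colData = cd)
    exprSE <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = expr), colData = cd)
    new("MethylOmics", methylation = methSE, expression = exprSE)
  })
}

#' Construct a MethylOmics container from matrices
#'
#' @param beta probes x samples beta matrix in \[0, 1\].
#' @param expression genes x samples expression matrix over the same
#'   samples.
#' @param sampleData data.frame/DataFrame of per-sample metadata with at
#'   least a `subgroup` column.
#' @return a [MethylOmics-class].
#' @export
MethylOmics <- function(beta, expression, sampleData) {
  checkMatrix(beta, "beta")
  checkMatrix(expression, "expression")
  cd <- S4Vectors::DataFrame(sampleData)
  rownames(cd) <- colnames(beta)
  new("MethylOmics",
      methylation = SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta), colData = cd),
      expression = SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = expression), colData = cd))
}

#' Generate intensity matrices consistent with target beta values
#'
#' Inverse construction of the beta formula `M / (M + U + offset)`:
#' integer methylated/unmethylated intensities are built so that applying
#' the formula recovers the target betas within 0.01, together with a
#' detection p-value matrix in which a configurable fraction of probes
#' "fail" (p > alpha) in a configurable fraction of samples.
#'
#' @param spec a [SyntheticSpec-class] (supplies the seed).
#' @param targetBeta probes x samples matrix with values in \[0, 1).
#' @param totalIntensity nominal M + U total per probe (default 10000).
#' @param offset the beta-formula offset (default 100).
#' @param failFrac fraction of probes designated as failing.
#' @param failSampleFrac fraction of samples in which a failing probe has
#'   p > alpha.
#' @param alpha detection p-value threshold (default 0.05).
#' @return list with integer matrices `M` and `U` and p-value matrix `P`;
#'   failing probe ids in `attr(P, "failing")`.
#' @examples
#' sp <- syntheticSpec(seed = 1)
#' tb <- matrix(c(0, 0.5, 0.9), 3, 2, dimnames = list(paste0("p", 1:3), NULL))
#' ii <- generateIntensities(sp, tb)
#' max(abs(computeBeta(ii$M, ii$U) - tb)) < 0.01
#' @export
generateIntensities <- function(spec, targetBeta, totalIntensity = 10000,
                                offset = 100, failFrac = 0,
                                failSampleFrac = 0.1, alpha = 0.05) {
  checkMatrix(targetBeta, "targetBeta")
  if (any(targetBeta < 0) || any(targetBeta >= 1))
    stopMsg("target beta values must lie in [0, 1): beta = 1 is unreachable with a positive offset")
  withSeed(deriveSeed(spec@seed, "intensities"), {
    # per-entry total S such that U = S - M stays nonnegative:
    # need S >= offset * beta / (1 - beta)
    S <- pmax(totalIntensity, ceiling(offset * targetBeta / (1 - targetBeta)) + offset)
    M <- round(targetBeta * (S + offset))
    U <- S - M
    nProbe <- nrow(targetBeta)
    P <- matrix(runif(length(targetBeta), 0, alpha * 0.8),
                nProbe, ncol(targetBeta), dimnames = dimnames(targetBeta))
    failing <- character()
    nFail <- round(failFrac * nProbe)
    if (nFail > 0) {
      idx <- sample.int(nProbe, nFail)
      failing <- rownames(targetBeta)[idx]
      for (i in idx) {
        bad <- sample.int(ncol(P), max(1L, round(failSampleFrac * ncol(P))))
        P[i, bad] <- runif(length(bad), alpha + 1e-6, 1)
      }
    }
    attr(P, "failing") <- failing
    list(M = M, U = U, P = P)
  })
}

#' Generate subgroup-dependent survival data
#'
#' Event times are exponential with per-subgroup hazard
#' `lambda0 * exp(logHR[subgroup])`; censoring is an independent
#' exponential whose rate is set so the expected censored fraction
#' matches `censorRate`. Ages are drawn from a truncated normal matching
#' a pediatric cohort (mean 10.4, SD 9.4 years) and sex from a 66% male
#' Bernoulli.
#'
#' @param labels factor/character of subgroup labels.
#' @param spec a [SyntheticSpec-class] (supplies `logHR`, `censorRate`,
#'   seed).
#' @param lambda0 baseline yearly hazard (default 0.08).
#' @return data.frame with sample, subgroup, age, sex, time (years,
#'   > 0), event (1 death / 0 censored).
#' @export
generateSurvival <- function(labels, spec, lambda0 = 0.08) {
  if (!length(labels)) stopMsg("labels must be nonempty")
  labels <- as.character(labels)
  if (!all(labels %in% names(spec@logHR)))
    stopMsg("labels contain classes not named in spec logHR")
  withSeed(deriveSeed(spec@seed, "survival"), {
    n <- length(labels)
    rate <- lambda0 * exp(spec@logHR[labels])
    eventTime <- rexp(n, rate = rate)
    if (spec@censorRate > 0) {
      cRate <- spec@censorRate / (1 - spec@censorRate) * mean(rate)
      censTime <- rexp(n, rate = cRate)
    } else {
      censTime <- rep(Inf, n)
    }
    time <- pmin(eventTime, censTime)
    event <- as.integer(eventTime <= censTime)
    age <- clip(rnorm(n, 10.43, 9.43), 0.1, 80)
    sex <- ifelse(runif(n) < 0.6565, "M", "F")
    data.frame(sample = if (!is.null(names(labels))) names(labels)
               else sprintf("S%04d", seq_len(n)),
               subgroup = labels, age = age, sex = sex,
               time = pmax(time, 1e-4), event = event,
               stringsAsFactors = FALSE)
  })
}

#' Write a MethylOmics container as TSV files
#'
#' Writes `beta.tsv` and `expression.tsv` (features x samples, header row
#' = sample ids, first column = feature id) and `metadata.tsv`
#' (sample_id, subgroup, age, sex, time, event) into `dir`.
#'
#' @param omics a [MethylOmics-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeOmics <- function(omics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("beta.tsv", "expression.tsv", "metadata.tsv"))
  writeMatrixTSV(betaValues(omics), paths[1L])
  writeMatrixTSV(exprValues(omics), paths[2L])
  cd <- as.data.frame(sampleInfo(omics))
  meta <- data.frame(sample_id = rownames(cd), cd, row.names = NULL,
                     check.names = FALSE)
  utils::write.table(meta, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write a features-x-samples matrix as TSV
#' @param x numeric matrix with row and column names.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeMatrixTSV <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features-x-samples TSV matrix
#' @param path TSV written by [writeMatrixTSV()] (first column feature
#'   id, header row sample ids).
#' @return numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
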