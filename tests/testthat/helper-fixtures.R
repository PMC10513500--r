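# Shared fixtures: small synthetic cohorts built in code.

tinySpec <- function(seed = 3L, ...) {
  args <- list(classCounts = c(WNT = 15L, SHH = 25L, Group3 = 20L,
                               Group4 = 30L),
               nProbes = 300L, nInformative = 60L, delta = 0.4,
               noiseSd = 0.05, nGenes = 200L, coupling = 0.8, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(syntheticSpec, args)
}

tinyOmics <- function(seed = 3L, ...) generateOmics(tinySpec(seed, ...))

# Well-separated labeled feature matrix for classifier tests.
separableData <- function(nPerClass = 30L, nFeatures = 40L, seed = 5L) {
  om <- generateOmics(syntheticSpec(
    classCounts = setNames(rep(nPerClass, 4L),
                           c("WNT", "SHH", "Group3", "Group4")),
    nProbes = nFeatures, nInformative = as.integer(nFeatures / 2),
    delta = 0.4, noiseSd = 0.05, nGenes = 10L, seed = seed))
  list(x = t(betaValues(om)), y = subgroups(om))
}

# Tiny hand-checkable survival data.
handSurvival <- function() {
  data.frame(
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    group = rep(c("A", "B"), 4),
    stringsAsFactors = FALSE)
}
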