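#' @include utils.R synthetic.R integration.R features.R models.R evaluate.R
NULL

#' Default pipeline configuration
#'
#' One document holding every stage's parameters at the package
#' defaults: SNF K=51/mu=0.85/t=120/k=4; MAD top 5000 then RF top 399;
#' SMOTE 200% on the minority class; 0.8 train split and 10 folds; the
#' [annConfig()] network; gene-network r threshold 0.6 and minimum
#' degree 2. All randomness flows from the root `seed` via per-stage
#' derived seeds.
#'
#' @param seed root RNG seed.
#' @return nested named list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(classCounts = c(WNT = 20L, SHH = 50L, Group3 = 40L,
                                     Group4 = 80L),
                     nProbes = 1200L, nInformative = 120L, delta = 0.4,
                     noiseSd = 0.5, nGenes = 500L, coupling = 0.8,
                     censorRate = 0.3),
    snf = list(K = 51L, mu = 0.85, t = 120L, kClusters = 4L),
    features = list(nTop = 5000L, nSelect = 399L),
    smote = list(percOver = 200, kNeighbors = 5L),
    split = list(trainFrac = 0.8, kFolds = 10L),
    models = list(families = c("RF", "SVM", "KNN", "NB", "XGB", "LDA", "ANN")),
    ann = list(epochs = 60L),
    network = list(rThreshold = 0.6, minDegree = 2L, sizeScale = 10),
    smoteBeforeSplit = FALSE
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stopMsg("unknown config key: '%s'", nm)
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full synthetic-cohort workflow
#'
#' Orchestrates simulate, fuse and relabel, feature selection, SMOTE
#' balancing of the training partition, training of the requested model
#' families (on fused labels; scoring is always against the original
#' labels), and evaluation. Every stage's output is persisted under
#' `outDir` together with a manifest of md5 checksums and a run log
#' recording every resolved hyperparameter. Identical config + seed
#' reproduces identical selected-probe lists and manifest checksums for
#' the deterministic stages.
#'
#' SMOTE is applied to the training partition only by default;
#' `smoteBeforeSplit = TRUE` oversamples the full cohort before splitting,
#' which leaks interpolated copies of test samples into training and is
#' provided for comparison only.
#'
#' @param config overrides merged into [defaultRunConfig()].
#' @param outDir output directory.
#' @param seed root seed (overrides the config's).
#' @return invisibly, a list with the per-family metrics table, the
#'   selected panel, the integration result, and the artifact manifest.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("methylfuse_run"),
                        seed = NULL) {
  cfg <- mergeConfig(defaultRunConfig(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logPath, append = TRUE)
  cat("", file = logPath)
  logLine("resolved config: %s",
          jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))

  # simulate
  spec <- do.call(syntheticSpec,
                  c(cfg$synthetic, list(seed = deriveSeed(cfg$seed, "sim"))))
  omics <- generateOmics(spec)
  writeOmics(omics, file.path(outDir, "simulated"))

  # integrate
  params <- do.call(snfParams, cfg$snf)
  integ <- integrateOmics(omics, params, seed = deriveSeed(cfg$seed, "snf"))
  writeMatrixTSV(integ$fused, file.path(outDir, "fused_affinity.tsv"))
  utils::write.table(
    data.frame(sample_id = colnames(betaValues(omics)),
               cluster = integ$clusters, fused_label = integ$labels,
               original = as.character(subgroups(omics))),
    file.path(outDir, "fused_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  logLine("fusion NMI vs original labels: %.4f", integ$nmi)

  # feature selection
  beta <- betaValues(omics)
  nTop <- min(cfg$features$nTop, nrow(beta))
  top <- madSelect(beta, nTop)
  nSel <- min(cfg$features$nSelect, length(top))
  panel <- rfImportanceSelect(beta[top, , drop = FALSE], integ$labels,
                              nSelect = nSel,
                              seed = deriveSeed(cfg$seed, "rfsel"))
  writeLines(panel, file.path(outDir, "selected_probes.txt"))
  logLine("feature chain: %d -> %d (MAD) -> %d (RF)", nrow(beta), nTop, nSel)

  # split; training labels are the fused relabeling, scoring labels the
  # originals
  x <- t(beta[panel, , drop = FALSE])
  yTrainLab <- factor(integ$labels, levels = levels(subgroups(omics)))
  yTrue <- subgroups(omics)
  sp <- splitData(yTrue, trainFrac = cfg$split$trainFrac,
                  seed = deriveSeed(cfg$seed, "split"))
  jsonlite::write_json(lapply(makeFolds(yTrue[sp$train], cfg$split$kFolds,
                                        seed = deriveSeed(cfg$seed, "folds")),
                              identity),
                       file.path(outDir, "folds.json"))

  if (isTRUE(cfg$smoteBeforeSplit)) {
    bal <- smoteBalance(x, as.character(yTrainLab),
                        percOver = cfg$smote$percOver,
                        kNeighbors = cfg$smote$kNeighbors,
                        seed = deriveSeed(cfg$seed, "smote"))
    xtr <- bal$x[c(sp$train, nrow(x) + seq_len(nrow(bal$x) - nrow(x))), ,
                 drop = FALSE]
    ytr <- bal$y[c(sp$train, nrow(x) + seq_len(nrow(bal$x) - nrow(x)))]
    logLine("SMOTE applied before splitting (leakage-prone)")
  } else {
    bal <- smoteBalance(x[sp$train, , drop = FALSE],
                        as.character(yTrainLab)[sp$train],
                        percOver = cfg$smote$percOver,
                        kNeighbors = cfg$smote$kNeighbors,
                        seed = deriveSeed(cfg$seed, "smote"))
    xtr <- bal$x; ytr <- bal$y
  }
  logLine("training samples after SMOTE: %d (%s)", length(ytr),
          paste(sprintf("%s=%d", names(table(ytr)), table(ytr)),
                collapse = ", "))

  # train + evaluate each family against the ORIGINAL test labels
  metrics <- list()
  for (fam in cfg$models$families) {
    extra <- if (fam == "ANN") cfg$ann else list()
    m <- trainModel(xtr, ytr, fam, params = extra,
                    seed = deriveSeed(cfg$seed, fam))
    logLine("[%s] resolved params: %s", fam,
            jsonlite::toJSON(modelParams(m)[!vapply(modelParams(m), is.function,
                                                    logical(1L))],
                             auto_unbox = TRUE, digits = NA, force = TRUE))
    pr <- predictSubgroups(m, x[sp$test, , drop = FALSE])
    cm <- confusionCounts(as.character(yTrue)[sp$test],
                          as.character(pr$class), classes = levels(yTrue))
    met <- classMetrics(cm)
    met$model <- fam
    met$auc <- tryCatch(multiclassAUC(yTrue[sp$test], pr$prob),
                        error = function(e) NA_real_)
    metrics[[fam]] <- met
  }
  metricsTab <- do.call(rbind, metrics)
  utils::write.table(metricsTab, file.path(outDir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(file = sub(paste0(outDir, "/"), "", files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(metrics = metricsTab, panel = panel, integration = integ,
                 split = sp, manifest = manifest, outDir = outDir))
}
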