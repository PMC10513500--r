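#' @include utils.R
NULL

#' Select the most variable probes by median absolute deviation
#'
#' Probes are ranked by per-probe MAD (unscaled: the 1.4826 consistency
#' factor never changes ranks) in descending order, ties broken by probe
#' id lexicographically, and the top `nTop` are returned.
#'
#' @param beta probes x samples matrix with probe rownames.
#' @param nTop number of probes to keep (default 5000).
#' @return character vector of `nTop` probe ids.
#' @export
madSelect <- function(beta, nTop = 5000L) {
  checkMatrix(beta, "beta")
  if (is.null(rownames(beta))) stopMsg("beta must have probe rownames")
  if (nTop > nrow(beta)) stopMsg("nTop exceeds the number of probes")
  m <- apply(beta, 1L, stats::mad, constant = 1)
  ids <- rownames(beta)
  ord <- order(-m, ids)
  ids[ord][seq_len(nTop)]
}

#' Select probes by random-forest importance
#'
#' Grows a random forest over the (already variance-filtered) probes and
#' ranks them by importance aggregated across subgroups: the per-class
#' permutation importances are averaged ("across all subgroups"), with
#' Gini impurity importance available as an alternative. Returns the top
#' `nSelect` probes; ties broken by probe id.
#'
#' @param beta probes x samples matrix (typically the MAD-filtered top
#'   5000).
#' @param labels subgroup per sample (>= 2 classes).
#' @param nTrees trees to grow (default 300).
#' @param nSelect panel size (default 399).
#' @param seed RNG seed.
#' @param type `"permutation"` (default) or `"gini"`.
#' @return character vector of `nSelect` probe ids, importance in
#'   `attr(, "importance")`.
#' @export
rfImportanceSelect <- function(beta, labels, nTrees = 300L, nSelect = 399L,
                               seed = 1L, type = c("permutation", "gini")) {
  checkMatrix(beta, "beta")
  type <- match.arg(type)
  y <- factor(labels)
  if (nlevels(y) < 2L) stopMsg("labels must contain >= 2 classes")
  if (nSelect > nrow(beta)) stopMsg("nSelect exceeds the number of probes")
  x <- t(beta)
  colnames(x) <- rownames(beta)
  fit <- withSeed(seed,
    randomForest::randomForest(x = x, y = y, ntree = nTrees,
                               importance = (type == "permutation")))
  imp <- randomForest::importance(fit)
  score <- if (type == "permutation") {
    rowMeans(imp[, levels(y), drop = FALSE])
  } else {
    imp[, "MeanDecreaseGini"]
  }
  ord <- order(-score, names(score))
  out <- names(score)[ord][seq_len(nSelect)]
  attr(out, "importance") <- score[ord][seq_len(nSelect)]
  out
}

#' Split samples into train/test (or train/test/validation) sets
#'
#' Two-way split at `trainFrac` (default 0.8) or, with
#' `threeWay = TRUE`, the 0.6/0.2/0.2 split used for neural-network
#' training. Stratification preserves class proportions within one
#' sample per class.
#'
#' @param y labels, one per sample.
#' @param trainFrac training fraction (default 0.8).
#' @param threeWay if TRUE split 0.6/0.2/0.2 into
#'   train/validation/test.
#' @param stratified stratify on `y` (default TRUE).
#' @param seed RNG seed.
#' @return list of disjoint index vectors covering all samples:
#'   `train`, `test`, and (three-way only) `validation`.
#' @export
splitData <- function(y, trainFrac = 0.8, threeWay = FALSE,
                      stratified = TRUE, seed = 1L) {
  n <- length(y)
  if (n < 5L) stopMsg("need at least 5 samples")
  if (trainFrac <= 0 || trainFrac >= 1) stopMsg("trainFrac must lie in (0, 1)")
  fracs <- if (threeWay) c(train = 0.6, validation = 0.2, test = 0.2)
           else c(train = trainFrac, test = 1 - trainFrac)
  withSeed(seed, {
    pools <- if (stratified) {
      cls <- split(seq_len(n), y)
      if (any(lengths(cls) < 2L))
        stopMsg("stratified split needs >= 2 samples per class")
      cls
    } else list(seq_len(n))
    parts <- setNames(vector("list", length(fracs)), names(fracs))
    for (pool in pools) {
      pool <- sample(pool)
      sizes <- floor(fracs * length(pool))
      # distribute the rounding remainder to the largest fractions
      rem <- length(pool) - sum(sizes)
      if (rem > 0) {
        ord <- order(-(fracs * length(pool) - sizes))
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
      }
      at <- 0L
      for (p in names(fracs)) {
        parts[[p]] <- c(parts[[p]], pool[at + seq_len(sizes[p])])
        at <- at + sizes[p]
      }
    }
    lapply(parts, sort)
  })
}

#' Build k cross-validation folds
#'
#' Indices are shuffled within class and dealt round-robin to folds, so
#' fold sizes differ by at most one and class proportions are
#' approximately preserved.
#'
#' @param y labels, one per sample.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return list of `k` disjoint test-index vectors partitioning all
#'   samples.
#' @export
makeFolds <- function(y, k = 10L, seed = 1L) {
  n <- length(y)
  if (k > n) stopMsg("k cannot exceed the number of samples")
  if (k < 2L) stopMsg("k must be >= 2")
  withSeed(seed, {
    idx <- unlist(lapply(split(seq_len(n), y), sample), use.names = FALSE)
    fold <- rep(seq_len(k), length.out = n)
    out <- split(idx, fold)
    names(out) <- sprintf("Fold%02d", seq_len(k))
    lapply(out, sort)
  })
}

#' SMOTE: interpolated synthetic minority samples
#'
#' For each minority sample, `percOver / 100` synthetic points are
#' created by `x + u * (neighbor - x)` with `u ~ Uniform(0, 1)` and the
#' neighbor drawn among the sample's `kNeighbors` nearest minority
#' neighbors (Euclidean). Every synthetic coordinate therefore lies
#' within the segment between its two parents.
#'
#' @param x minority-class samples x features matrix.
#' @param kNeighbors neighbors to interpolate with (default 5).
#' @param percOver oversampling percentage, a positive multiple of 100
#'   (default 200, i.e. two synthetic points per original).
#' @param seed RNG seed.
#' @return matrix of `nrow(x) * percOver / 100` synthetic samples.
#' @examples
#' x <- matrix(rnorm(70 * 4), 70, 4)
#' nrow(smote(x, percOver = 200, seed = 1))  # 140
#' @export
smote <- function(x, kNeighbors = 5L, percOver = 200, seed = 1L) {
  checkMatrix(x, "x")
  if (percOver <= 0 || percOver %% 100 != 0)
    stopMsg("percOver must be a positive multiple of 100")
  n <- nrow(x)
  if (n <= kNeighbors)
    stopMsg("minority count (%d) must exceed kNeighbors (%d)", n, kNeighbors)
  reps <- percOver / 100
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  withSeed(seed, {
    out <- matrix(NA_real_, n * reps, ncol(x))
    colnames(out) <- colnames(x)
    parents <- data.frame(base = integer(n * reps),
                          neighbor = integer(n * reps),
                          u = numeric(n * reps))
    row <- 0L
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[seq_len(kNeighbors)]
      for (r in seq_len(reps)) {
        j <- nb[sample.int(kNeighbors, 1L)]
        u <- runif(1L)
        row <- row + 1L
        out[row, ] <- x[i, ] + u * (x[j, ] - x[i, ])
        parents[row, ] <- list(i, j, u)
      }
    }
    rownames(out) <- sprintf("syn%04d", seq_len(nrow(out)))
    attr(out, "parents") <- parents
    out
  })
}

#' Oversample minority classes of a labeled dataset
#'
#' Applies [smote()] to one class (default usage: the 70-sample minority
#' at 200% giving 210) or, with `toMajority = TRUE`, to every
#' non-majority class until it reaches the majority size. Best applied
#' to the training partition only: oversampling before splitting leaks
#' synthetic copies of test samples into training.
#'
#' @param x samples x features matrix.
#' @param y labels.
#' @param class class to oversample (default: the rarest).
#' @param percOver oversampling percentage for the single-class case.
#' @param kNeighbors SMOTE neighbors.
#' @param toMajority oversample every non-majority class up to the
#'   majority count (rounded down to a multiple of 100%).
#' @param seed RNG seed.
#' @return list with augmented `x` and `y`.
#' @export
smoteBalance <- function(x, y, class = NULL, percOver = 200, kNeighbors = 5L,
                         toMajority = FALSE, seed = 1L) {
  checkMatrix(x, "x")
  y <- as.character(y)
  counts <- table(y)
  if (toMajority) {
    maj <- max(counts)
    for (cl in names(counts)) {
      need <- maj - counts[[cl]]
      if (need <= 0) next
      # SMOTE rounds of 100% each; the last round is subset to hit the
      # majority count exactly
      rounds <- ceiling(need / counts[[cl]])
      xs <- smote(x[y == cl, , drop = FALSE], kNeighbors = kNeighbors,
                  percOver = rounds * 100, seed = deriveSeed(seed, cl))
      xs <- xs[seq_len(need), , drop = FALSE]
      x <- rbind(x, xs)
      y <- c(y, rep(cl, nrow(xs)))
    }
  } else {
    cl <- if (is.null(class)) names(which.min(counts)) else class
    xs <- smote(x[y == cl, , drop = FALSE], kNeighbors = kNeighbors,
                percOver = percOver, seed = deriveSeed(seed, cl))
    x <- rbind(x, xs)
    y <- c(y, rep(cl, nrow(xs)))
  }
  list(x = x, y = y)
}

#' Collapse probe values to genes by median
#'
#' Probes without a gene symbol are dropped; when several probes
#' annotate the same gene, the per-sample gene value is the median over
#' that gene's probes.
#'
#' @param values probes x samples matrix.
#' @param ann annotation data.frame with `probe_id` and `gene` columns
#'   covering every probe.
#' @return genes x samples matrix with unique gene rownames.
#' @export
annotateCollapse <- function(values, ann) {
  checkMatrix(values, "values")
  missing <- setdiff(rownames(values), ann$probe_id)
  if (length(missing))
    stopMsg("probes missing from annotation: %s",
            paste(head(missing, 5L), collapse = ", "))
  gene <- ann$gene[match(rownames(values), ann$probe_id)]
  keep <- !is.na(gene) & nzchar(gene)
  if (!any(keep)) {
    warning("no probe has a gene annotation; returning empty matrix",
            call. = FALSE)
    return(values[0L, , drop = FALSE])
  }
  v <- values[keep, , drop = FALSE]
  g <- gene[keep]
  genes <- unique(g)
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  for (gn in genes) {
    rows <- v[g == gn, , drop = FALSE]
    out[gn, ] <- apply(rows, 2L, median)
  }
  out
}
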