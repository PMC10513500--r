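#' @include AllClasses.R utils.R
NULL

#' Build a confusion matrix with one-vs-rest counts
#'
#' @param true true labels.
#' @param pred predicted labels, same length.
#' @param classes class set (default: union of labels, in order of
#'   appearance in `true` then `pred`).
#' @return a [ConfusionMatrix-class].
#' @export
confusionCounts <- function(true, pred, classes = NULL) {
  if (length(true) != length(pred)) stopMsg("label vectors must have equal length")
  true <- as.character(true); pred <- as.character(pred)
  if (is.null(classes)) classes <- unique(c(true, pred))
  bad <- setdiff(c(true, pred), classes)
  if (length(bad)) stopMsg("labels outside the class set: %s",
                           paste(unique(bad), collapse = ", "))
  tab <- table(factor(true, levels = classes), factor(pred, levels = classes))
  tab <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = list(true = classes, predicted = classes))
  n <- sum(tab)
  ovr <- t(vapply(classes, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    tn <- n - tp - fp - fn
    c(TP = tp, FP = fp, TN = tn, FN = fn)
  }, numeric(4L)))
  new("ConfusionMatrix", table = tab, classes = classes, ovr = ovr)
}

safeRatio <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Per-class performance metrics from a confusion matrix
#'
#' One-vs-rest metrics by the standard count formulas:
#' accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), and F1 2TP/(2TP+FP+FN).
#' Undefined ratios (0/0) are reported as `NA`, never as 0. A `macro`
#' row carries the mean of the per-class values.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return data.frame with one row per class plus a macro row.
#' @export
classMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  o <- cm@ovr
  tp <- o[, "TP"]; fp <- o[, "FP"]; tn <- o[, "TN"]; fn <- o[, "FN"]
  df <- data.frame(
    class = cm@classes,
    accuracy = safeRatio(tp + tn, tp + tn + fp + fn),
    precision = safeRatio(tp, tp + fp),
    sensitivity = safeRatio(tp, tp + fn),
    specificity = safeRatio(tn, tn + fp),
    f1 = safeRatio(2 * tp, 2 * tp + fp + fn),
    row.names = NULL)
  macro <- data.frame(class = "macro", t(colMeans(df[, -1L], na.rm = TRUE)))
  rbind(df, macro)
}

binaryAUC <- function(scorePos, scoreNeg) {
  n1 <- length(scorePos); n0 <- length(scoreNeg)
  r <- rank(c(scorePos, scoreNeg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUC by the Hand-Till construction
#'
#' The mean over all unordered class pairs (i, j) of the average of the
#' two one-vs-one rank AUCs `A(i|j)` and `A(j|i)`, each computed from
#' the corresponding class-probability column restricted to samples of
#' the two classes. Equals the standard rank-based AUC in the binary
#' case, 1 for perfect separation, 0.5 for label-independent scores.
#'
#' @param true labels.
#' @param probs samples x classes probability matrix (rows sum to 1)
#'   with class column names.
#' @return AUC in \[0, 1\].
#' @export
multiclassAUC <- function(true, probs) {
  checkMatrix(probs, "probs")
  true <- as.character(true)
  if (length(true) != nrow(probs)) stopMsg("labels and rows disagree")
  classes <- intersect(colnames(probs), unique(true))
  if (length(classes) < 2L) stopMsg("need >= 2 observed classes")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  vals <- vapply(pairs, function(p) {
    i <- p[1L]; j <- p[2L]
    ii <- true == i; jj <- true == j
    aij <- binaryAUC(probs[ii, i], probs[jj, i])
    aji <- binaryAUC(probs[jj, j], probs[ii, j])
    (aij + aji) / 2
  }, numeric(1L))
  mean(vals)
}

#' PCA decision grid for classifier visualization
#'
#' PCA is fitted on the training set only; train and test sets are
#' projected onto the first two components; a rectangular grid spanning
#' the projected ranges (plus a 5% margin) is classified by a model of
#' the requested family refitted on the two projected training
#' coordinates. The grid labels paint the decision regions behind the
#' projected points.
#'
#' @param xTrain,yTrain training features and labels.
#' @param xTest,yTest test features and labels.
#' @param family model family code for the 2-D refit (see
#'   [trainModel()]).
#' @param resolution grid nodes per axis (>= 2; `resolution^2` total).
#' @param params hyperparameter overrides for the refit.
#' @param seed RNG seed.
#' @return list with `grid` (data.frame PC1, PC2, label), `train` and
#'   `test` (projected points with true labels), and `rotation`.
#' @export
pcaGrid <- function(xTrain, yTrain, xTest, yTest, family = "XGB",
                    resolution = 100L, params = list(), seed = 1L) {
  checkMatrix(xTrain, "xTrain")
  if (ncol(xTrain) < 2L) stopMsg("need >= 2 features")
  if (resolution < 2L) stopMsg("resolution must be >= 2")
  pca <- prcomp(xTrain, center = TRUE, scale. = FALSE, rank. = 2L)
  ptr <- predict(pca, xTrain)[, 1:2, drop = FALSE]
  pte <- predict(pca, xTest)[, 1:2, drop = FALSE]
  colnames(ptr) <- colnames(pte) <- c("PC1", "PC2")
  m <- trainModel(ptr, yTrain, family, params = params, seed = seed)
  rng <- apply(ptr, 2L, range)
  pad <- 0.05 * (rng[2L, ] - rng[1L, ])
  g1 <- seq(rng[1L, 1L] - pad[1L], rng[2L, 1L] + pad[1L],
            length.out = resolution)
  g2 <- seq(rng[1L, 2L] - pad[2L], rng[2L, 2L] + pad[2L],
            length.out = resolution)
  grid <- as.matrix(expand.grid(PC1 = g1, PC2 = g2))
  lab <- predictSubgroups(m, grid)$class
  list(grid = data.frame(grid, label = lab),
       train = data.frame(ptr, label = yTrain),
       test = data.frame(pte, label = yTest),
       rotation = pca$rotation)
}

#' t-SNE embedding of samples
#'
#' Exact (non-approximate) t-distributed stochastic neighbor embedding:
#' input affinities calibrated per point to the target perplexity by
#' binary search over the Gaussian bandwidth, symmetrized, then the
#' Student-t low-dimensional similarities fitted by gradient descent
#' with momentum and early exaggeration. Deterministic given the seed.
#' Intended for the desk-scale sample counts this package deals in.
#'
#' @param x samples x features matrix.
#' @param dims 2 or 3 output dimensions.
#' @param perplexity target perplexity (default 30; requires
#'   `n > 3 * perplexity`).
#' @param maxIter gradient-descent iterations (default 500).
#' @param seed RNG seed.
#' @return n x dims coordinate matrix.
#' @export
tsneEmbed <- function(x, dims = 2L, perplexity = 30, maxIter = 500L,
                      seed = 1L) {
  checkMatrix(x, "x")
  n <- nrow(x)
  if (!dims %in% c(2L, 3L)) stopMsg("dims must be 2 or 3")
  if (n <= 3 * perplexity) stopMsg("perplexity too large: need n > 3 * perplexity")
  D <- pairwiseSqDistance(x)
  # per-point bandwidth via binary search on entropy
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    betaLo <- -Inf; betaHi <- Inf; beta <- 1
    di <- D[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betaLo <- beta
        beta <- if (is.finite(betaHi)) (beta + betaHi) / 2 else beta * 2
      } else {
        betaHi <- beta
        beta <- if (is.finite(betaLo)) (beta + betaLo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
    G <- matrix(0, n, dims); gains <- matrix(1, n, dims)
    mom <- 0.5; eta <- 200
    exag <- 12
    for (it in seq_len(maxIter)) {
      Pe <- if (it <= 100) P * exag else P
      sq <- rowSums(Y^2)
      num <- 1 / (1 + outer(sq, sq, "+") - 2 * Y %*% t(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      G <- mom * G - eta * gains * grad
      Y <- Y + G
      Y <- scale(Y, center = TRUE, scale = FALSE)
      if (it == 250) mom <- 0.8
    }
    rownames(Y) <- rownames(x)
    colnames(Y) <- paste0("tSNE", seq_len(dims))
    Y
  })
}

#' Heatmap export: values with clustered orderings
#'
#' Emits the value matrix together with row and column orderings from
#' hierarchical clustering on correlation distance (average linkage);
#' rendering is left to any plotting layer.
#'
#' @param x features x samples matrix.
#' @return list with `values`, `rowOrder`, `colOrder`.
#' @export
heatmapData <- function(x) {
  checkMatrix(x, "x")
  corDist <- function(m) stats::as.dist(1 - suppressWarnings(cor(t(m))))
  safeOrder <- function(m) {
    if (nrow(m) < 3L) return(seq_len(nrow(m)))
    d <- corDist(m)
    if (anyNA(d)) d[is.na(d)] <- 1
    stats::hclust(d, method = "average")$order
  }
  list(values = x, rowOrder = safeOrder(x), colOrder = safeOrder(t(x)))
}
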