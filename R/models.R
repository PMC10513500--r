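#' @include utils.R ann.R
NULL

MODEL_FAMILIES <- c("RF", "SVM", "KNN", "NB", "XGB", "LDA", "ANN")

#' Train a subgroup classifier
#'
#' Trains one of the seven supported families with the package's
#' defaults: RF with 300 trees and at most 6 terminal nodes per tree;
#' SVM with a radial kernel (library-default cost/gamma, recorded in the
#' resolved parameters); KNN with 3 nearest neighbors; naive Bayes with
#' a 0.8 probability threshold flagging low-confidence calls; XGBoost
#' and LDA with library defaults (recorded); and the feed-forward
#' network of [trainAnn()]. Every resolved hyperparameter is stored in
#' the returned model ([modelParams()]), so runs are reproducible from
#' the run log.
#'
#' @param x samples x features matrix; column names are the feature ids
#'   prediction will insist on.
#' @param y labels, >= 2 classes.
#' @param family one of `"RF"`, `"SVM"`, `"KNN"`, `"NB"`, `"XGB"`,
#'   `"LDA"`, `"ANN"`.
#' @param params named list of hyperparameter overrides.
#' @param seed RNG seed; identical data + seed gives identical models.
#' @return a [SubgroupModel-class].
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' y <- rep(c("A", "B"), 25); x[y == "B", 1] <- x[y == "B", 1] + 4
#' m <- trainModel(x, y, "RF", seed = 1)
#' table(predictSubgroups(m, x)$class, y)
#' @export
trainModel <- function(x, y, family = "RF", params = list(), seed = 1L) {
  checkMatrix(x, "x")
  family <- match.arg(family, MODEL_FAMILIES)
  y <- factor(y)
  if (nlevels(y) < 2L) stopMsg("labels must contain >= 2 classes")
  if (nrow(x) != length(y)) stopMsg("feature rows and labels disagree")
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%05d", seq_len(ncol(x)))
  classes <- levels(y)

  if (family == "ANN") {
    cfg <- do.call(annConfig, c(params[names(params) %in%
                                         names(formals(annConfig))],
                                list(seed = as.integer(seed))))
    return(trainAnn(x, y, cfg))
  }

  resolved <- switch(family,
    RF = list(nTrees = 300L, maxTerminalNodes = 6L),
    SVM = list(kernel = "radial", cost = 1, gamma = 1 / ncol(x)),
    KNN = list(k = 3L),
    NB = list(probThreshold = 0.8, laplace = 0),
    XGB = list(nrounds = 50L, learningRate = 0.3, maxDepth = 6L,
               objective = "multi:softprob"),
    LDA = list(prior = "class proportions", method = "moment"))
  resolved[names(params)] <- params

  fit <- withSeed(seed, switch(family,
    RF = randomForest::randomForest(
      x = x, y = y, ntree = resolved$nTrees,
      maxnodes = resolved$maxTerminalNodes),
    SVM = e1071::svm(x = x, y = y, kernel = resolved$kernel,
                     cost = resolved$cost, gamma = resolved$gamma,
                     probability = TRUE),
    KNN = list(x = x, y = y, k = resolved$k),
    NB = e1071::naiveBayes(x = x, y = y, laplace = resolved$laplace),
    XGB = xgboost::xgboost(
      x, y, nrounds = resolved$nrounds,
      learning_rate = resolved$learningRate,
      max_depth = resolved$maxDepth, nthreads = 1L, verbosity = 0),
    LDA = MASS::lda(x, grouping = y)))

  new("SubgroupModel", family = family, fit = fit, classes = classes,
      featureIds = colnames(x), params = resolved,
      seed = as.integer(seed), nTrain = nrow(x))
}

knnProb <- function(fit, x) {
  D <- as.matrix(stats::dist(rbind(fit$x, x)))
  ntr <- nrow(fit$x)
  classes <- levels(fit$y)
  prob <- matrix(0, nrow(x), length(classes),
                 dimnames = list(NULL, classes))
  for (i in seq_len(nrow(x))) {
    d <- D[ntr + i, seq_len(ntr)]
    nb <- order(d)[seq_len(fit$k)]
    tab <- table(factor(fit$y[nb], levels = classes))
    prob[i, ] <- tab / fit$k
  }
  prob
}

#' Predict subgroups with a fitted model
#'
#' All families share the same contract: a class-probability matrix
#' whose rows sum to 1, the argmax label, and a low-confidence flag (for
#' naive Bayes, set when the maximum posterior falls below the 0.8
#' threshold; the argmax label is still emitted). Prediction refuses
#' feature sets that differ from training.
#'
#' @param model a [SubgroupModel-class].
#' @param x samples x features matrix with the training feature ids.
#' @return list with `class` (factor), `prob` (matrix), and
#'   `lowConfidence` (logical).
#' @export
predictSubgroups <- function(model, x) {
  checkMatrix(x, "x")
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model@featureIds))
      stopMsg("feature count differs from training")
    colnames(x) <- model@featureIds
  }
  unknown <- setdiff(colnames(x), model@featureIds)
  if (length(unknown))
    stopMsg("unknown features: %s", paste(head(unknown, 5L), collapse = ", "))
  if (!setequal(colnames(x), model@featureIds))
    stopMsg("missing features: %s",
            paste(head(setdiff(model@featureIds, colnames(x)), 5L),
                  collapse = ", "))
  x <- x[, model@featureIds, drop = FALSE]
  cls <- model@classes

  prob <- switch(model@family,
    RF = predict(model@fit, x, type = "prob"),
    SVM = {
      p <- predict(model@fit, x, probability = TRUE)
      attr(p, "probabilities")
    },
    KNN = knnProb(model@fit, x),
    NB = predict(model@fit, x, type = "raw"),
    XGB = predict(model@fit, x, type = "response"),
    LDA = predict(model@fit, x)$posterior,
    ANN = {
      p <- predictAnnProb(model@fit, x)
      colnames(p) <- cls
      p
    })
  prob <- prob[, cls, drop = FALSE]
  prob <- prob / rowSums(prob)
  rownames(prob) <- rownames(x)
  labels <- factor(cls[max.col(prob, ties.method = "first")], levels = cls)
  low <- if (model@family == "NB") {
    thr <- model@params$probThreshold
    apply(prob, 1L, max) < thr
  } else rep(FALSE, nrow(prob))
  list(class = labels, prob = prob, lowConfidence = unname(low))
}

#' @describeIn predictSubgroups S4 `predict` method.
#' @param object a [SubgroupModel-class].
#' @param newdata samples x features matrix.
#' @export
setMethod("predict", "SubgroupModel", function(object, newdata, ...)
  predictSubgroups(object, newdata))

#' k-fold cross-validation of one model family
#'
#' For each fold the model is trained on the remaining samples and
#' scored on the fold: overall accuracy, macro precision, sensitivity,
#' specificity and F1 (one-vs-rest averages), and Hand-Till multiclass
#' AUC. A `summary` attribute carries the mean and SD over folds.
#'
#' @param x samples x features matrix.
#' @param y labels.
#' @param family model family code (see [trainModel()]).
#' @param folds list of test-index vectors partitioning the samples
#'   (see [makeFolds()]).
#' @param params hyperparameter overrides.
#' @param seed RNG seed.
#' @return data.frame with one row per fold;
#'   `attr(, "summary")` holds mean and sd rows.
#' @export
crossValidate <- function(x, y, family = "RF", folds = makeFolds(y),
                          params = list(), seed = 1L) {
  y <- factor(y)
  all <- sort(unlist(folds, use.names = FALSE))
  if (!identical(all, seq_len(length(y))))
    stopMsg("folds must partition all samples")
  rows <- lapply(seq_along(folds), function(i) {
    te <- folds[[i]]
    ytr <- y[-te]
    if (nlevels(droplevels(ytr)) < 2L)
      stopMsg("fold %d leaves a single-class training set", i)
    m <- trainModel(x[-te, , drop = FALSE], droplevels(ytr), family,
                    params = params, seed = deriveSeed(seed, i))
    pr <- predictSubgroups(m, x[te, , drop = FALSE])
    cm <- confusionCounts(as.character(y[te]), as.character(pr$class),
                          classes = levels(y))
    met <- classMetrics(cm)
    macro <- met[met$class == "macro", ]
    data.frame(fold = names(folds)[i] %||% i,
               accuracy = mean(as.character(y[te]) == as.character(pr$class)),
               precision = macro$precision, sensitivity = macro$sensitivity,
               specificity = macro$specificity, f1 = macro$f1,
               auc = tryCatch(multiclassAUC(y[te], pr$prob),
                              error = function(e) NA_real_))
  })
  out <- do.call(rbind, rows)
  num <- out[, -1L]
  attr(out, "summary") <- data.frame(
    stat = c("mean", "sd"),
    rbind(colMeans(num, na.rm = TRUE), apply(num, 2L, sd, na.rm = TRUE)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
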