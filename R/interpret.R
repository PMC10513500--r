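#' @include AllClasses.R utils.R
NULL

#' Sampling-based Shapley values for one prediction
#'
#' Permutation-sampling estimator of Shapley values: each Monte-Carlo
#' draw picks a random feature permutation and a random background row;
#' walking the permutation, feature j's contribution is the change in
#' the model output when j switches from its background to its instance
#' value, with the features before j already set to the instance and
#' those after j still at the background. Contributions are averaged
#' over draws, per output class, on the probability scale, and
#' Monte-Carlo standard errors are reported alongside. Deterministic
#' given the seed.
#'
#' @param predictFn function mapping a samples x features matrix to a
#'   samples x classes probability matrix.
#' @param background background feature matrix (nonempty; its empirical
#'   distribution defines the feature-removal baseline).
#' @param instance the feature vector to explain (names matching the
#'   background columns).
#' @param mSamples Monte-Carlo draws (default 1000).
#' @param seed RNG seed.
#' @return a [ShapleyExplanation-class].
#' @export
shapleyExplain <- function(predictFn, background, instance,
                           mSamples = 1000L, seed = 1L) {
  checkMatrix(background, "background")
  if (!nrow(background)) stopMsg("background must be nonempty")
  if (mSamples < 1L) stopMsg("mSamples must be >= 1")
  instance <- unlist(instance)
  if (length(instance) != ncol(background))
    stopMsg("instance features do not match the background")
  d <- length(instance)
  if (is.null(names(instance))) names(instance) <- colnames(background)

  basePred <- predictFn(background)
  if (is.null(dim(basePred))) basePred <- matrix(basePred, ncol = 1L)
  nc <- ncol(basePred)
  classes <- colnames(basePred)
  if (is.null(classes)) classes <- paste0("class", seq_len(nc))
  baseline <- colMeans(basePred)
  instPred <- predictFn(matrix(instance, 1L, d,
                               dimnames = list(NULL, names(instance))))

  phiSum <- matrix(0, d, nc)
  phiSq <- matrix(0, d, nc)
  withSeed(seed, {
    chunk <- 200L
    done <- 0L
    while (done < mSamples) {
      m <- min(chunk, mSamples - done)
      # build all coalition rows for this chunk: m * (d + 1) evaluations
      rows <- matrix(NA_real_, m * (d + 1L), d)
      perms <- matrix(NA_integer_, m, d)
      for (s in seq_len(m)) {
        b <- background[sample.int(nrow(background), 1L), ]
        perm <- sample.int(d)
        perms[s, ] <- perm
        cur <- as.numeric(b)
        at <- (s - 1L) * (d + 1L)
        rows[at + 1L, ] <- cur
        for (t in seq_len(d)) {
          cur[perm[t]] <- instance[perm[t]]
          rows[at + 1L + t, ] <- cur
        }
      }
      colnames(rows) <- names(instance)
      preds <- predictFn(rows)
      if (is.null(dim(preds))) preds <- matrix(preds, ncol = 1L)
      for (s in seq_len(m)) {
        at <- (s - 1L) * (d + 1L)
        dlt <- preds[at + 1L + seq_len(d), , drop = FALSE] -
          preds[at + seq_len(d), , drop = FALSE]
        ordBack <- order(perms[s, ])  # contribution of feature j
        phiSum <- phiSum + dlt[ordBack, , drop = FALSE]
        phiSq <- phiSq + dlt[ordBack, , drop = FALSE]^2
      }
      done <- done + m
    }
  })
  phi <- phiSum / mSamples
  se <- sqrt(pmax(phiSq / mSamples - phi^2, 0) / mSamples)
  dimnames(phi) <- dimnames(se) <- list(names(instance), classes)
  new("ShapleyExplanation", phi = phi, se = se,
      baseline = setNames(as.numeric(baseline), classes),
      prediction = setNames(as.numeric(instPred[1L, ]), classes),
      instance = instance, nSamples = as.integer(mSamples))
}

#' Explain one instance per subgroup
#'
#' Computes a [shapleyExplain()] explanation for one training instance
#' of each subgroup, reporting phi for the instance's own class and all
#' others.
#'
#' @param model a [SubgroupModel-class].
#' @param xTrain training feature matrix (used as background).
#' @param labels training labels (used to pick one instance per class
#'   when `instances` is NULL).
#' @param instances optional matrix with one named row per class;
#'   default: the first training instance of each class.
#' @param mSamples Monte-Carlo draws per explanation.
#' @param seed RNG seed.
#' @return named list of [ShapleyExplanation-class], one per class.
#' @export
explainSubgroups <- function(model, xTrain, labels, instances = NULL,
                             mSamples = 1000L, seed = 1L) {
  checkMatrix(xTrain, "xTrain")
  classes <- model@classes
  if (is.null(instances)) {
    labels <- as.character(labels)
    missing <- setdiff(classes, labels)
    if (length(missing))
      stopMsg("no training instance for class: %s",
              paste(missing, collapse = ", "))
    idx <- vapply(classes, function(cl) which(labels == cl)[1L], integer(1L))
    instances <- xTrain[idx, , drop = FALSE]
    rownames(instances) <- classes
  }
  if (!all(classes %in% rownames(instances)))
    stopMsg("instances must include one row per class")
  predictFn <- function(m) predictSubgroups(model, m)$prob
  out <- lapply(classes, function(cl)
    shapleyExplain(predictFn, xTrain, instances[cl, ],
                   mSamples = mSamples, seed = deriveSeed(seed, cl)))
  names(out) <- classes
  out
}

#' Tidy a Shapley explanation into a table
#'
#' @param explanation a [ShapleyExplanation-class].
#' @return data.frame with feature, value, class, phi, mc_se.
#' @export
shapleyTable <- function(explanation) {
  phi <- explanation@phi
  data.frame(
    feature = rep(rownames(phi), ncol(phi)),
    value = rep(explanation@instance, ncol(phi)),
    class = rep(colnames(phi), each = nrow(phi)),
    phi = as.vector(phi),
    mc_se = as.vector(explanation@se),
    row.names = NULL)
}
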