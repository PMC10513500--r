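#' @include utils.R
NULL

#' Feed-forward network configuration
#'
#' The default architecture: four dense layers of widths 40, 30, 10 and
#' 4 (the last resized to the number of classes at fit time), leaky-ReLU
#' activation on the first three and softmax output; dropout at rates
#' 0.5/0.4/0.1 after the three hidden layers; L2 penalty 0.009 on the
#' second layer's weights; categorical cross-entropy loss optimized by
#' SGD with learning rate 0.03, per-step decay 0.00006, momentum 0.05
#' and Nesterov momentum; at most 200 epochs of batch size 16 with early
#' stopping after 5 epochs without validation-loss improvement.
#'
#' @param layerSizes dense layer widths.
#' @param dropout dropout rates after each hidden layer.
#' @param l2Layer2 L2 penalty on the second dense layer's weights.
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param learningRate initial SGD learning rate.
#' @param decay per-step learning-rate decay:
#'   `lr_t = lr / (1 + decay * step)`.
#' @param momentum SGD momentum coefficient.
#' @param nesterov use Nesterov momentum.
#' @param patience early-stopping patience in epochs.
#' @param leakySlope negative-side slope of the leaky ReLU.
#' @param seed RNG seed for initialization and batching.
#' @return named list of settings for [trainAnn()].
#' @export
annConfig <- function(layerSizes = c(40L, 30L, 10L, 4L),
                      dropout = c(0.5, 0.4, 0.1),
                      l2Layer2 = 0.009, epochs = 200L, batchSize = 16L,
                      learningRate = 0.03, decay = 0.00006,
                      momentum = 0.05, nesterov = TRUE, patience = 5L,
                      leakySlope = 0.3, seed = 1L) {
  stopifnot(length(layerSizes) >= 2L, all(layerSizes > 0),
            length(dropout) == length(layerSizes) - 1L,
            all(dropout >= 0 & dropout < 1),
            epochs >= 1L, batchSize >= 1L, learningRate > 0)
  list(layerSizes = as.integer(layerSizes), dropout = dropout,
       l2Layer2 = l2Layer2, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), learningRate = learningRate,
       decay = decay, momentum = momentum, nesterov = nesterov,
       patience = as.integer(patience), leakySlope = leakySlope,
       seed = as.integer(seed))
}

lrelu <- function(z, slope) ifelse(z > 0, z, slope * z)
lreluGrad <- function(z, slope) ifelse(z > 0, 1, slope)

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

annForward <- function(W, b, x, slope, dropout = NULL) {
  nl <- length(W)
  A <- x
  cacheZ <- vector("list", nl)
  cacheA <- vector("list", nl + 1L)
  masks <- vector("list", nl - 1L)
  cacheA[[1L]] <- A
  for (l in seq_len(nl)) {
    Z <- A %*% W[[l]] + matrix(b[[l]], nrow(A), length(b[[l]]), byrow = TRUE)
    cacheZ[[l]] <- Z
    if (l < nl) {
      A <- lrelu(Z, slope)
      if (!is.null(dropout) && dropout[l] > 0) {
        mask <- matrix(rbinom(length(A), 1L, 1 - dropout[l]),
                       nrow(A), ncol(A)) / (1 - dropout[l])
        masks[[l]] <- mask
        A <- A * mask
      }
    } else {
      A <- softmaxRows(Z)
    }
    cacheA[[l + 1L]] <- A
  }
  list(prob = A, Z = cacheZ, A = cacheA, masks = masks)
}

annLoss <- function(prob, yOne, W2, l2) {
  ce <- -mean(rowSums(yOne * log(pmax(prob, 1e-12))))
  ce + l2 * sum(W2^2)
}

#' Train the feed-forward subgroup classifier
#'
#' Fits the network described by [annConfig()] with minibatch SGD.
#' Features are standardized with training-set statistics (stored in
#' the model). A stratified `valFrac` slice is held out to monitor
#' validation loss; training halts at the epoch limit or when validation
#' loss fails to improve for `patience` consecutive epochs, and the best
#' weights seen are restored. Deterministic given the config seed.
#'
#' @param x samples x features matrix.
#' @param y labels (>= 2 classes); factor level order fixes the output
#'   column order.
#' @param config [annConfig()].
#' @param valFrac validation fraction (default 0.2).
#' @return a [SubgroupModel-class] with `family = "ANN"`.
#' @export
trainAnn <- function(x, y, config = annConfig(), valFrac = 0.2) {
  checkMatrix(x, "x")
  y <- factor(y)
  if (nlevels(y) < 2L) stopMsg("labels must contain >= 2 classes")
  if (nrow(x) < 20L) stopMsg("ANN training needs >= 20 samples")
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%05d", seq_len(ncol(x)))
  classes <- levels(y)
  sizes <- config$layerSizes
  if (sizes[length(sizes)] != nlevels(y))
    sizes[length(sizes)] <- nlevels(y)
  widths <- c(ncol(x), sizes)
  nl <- length(sizes)

  center <- colMeans(x)
  scl <- apply(x, 2L, sd); scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)

  withSeed(config$seed, {
    sp <- splitData(y, trainFrac = 1 - valFrac, stratified = TRUE,
                    seed = deriveSeed(config$seed, "annval"))
    vi <- sp$test
    xtr <- xs[-vi, , drop = FALSE]; ytr <- y[-vi]
    xva <- xs[vi, , drop = FALSE];  yva <- y[vi]
    oneHot <- function(f) {
      m <- matrix(0, length(f), nlevels(y))
      m[cbind(seq_along(f), as.integer(f))] <- 1
      m
    }
    ytrOne <- oneHot(ytr); yvaOne <- oneHot(yva)

    W <- vector("list", nl); b <- vector("list", nl)
    vW <- vector("list", nl); vb <- vector("list", nl)
    for (l in seq_len(nl)) {
      W[[l]] <- matrix(rnorm(widths[l] * widths[l + 1L],
                             sd = sqrt(2 / widths[l])),
                       widths[l], widths[l + 1L])
      b[[l]] <- rep(0, widths[l + 1L])
      vW[[l]] <- W[[l]] * 0; vb[[l]] <- b[[l]] * 0
    }

    step <- 0L
    bestLoss <- Inf; bestW <- W; bestB <- b; wait <- 0L
    history <- data.frame(epoch = integer(), trainLoss = numeric(),
                          valLoss = numeric(), valAcc = numeric())
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(xtr))
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      for (bt in batches) {
        xb <- xtr[bt, , drop = FALSE]; yb <- ytrOne[bt, , drop = FALSE]
        fw <- annForward(W, b, xb, config$leakySlope, config$dropout)
        if (any(!is.finite(fw$prob)))
          stopMsg("divergent loss (NaN); lower the learning rate")
        B <- nrow(xb)
        dZ <- (fw$prob - yb) / B
        step <- step + 1L
        lr <- config$learningRate / (1 + config$decay * step)
        for (l in rev(seq_len(nl))) {
          dW <- t(fw$A[[l]]) %*% dZ
          db <- colSums(dZ)
          if (l == 2L && config$l2Layer2 > 0)
            dW <- dW + 2 * config$l2Layer2 * W[[l]]
          if (l > 1L) {
            dA <- dZ %*% t(W[[l]])
            if (!is.null(fw$masks[[l - 1L]])) dA <- dA * fw$masks[[l - 1L]]
            dZ <- dA * lreluGrad(fw$Z[[l - 1L]], config$leakySlope)
          }
          vW[[l]] <- config$momentum * vW[[l]] - lr * dW
          vb[[l]] <- config$momentum * vb[[l]] - lr * db
          if (config$nesterov) {
            W[[l]] <- W[[l]] + config$momentum * vW[[l]] - lr * dW
            b[[l]] <- b[[l]] + config$momentum * vb[[l]] - lr * db
          } else {
            W[[l]] <- W[[l]] + vW[[l]]
            b[[l]] <- b[[l]] + vb[[l]]
          }
        }
      }
      trFw <- annForward(W, b, xtr, config$leakySlope)
      vaFw <- annForward(W, b, xva, config$leakySlope)
      trLoss <- annLoss(trFw$prob, ytrOne, W[[2L]], config$l2Layer2)
      vaLoss <- annLoss(vaFw$prob, yvaOne, W[[2L]], config$l2Layer2)
      if (!is.finite(vaLoss))
        stopMsg("divergent loss (NaN); lower the learning rate")
      vaAcc <- mean(max.col(vaFw$prob, ties.method = "first") ==
                      as.integer(yva))
      history <- rbind(history, data.frame(epoch = epoch, trainLoss = trLoss,
                                           valLoss = vaLoss, valAcc = vaAcc))
      if (vaLoss < bestLoss - 1e-8) {
        bestLoss <- vaLoss; bestW <- W; bestB <- b; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    fit <- list(W = bestW, b = bestB, center = center, scale = scl,
                slope = config$leakySlope, widths = widths,
                history = history, valLoss = bestLoss)
    new("SubgroupModel", family = "ANN", fit = fit, classes = classes,
        featureIds = colnames(x),
        params = c(config, list(widths = widths, valFrac = valFrac)),
        seed = config$seed, nTrain = nrow(xtr))
  })
}

predictAnnProb <- function(fit, x) {
  xs <- scale(x, center = fit$center, scale = fit$scale)
  annForward(fit$W, fit$b, xs, fit$slope)$prob
}

#' Layer widths of a fitted network
#' @param model an ANN [SubgroupModel-class].
#' @return integer vector of dense-layer widths (excluding the input).
#' @export
annLayerSizes <- function(model) {
  stopifnot(model@family == "ANN")
  model@fit$widths[-1L]
}
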