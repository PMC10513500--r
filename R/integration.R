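#' @include utils.R
NULL

#' Similarity-network-fusion parameters
#'
#' Defaults follow the integration settings used throughout the package:
#' 51 nearest neighbors, kernel scale 0.85, 120 cross-diffusion
#' iterations, and 4 clusters. `K` is clamped to `n - 1` with a warning
#' for small cohorts.
#'
#' @param K neighbor count (default 51).
#' @param mu kernel scale (default 0.85).
#' @param t fusion iterations (default 120).
#' @param kClusters number of clusters (default 4).
#' @return named list of validated parameters.
#' @export
snfParams <- function(K = 51L, mu = 0.85, t = 120L, kClusters = 4L) {
  if (K < 1L) stopMsg("K must be >= 1")
  if (mu <= 0) stopMsg("mu must be > 0")
  if (t < 1L) stopMsg("t must be >= 1")
  if (kClusters < 2L) stopMsg("kClusters must be >= 2")
  list(K = as.integer(K), mu = mu, t = as.integer(t),
       kClusters = as.integer(kClusters))
}

#' Pairwise squared Euclidean distances between samples
#'
#' @param x samples x features matrix, no missing values.
#' @return n x n symmetric matrix of squared distances, zero diagonal.
#' @export
pairwiseSqDistance <- function(x) {
  checkMatrix(x, "x")
  if (nrow(x) < 2L) stopMsg("need at least 2 samples")
  d <- as.matrix(stats::dist(x))^2
  diag(d) <- 0
  d
}

clampK <- function(K, n) {
  if (K >= n) {
    warning(sprintf("K = %d >= n = %d; clamping to n - 1", K, n), call. = FALSE)
    K <- n - 1L
  }
  as.integer(K)
}

# Mean of the K smallest off-diagonal entries of each row.
knnRowMeans <- function(D, K) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    v <- sort(D[i, -i], partial = K)[seq_len(K)]
    mean(v)
  }, numeric(1L))
}

#' Scaled exponential affinity kernel
#'
#' `W(i,j) = exp(-d(i,j) / (mu * eps(i,j)))` with the locally adaptive
#' scale `eps(i,j)` equal to the mean of (average distance of i to its K
#' nearest neighbors, the same for j, and `d(i,j)` itself). `d` is the
#' squared-distance matrix from [pairwiseSqDistance()]. The diagonal is
#' 1 and values lie in (0, 1].
#'
#' @param D squared-distance matrix.
#' @param params output of [snfParams()].
#' @return symmetric affinity matrix.
#' @export
affinityKernel <- function(D, params = snfParams()) {
  checkMatrix(D, "D")
  n <- nrow(D)
  if (n != ncol(D)) stopMsg("D must be square")
  K <- clampK(params$K, n)
  m <- knnRowMeans(D, K)
  eps <- (outer(m, m, "+") + D) / 3
  eps[eps <= 0] <- .Machine$double.eps
  W <- exp(-D / (params$mu * eps))
  W <- (W + t(W)) / 2
  dimnames(W) <- dimnames(D)
  W
}

# Full transition kernel: off-diagonal mass 1/2, diagonal 1/2.
snfFullKernel <- function(W) {
  P <- W
  diag(P) <- 0
  rs <- rowSums(P)
  rs[rs == 0] <- 1
  P <- P / (2 * rs)
  diag(P) <- 0.5
  P
}

# Local (KNN-masked) kernel: row-normalized over the K nearest neighbors.
snfLocalKernel <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(W[i, -i], decreasing = TRUE)
    nb <- (seq_len(n)[-i])[ord[seq_len(K)]]
    S[i, nb] <- W[i, nb]
  }
  rs <- rowSums(S)
  rs[rs == 0] <- 1
  S / rs
}

#' Fuse affinity matrices by cross-diffusion
#'
#' Similarity network fusion: each view's full kernel (off-diagonal mass
#' one half) is iteratively diffused through its KNN-masked local kernel
#' against the average of the other views' kernels,
#' `P_v <- S_v (mean of other P) S_v'`, for `t` iterations, with
#' renormalization and symmetrization after each step; the fused network
#' is the symmetrized average of the final views.
#'
#' @param affinities list of >= 2 affinity matrices over the same samples
#'   in the same order (see [affinityKernel()]).
#' @param params output of [snfParams()].
#' @return fused symmetric affinity matrix.
#' @export
snfFuse <- function(affinities, params = snfParams()) {
  if (!is.list(affinities) || length(affinities) < 2L)
    stopMsg("fusion needs >= 2 views")
  n <- nrow(affinities[[1L]])
  for (W in affinities) {
    checkMatrix(W)
    if (!all(dim(W) == n)) stopMsg("all views must cover the same samples")
  }
  K <- clampK(params$K, n)
  P <- lapply(affinities, snfFullKernel)
  S <- lapply(affinities, snfLocalKernel, K = K)
  m <- length(P)
  for (iter in seq_len(params$t)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1L)
      Q <- S[[v]] %*% others %*% t(S[[v]])
      Q <- (Q + t(Q)) / 2
      Pnew[[v]] <- snfFullKernel(Q)
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(affinities[[1L]])
  fused
}

#' Spectral clustering of an affinity matrix
#'
#' Normalized spectral clustering (Ng-Jordan-Weiss): the top-k
#' eigenvectors of the symmetrically normalized affinity
#' `D^(-1/2) W D^(-1/2)` are row-normalized and partitioned by k-means
#' with a fixed seed and 50 restarts.
#'
#' @param A symmetric nonnegative affinity matrix.
#' @param k number of clusters, `k < n`.
#' @param seed RNG seed for the k-means step.
#' @param nstart k-means restarts (default 50).
#' @return integer labels in 1..k, named by the samples.
#' @export
spectralCluster <- function(A, k, seed = 1L, nstart = 50L) {
  checkMatrix(A, "A")
  n <- nrow(A)
  if (k >= n) stopMsg("k must be < number of samples")
  if (k < 1L) stopMsg("k must be >= 1")
  if (k == 1L) return(setNames(rep(1L, n), rownames(A)))
  if (max(abs(A - t(A))) > 1e-8) stopMsg("affinity must be symmetric")
  d <- rowSums(A)
  d[d <= 0] <- .Machine$double.eps
  Dg <- 1 / sqrt(d)
  L <- A * outer(Dg, Dg)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  cl <- withSeed(seed, kmeans(U, centers = k, nstart = nstart, iter.max = 100L))
  setNames(as.integer(cl$cluster), rownames(A))
}

#' Normalized mutual information between two labelings
#'
#' `I(a; b) / sqrt(H(a) H(b))`: 1 iff the partitions are identical up to
#' renaming, 0 for independent partitions. When both entropies are zero
#' (single-cluster partitions) the convention is 1.
#'
#' @param a,b label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c("b", "b", "a", "a"))  # 1: same partition
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stopMsg("label vectors must have equal length")
  if (!length(a)) stopMsg("labels must be nonempty")
  tab <- table(a, b)
  # identical partitions up to renaming: exactly one nonzero cell per
  # row and column; return exactly 1 rather than its floating image
  if (nrow(tab) == ncol(tab) &&
      all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L))
    return(1)
  n <- sum(tab)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  max(0, min(1, mi / sqrt(ha * hb)))
}

#' Map cluster numbers to subgroup names by maximal overlap
#'
#' Finds the one-to-one assignment of clusters to reference classes that
#' maximizes total agreement (exact search over assignments, feasible for
#' the at-most-8 clusters this package deals in), and returns the cluster
#' labels renamed accordingly.
#'
#' @param clusterIds integer/character cluster labels.
#' @param reference subgroup labels of the same length.
#' @return character vector of subgroup names, plus the cluster-to-class
#'   map in `attr(, "map")`.
#' @export
relabelClusters <- function(clusterIds, reference) {
  if (length(clusterIds) != length(reference))
    stopMsg("label vectors must have equal length")
  cls <- sort(unique(as.character(clusterIds)))
  ref <- unique(as.character(reference))
  if (length(cls) > length(ref))
    stopMsg("more clusters than reference classes")
  if (length(cls) > 8L)
    stopMsg("exact relabeling supports at most 8 clusters")
  ov <- table(factor(as.character(clusterIds), levels = cls),
              factor(as.character(reference), levels = ref))
  if (all(ov == 0)) stopMsg("degenerate overlap: no co-occurring labels")
  # exact maximum-agreement injection of clusters into classes
  best <- NULL; bestScore <- -1
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (sel in utils::combn(seq_along(ref), length(cls), simplify = FALSE)) {
    for (p in perms(sel)) {
      score <- sum(ov[cbind(seq_along(cls), p)])
      if (score > bestScore) { bestScore <- score; best <- p }
    }
  }
  map <- setNames(ref[best], cls)
  out <- unname(map[as.character(clusterIds)])
  attr(out, "map") <- map
  out
}

#' Integrate methylation and expression views of a cohort
#'
#' Convenience wrapper over the fusion pipeline: builds per-view affinity
#' kernels from squared Euclidean distances on the samples, fuses them by
#' cross-diffusion, spectrally clusters the fused network, scores the
#' partition against the recorded subgroups with NMI, and relabels the
#' clusters by maximal overlap.
#'
#' @param omics a [MethylOmics-class].
#' @param params [snfParams()].
#' @param seed RNG seed for the clustering step.
#' @return list with `fused` (affinity matrix), `clusters` (integer
#'   labels), `labels` (relabeled subgroups), and `nmi` against the
#'   recorded subgroups.
#' @export
integrateOmics <- function(omics, params = snfParams(), seed = 1L) {
  views <- list(t(betaValues(omics)), t(exprValues(omics)))
  aff <- lapply(views, function(v) affinityKernel(pairwiseSqDistance(v), params))
  fused <- snfFuse(aff, params)
  cl <- spectralCluster(fused, params$kClusters, seed = seed)
  truth <- as.character(subgroups(omics))
  list(fused = fused, clusters = cl,
       labels = relabelClusters(cl, truth),
       nmi = nmi(cl, truth))
}
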