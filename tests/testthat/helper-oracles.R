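# Independent brute-force oracles used to validate the implementations.

# Minimum spanning forest weight by exhaustive enumeration of edge subsets.
# edges: data.frame(from, to, w) over vertices 1..n.
bruteMSTWeight <- function(n, edges) {
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  m <- nrow(edges)
  comps <- function(sel) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in sel) {
      a <- find(edges$from[k]); b <- find(edges$to[k])
      if (a != b) parent[a] <- b
    }
    length(unique(vapply(seq_len(n), find, integer(1L))))
  }
  target <- comps(seq_len(m))           # components of the full graph
  need <- n - target                    # edges in any spanning forest
  if (need == 0L) return(0)
  best <- Inf
  for (sel in utils::combn(m, need, simplify = FALSE)) {
    if (comps(sel) == target) best <- min(best, sum(edges$w[sel]))
  }
  best
}

# Exact interventional Shapley values over all 2^d coalitions.
# predictFn: matrix -> matrix (samples x classes).
exactShapley <- function(predictFn, background, instance) {
  d <- length(instance)
  classes <- ncol(predictFn(background))
  value <- function(S) {
    rows <- background
    for (j in S) rows[, j] <- instance[j]
    colMeans(predictFn(rows))
  }
  subsets <- lapply(0:(2^d - 1), function(b) which(bitwAnd(b, 2^(0:(d - 1))) > 0))
  vals <- lapply(subsets, value)
  names(vals) <- vapply(subsets, function(s) paste(s, collapse = ","), "")
  phi <- matrix(0, d, classes)
  for (j in seq_len(d)) {
    for (k in seq_along(subsets)) {
      S <- subsets[[k]]
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(d - length(S) - 1) / factorial(d)
      withJ <- vals[[paste(sort(c(S, j)), collapse = ",")]]
      phi[j, ] <- phi[j, ] + w * (withJ - vals[[k]])
    }
  }
  phi
}

# Cox partial log-likelihood for a single binary covariate, no ties.
coxPartialLogLik <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

# Two-group log-rank statistic by direct observed-minus-expected tally.
logrankByHand <- function(time, event, group) {
  g1 <- unique(group)[1L]
  dtimes <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in dtimes) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Unscaled MAD by definition.
madByHand <- function(x) median(abs(x - median(x)))

# Rank-based binary AUC by brute force over all positive/negative pairs.
aucByPairs <- function(scorePos, scoreNeg) {
  tot <- 0
  for (p in scorePos) for (q in scoreNeg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(scorePos) * length(scoreNeg))
}
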