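# Build a GeneNetwork directly from a symmetric r matrix.
netFromR <- function(r, minDegree = 2L, rThreshold = 0.6) {
  buildGraph(r, setNames(rep(0.5, nrow(r)), rownames(r)),
             networkParams(rThreshold = rThreshold, minDegree = minDegree))
}

symR <- function(n, fill = 0) {
  r <- matrix(fill, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  diag(r) <- 1
  r
}

setR <- function(r, i, j, v) { r[i, j] <- v; r[j, i] <- v; r }

test_that("correlation matrix matches hand-computed Pearson r", {
  v <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),
             g3 = c(4, 3, 2, 1))
  r <- correlationMatrix(v)
  expect_equal(diag(r), setNames(rep(1, 3L), rownames(v)))
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  # hand-computed r for a non-trivial pair
  a <- c(1, 2, 4, 3); b <- c(2, 1, 5, 4)
  byHand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlationMatrix(rbind(x = a, y = b))["x", "y"], byHand)
  expect_error(correlationMatrix(v[, 1:2]), "3 samples")
  expect_warning(correlationMatrix(rbind(v, g4 = c(1, 1, 1, 1))), "constant")
})

test_that("graph construction enforces the strict threshold and degree floor", {
  # an edge at exactly the threshold is removed
  r <- setR(symR(3L), "g1", "g2", 0.6)
  r <- setR(r, "g1", "g3", 0.9); r <- setR(r, "g2", "g3", 0.9)
  suppressWarnings(net <- netFromR(r, minDegree = 0L))
  el <- edgeList(net)
  expect_false(any(el$r <= 0.6))
  expect_equal(nrow(el), 2L)
  # a vertex left with one edge is removed at minDegree 2
  r2 <- setR(symR(4L), "g1", "g2", 0.9)
  r2 <- setR(r2, "g2", "g3", 0.9); r2 <- setR(r2, "g1", "g3", 0.9)
  r2 <- setR(r2, "g3", "g4", 0.9)   # g4 dangles
  net2 <- netFromR(r2)
  expect_setequal(igraph::V(net2@graph)$name, c("g1", "g2", "g3"))
  expect_equal(nrow(edgeList(net2)), 3L)   # the triangle survives intact
  # vertex sizes are mean beta x the scale factor
  expect_equal(igraph::V(net2@graph)$size, rep(5, 3L))
  # empty result warns
  expect_warning(netFromR(symR(3L)), "empty network")
})

test_that("the degree filter is a single pass, not a k-core", {
  # path g1-g2-g3-g4: ends have degree 1 and are removed once; the
  # middle vertices then have degree 1 but stay (single pass)
  r <- symR(4L)
  r <- setR(r, "g1", "g2", 0.9); r <- setR(r, "g2", "g3", 0.9)
  r <- setR(r, "g3", "g4", 0.9)
  net <- netFromR(r)
  expect_setequal(igraph::V(net@graph)$name, c("g2", "g3"))
})

test_that("the spanning tree keeps the strongest correlations", {
  r <- symR(3L)
  r <- setR(r, "g1", "g2", 0.9); r <- setR(r, "g1", "g3", 0.8)
  r <- setR(r, "g2", "g3", 0.7)
  net <- netFromR(r, minDegree = 0L)
  tr <- minimumSpanningTree(net)
  el <- edgeList(tr)
  expect_equal(nrow(el), 2L)
  expect_setequal(el$r, c(0.9, 0.8))
  # a tree input is returned unchanged (same edges)
  tr2 <- minimumSpanningTree(tr)
  expect_equal(edgeList(tr2)[order(edgeList(tr2)$r), ],
               el[order(el$r), ], ignore_attr = TRUE)
})

test_that("MST weight equals exhaustive enumeration on random graphs", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:6, 1L)
    r <- symR(n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (runif(1L) < 0.7) r <- setR(r, i, j, runif(1L, 0.61, 0.99))
    suppressWarnings(net <- netFromR(r, minDegree = 0L))
    g <- net@graph
    if (igraph::ecount(g) == 0L) next
    tr <- minimumSpanningTree(net)
    treeW <- sum(1 - edgeList(tr)$r)
    eg <- igraph::as_edgelist(g, names = FALSE)
    oracle <- bruteMSTWeight(igraph::vcount(g),
                             data.frame(from = eg[, 1L], to = eg[, 2L],
                                        w = 1 - igraph::E(g)$r))
    expect_equal(treeW, oracle, tolerance = 1e-10)
    # spanning forest size: |V| - #components
    comps <- igraph::count_components(g)
    expect_equal(nrow(edgeList(tr)), igraph::vcount(g) - comps)
  }
})

test_that("edge-betweenness communities split the known structures", {
  # two triangles joined by a single bridge: the canonical 2-community case
  r <- symR(6L)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    r <- setR(r, e[1L], e[2L], 0.9)
  r <- setR(r, 3L, 4L, 0.7)
  net <- detectCommunities(netFromR(r))
  mem <- net@membership
  expect_length(unique(mem), 2L)
  expect_length(unique(mem[c("g1", "g2", "g3")]), 1L)
  expect_length(unique(mem[c("g4", "g5", "g6")]), 1L)
  expect_false(mem[["g1"]] == mem[["g4"]])
  # complete graph with equal weights: one community
  rc <- symR(5L, fill = 0.9); diag(rc) <- 1
  expect_length(unique(detectCommunities(netFromR(rc))@membership), 1L)
  # disconnected components get at least one community each, and the
  # membership covers every vertex exactly once
  r2 <- symR(6L)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    r2 <- setR(r2, e[1L], e[2L], 0.9)
  netD <- detectCommunities(netFromR(r2))
  expect_gte(length(unique(netD@membership)), 2L)
  expect_setequal(names(netD@membership), paste0("g", 1:6))
  expect_equal(communityGenes(netD),
               split(names(netD@membership), netD@membership))
})

test_that("cluster augmentation adds the missing discriminating gene", {
  # class separability lives in gene gA; cluster1 lacks it
  evalFn <- function(genes) {
    if ("gA" %in% genes) c(A = 1, B = 1) else c(A = 0.4, B = 1)
  }
  res <- augmentClusters(list(c1 = c("g1", "g2")),
                         pool = c("gX", "gA", "gY"), evalFn)
  expect_true("gA" %in% res$clusters$c1)
  expect_false("gY" %in% res$clusters$c1)  # stops once per-class F1 hits 1
  expect_true(all(c("gX", "gA") %in% res$trace$gene))
  # a perfect cluster is left untouched
  res2 <- augmentClusters(list(c1 = "gA"), pool = c("gX", "gY"), evalFn)
  expect_identical(res2$clusters$c1, "gA")
  # unreachable gain accepts nothing
  res3 <- augmentClusters(list(c1 = c("g1", "g2")),
                          pool = c("gA"), evalFn, minGain = 1.5)
  expect_identical(res3$clusters$c1, c("g1", "g2"))
  expect_false(any(res3$trace$accepted))
  expect_error(augmentClusters(list(a = "g1", b = "g1"), "gX", evalFn),
               "disjoint")
})
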