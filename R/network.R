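#' @include AllClasses.R utils.R
NULL

#' Gene-network construction parameters
#'
#' @param rThreshold edges kept iff Pearson r is strictly greater
#'   (default 0.6; an edge at exactly 0.6 is removed).
#' @param minDegree vertices with fewer adjacent edges are removed
#'   (default 2).
#' @param sizeScale display size = mean beta x this factor (default 10).
#' @return named list.
#' @export
networkParams <- function(rThreshold = 0.6, minDegree = 2L, sizeScale = 10) {
  if (rThreshold <= -1 || rThreshold >= 1) stopMsg("rThreshold must lie in (-1, 1)")
  if (minDegree < 0L) stopMsg("minDegree must be >= 0")
  list(rThreshold = rThreshold, minDegree = as.integer(minDegree),
       sizeScale = sizeScale)
}

#' Pearson correlation matrix between genes
#'
#' Constant genes (undefined correlation) are excluded with a warning.
#'
#' @param values genes x samples matrix, >= 3 samples.
#' @return symmetric gene x gene correlation matrix, unit diagonal.
#' @export
correlationMatrix <- function(values) {
  checkMatrix(values, "values")
  if (ncol(values) < 3L) stopMsg("need >= 3 samples")
  sds <- apply(values, 1L, sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant gene(s) with undefined correlation",
                    sum(sds == 0)), call. = FALSE)
    values <- values[sds > 0, , drop = FALSE]
  }
  r <- cor(t(values))
  diag(r) <- 1
  r
}

#' Build a thresholded gene correlation network
#'
#' Keeps edges with r strictly above the threshold, removes self-loops
#' and duplicate edges, then removes vertices whose degree falls below
#' `minDegree` in a single pass (not iterated to a k-core). Vertex
#' display sizes are mean beta times `sizeScale`.
#'
#' @param r gene x gene correlation matrix.
#' @param betaMeans named per-gene mean beta values.
#' @param params [networkParams()].
#' @return a [GeneNetwork-class] (possibly empty, with a warning).
#' @export
buildGraph <- function(r, betaMeans, params = networkParams()) {
  checkMatrix(r, "r")
  genes <- rownames(r)
  if (is.null(genes)) stopMsg("correlation matrix must have gene names")
  adj <- (r > params$rThreshold) * r
  diag(adj) <- 0
  adj[adj < 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  igraph::E(g)$r <- igraph::E(g)$weight
  low <- igraph::V(g)[igraph::degree(g) < params$minDegree]
  g <- igraph::delete_vertices(g, low)
  if (igraph::vcount(g) == 0L)
    warning("empty network after filtering", call. = FALSE)
  mb <- betaMeans[igraph::V(g)$name]
  igraph::V(g)$meanBeta <- as.numeric(mb)
  igraph::V(g)$size <- as.numeric(mb) * params$sizeScale
  new("GeneNetwork", graph = g, params = params, membership = integer())
}

#' Minimum spanning tree of a gene network
#'
#' Prim's algorithm under the weight transform `1 - r`, so the tree
#' retains the strongest correlations; for disconnected input the
#' result is a spanning forest (one tree per component).
#'
#' @param network a [GeneNetwork-class].
#' @return a [GeneNetwork-class] holding the spanning tree/forest.
#' @export
minimumSpanningTree <- function(network) {
  g <- network@graph
  if (igraph::vcount(g) == 0L) return(network)
  tr <- igraph::mst(g, weights = 1 - igraph::E(g)$r, algorithm = "prim")
  new("GeneNetwork", graph = tr, params = network@params,
      membership = integer())
}

#' Edge-betweenness communities
#'
#' Girvan-Newman community detection: edges with the highest
#' betweenness are removed iteratively and the partition with maximum
#' modularity is returned. Run on the thresholded graph's topology
#' (edges unweighted).
#'
#' @param network a [GeneNetwork-class].
#' @return the network with `membership` filled in (named integer
#'   community ids covering every vertex).
#' @export
detectCommunities <- function(network) {
  g <- network@graph
  if (igraph::vcount(g) == 0L) stopMsg("empty network")
  # igraph warns that the membership is chosen at maximum modularity,
  # which is exactly the contract here
  comm <- withCallingHandlers(
    igraph::cluster_edge_betweenness(g, weights = NULL),
    warning = function(w) {
      if (grepl("modularity", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mem <- igraph::membership(comm)
  new("GeneNetwork", graph = g, params = network@params,
      membership = setNames(as.integer(mem), igraph::V(g)$name))
}

#' Community gene sets of a network
#' @param network a [GeneNetwork-class] after [detectCommunities()].
#' @return named list of gene-id vectors, one per community.
#' @export
communityGenes <- function(network) {
  if (!length(network@membership)) stopMsg("run detectCommunities() first")
  split(names(network@membership), network@membership)
}

#' Greedy augmentation of gene clusters
#'
#' For each cluster, candidate genes from the ranked pool are appended
#' in order; an addition is kept iff it improves macro F1 by at least
#' `minGain`. Augmentation stops when the pool is exhausted or every
#' per-class F1 reaches `targetF1`. Every trial is recorded in the
#' trace.
#'
#' @param clusters named list of disjoint gene sets.
#' @param pool candidate genes in rank order (e.g. by global RF
#'   importance).
#' @param trainEval function gene-set -> named per-class F1 vector.
#' @param minGain minimum macro-F1 improvement to keep an addition
#'   (default 0.01).
#' @param targetF1 stop once all per-class F1 reach this (default 1).
#' @return list with `clusters` (augmented sets) and `trace`
#'   (data.frame of every trial).
#' @export
augmentClusters <- function(clusters, pool, trainEval, minGain = 0.01,
                            targetF1 = 1) {
  if (anyDuplicated(unlist(clusters))) stopMsg("clusters must be disjoint")
  trace <- data.frame(cluster = character(), gene = character(),
                      macroF1 = numeric(), accepted = logical())
  out <- clusters
  for (cn in names(clusters)) {
    genes <- clusters[[cn]]
    f1 <- trainEval(genes)
    best <- mean(f1)
    for (cand in setdiff(pool, genes)) {
      if (all(f1 >= targetF1)) break
      f1Try <- tryCatch(trainEval(c(genes, cand)), error = function(e) {
        stopMsg("train_eval failed on cluster %s + %s: %s (trace preserved)",
                cn, cand, conditionMessage(e))
      })
      gain <- mean(f1Try) - best
      accept <- gain >= minGain
      trace <- rbind(trace, data.frame(cluster = cn, gene = cand,
                                       macroF1 = mean(f1Try),
                                       accepted = accept))
      if (accept) {
        genes <- c(genes, cand)
        f1 <- f1Try
        best <- mean(f1)
      }
    }
    out[[cn]] <- genes
  }
  list(clusters = out, trace = trace)
}

#' Export a network as an edge list
#' @param network a [GeneNetwork-class].
#' @return data.frame gene_a, gene_b, r.
#' @export
edgeList <- function(network) {
  g <- network@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric()))
  e <- igraph::as_edgelist(g)
  data.frame(gene_a = e[, 1L], gene_b = e[, 2L], r = igraph::E(g)$r)
}
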