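test_that("confusion matrices tally counts and one-vs-rest totals", {
  true <- c("A", "A", "B", "B")
  pred <- c("A", "B", "B", "A")
  cm <- confusionCounts(true, pred)
  expect_equal(sum(cm@table) - sum(diag(cm@table)), 2L)
  # perfect predictions give a diagonal matrix
  cmP <- confusionCounts(true, true)
  expect_true(all(cmP@table[upper.tri(cmP@table)] == 0L))
  expect_true(all(cmP@table[lower.tri(cmP@table)] == 0L))
  # hand-tallied one-vs-rest counts on a 3-class example
  t3 <- c("A", "A", "A", "B", "B", "C")
  p3 <- c("A", "B", "A", "B", "C", "C")
  cm3 <- confusionCounts(t3, p3)
  # class A: TP = 2 (A->A twice), FN = 1 (A->B), FP = 0, TN = 3
  expect_equal(unname(cm3@ovr["A", ]), c(2, 0, 3, 1))
  # class B: TP = 1, FN = 1 (B->C), FP = 1 (A->B), TN = 3
  expect_equal(unname(cm3@ovr["B", ]), c(1, 1, 3, 1))
  expect_true(all(rowSums(cm3@ovr) == 6))
  expect_error(confusionCounts(t3, c("A", "A", "A", "B", "B", "Z"),
                               classes = c("A", "B", "C")), "outside")
})

test_that("class metrics reproduce the count formulas", {
  # craft a 2-class tally with TP=50 TN=40 FP=5 FN=5 for class P
  true <- c(rep("P", 55L), rep("N", 45L))
  pred <- c(rep("P", 50L), rep("N", 5L), rep("P", 5L), rep("N", 40L))
  met <- classMetrics(confusionCounts(true, pred))
  p <- met[met$class == "P", ]
  expect_equal(p$accuracy, 0.9)                    # (50+40)/100
  expect_equal(p$precision, 50 / 55)
  expect_equal(p$sensitivity, 50 / 55)
  expect_equal(p$specificity, 40 / 45)
  expect_equal(p$f1, 100 / 110)
  # F1 from TP=2, FP=1, FN=1 is 4/6
  t2 <- c("X", "X", "X", "Y")
  p2 <- c("X", "X", "Y", "X")
  m2 <- classMetrics(confusionCounts(t2, p2))
  expect_equal(m2$f1[m2$class == "X"], 4 / 6)
  # a perfect classifier scores 1 everywhere, for any labeling
  for (y in list(c("A", "B", "C", "A"), rep("Z", 5L), c(1, 2, 1, 2, 3, 3))) {
    mm <- classMetrics(confusionCounts(y, y))
    vals <- unlist(mm[mm$class != "macro",
                      c("precision", "sensitivity", "f1")])
    expect_true(all(is.na(vals) | vals == 1))
    expect_true(all(mm$accuracy == 1))
  }
})

test_that("macro metrics equal per-class means and 0/0 yields NA", {
  true <- c("A", "A", "B", "C")
  pred <- c("A", "A", "A", "C")   # class B never predicted: precision 0/0
  met <- classMetrics(confusionCounts(true, pred))
  expect_true(is.na(met$precision[met$class == "B"]))
  per <- met[met$class != "macro", ]
  mac <- met[met$class == "macro", ]
  expect_equal(mac$f1, mean(per$f1, na.rm = TRUE))
  expect_equal(mac$accuracy, mean(per$accuracy))
})

test_that("multiclass AUC reduces to rank AUC and calibrates to 0.5", {
  # binary case against the brute-force pairwise oracle
  true <- c("P", "P", "P", "N", "N", "N")
  pa <- c(0.9, 0.7, 0.65, 0.6, 0.3, 0.1)
  probs <- cbind(P = pa, N = 1 - pa)
  expect_equal(multiclassAUC(true, probs),
               aucByPairs(pa[1:3], pa[4:6]))
  # invariant under strictly monotone transformation of the scores
  f <- function(v) v^3
  probs2 <- cbind(P = f(pa), N = 1 - f(pa))
  expect_equal(multiclassAUC(true, probs2), multiclassAUC(true, probs))
  # perfect separation
  expect_equal(multiclassAUC(true, cbind(P = c(1, 1, 1, 0, 0, 0),
                                         N = c(0, 0, 0, 1, 1, 1))), 1)
  # label-independent probabilities hover at 0.5
  set.seed(21)
  n <- 2000L
  yy <- sample(c("A", "B", "C", "D"), n, replace = TRUE)
  pp <- matrix(runif(4L * n), n, 4L, dimnames = list(NULL, c("A", "B", "C", "D")))
  pp <- pp / rowSums(pp)
  expect_lt(abs(multiclassAUC(yy, pp) - 0.5), 0.05)
  expect_error(multiclassAUC(rep("A", 4L), pp[1:4, ]), "2 observed")
})

test_that("the PCA grid spans the projected training points", {
  d <- separableData(nPerClass = 20L, nFeatures = 15L, seed = 14L)
  sp <- splitData(d$y, seed = 1L)
  res <- 40L
  g <- pcaGrid(d$x[sp$train, ], d$y[sp$train], d$x[sp$test, ], d$y[sp$test],
               family = "XGB", resolution = res, seed = 2L)
  expect_equal(nrow(g$grid), res^2)
  expect_true(all(g$train$PC1 >= min(g$grid$PC1) &
                    g$train$PC1 <= max(g$grid$PC1)))
  expect_true(all(g$train$PC2 >= min(g$grid$PC2) &
                    g$train$PC2 <= max(g$grid$PC2)))
  # each cluster's projected points sit in a region of their own label
  nearestLabel <- function(pt) {
    i <- which.min((g$grid$PC1 - pt[1L])^2 + (g$grid$PC2 - pt[2L])^2)
    as.character(g$grid$label[i])
  }
  hits <- vapply(seq_len(nrow(g$train)),
                 function(i) nearestLabel(unlist(g$train[i, 1:2])) ==
                   as.character(g$train$label[i]), logical(1L))
  expect_gte(mean(hits), 0.95)
  expect_error(pcaGrid(d$x, d$y, d$x, d$y, resolution = 1L), "resolution")
})

test_that("t-SNE is deterministic and separates distinct clusters", {
  d <- separableData(nPerClass = 25L, nFeatures = 20L, seed = 15L)
  e1 <- tsneEmbed(d$x, dims = 2L, perplexity = 15, maxIter = 300L, seed = 3L)
  e2 <- tsneEmbed(d$x, dims = 2L, perplexity = 15, maxIter = 300L, seed = 3L)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(100L, 2L))
  e3 <- tsneEmbed(d$x, dims = 3L, perplexity = 15, maxIter = 200L, seed = 3L)
  expect_equal(ncol(e3), 3L)
  sil <- cluster::silhouette(as.integer(d$y), dist(e1))
  expect_gt(mean(sil[, 3L]), 0.5)
  expect_error(tsneEmbed(d$x[1:20, ], perplexity = 30), "perplexity")
})

test_that("heatmap export orders rows and columns by correlation clustering", {
  set.seed(16)
  x <- matrix(rnorm(200), 20L, 10L,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  h <- heatmapData(x)
  expect_identical(h$values, x)
  expect_setequal(h$rowOrder, 1:20)
  expect_setequal(h$colOrder, 1:10)
})
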