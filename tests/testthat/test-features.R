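test_that("MAD ranking matches a brute-force sort", {
  set.seed(3)
  b <- matrix(rnorm(100, sd = rep(c(2, 0.5), each = 50L)), 10L, 10L,
              dimnames = list(sprintf("cg%02d", 1:10), NULL))
  sel <- madSelect(b, 10L)
  mads <- apply(b, 1L, madByHand)
  oracle <- rownames(b)[order(-mads, rownames(b))]
  expect_identical(sel, oracle)
  # variable probe ranks above a constant probe
  b2 <- rbind(v = c(1, 2, 3, 4, 5), c = c(3, 3, 3, 3, 3))
  expect_identical(madSelect(b2, 2L), c("v", "c"))
  # scaling constant never changes ranks: compare against stats::mad default
  scaled <- rownames(b)[order(-apply(b, 1L, stats::mad), rownames(b))]
  expect_identical(sel, scaled)
  # constant matrix: deterministic lexicographic tie-break, no error
  b3 <- matrix(1, 4L, 3L, dimnames = list(c("d", "b", "a", "c"), NULL))
  expect_identical(madSelect(b3, 2L), c("a", "b"))
  expect_error(madSelect(b, 99L), "exceeds")
})

test_that("random-forest selection recovers informative probes", {
  om <- generateOmics(syntheticSpec(
    classCounts = c(WNT = 20L, SHH = 30L, Group3 = 25L, Group4 = 45L),
    nProbes = 500L, nInformative = 30L, delta = 0.4, noiseSd = 0.3,
    nGenes = 10L, seed = 13L))
  b <- betaValues(om)
  sel <- rfImportanceSelect(b, subgroups(om), nSelect = 30L, seed = 1L)
  informative <- rownames(b)[seq_len(30L)]
  expect_length(sel, 30L)
  expect_gte(length(intersect(sel, informative)), 27L)
  # deterministic given the seed
  expect_identical(as.vector(sel),
                   as.vector(rfImportanceSelect(b, subgroups(om),
                                                nSelect = 30L, seed = 1L)))
  # nSelect = nProbes returns everything
  expect_setequal(rfImportanceSelect(b[1:40, ], subgroups(om),
                                     nTrees = 50L, nSelect = 40L),
                  rownames(b)[1:40])
  expect_error(rfImportanceSelect(b, rep("A", ncol(b)), nSelect = 5L),
               "2 classes")
})

test_that("train/test splitting respects fractions and stratification", {
  y <- factor(rep(c("A", "B", "C", "D"), each = 25L))
  sp <- splitData(y, trainFrac = 0.8, seed = 1L)
  expect_length(sp$train, 80L)
  expect_length(sp$test, 20L)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  # stratification preserves proportions within one sample per class
  expect_true(all(abs(table(y[sp$train]) - 20L) <= 1L))
  # three-way neural-network split
  sp3 <- splitData(y, threeWay = TRUE, seed = 2L)
  expect_equal(lengths(sp3[c("train", "validation", "test")]),
               c(train = 60L, validation = 20L, test = 20L))
  expect_identical(sort(unlist(sp3, use.names = FALSE)), 1:100)
  expect_error(splitData(factor(c("A", rep("B", 9L))), seed = 1L),
               "2 samples per class")
})

test_that("folds partition samples with near-equal sizes", {
  y <- rep(c("A", "B"), each = 50L)
  f <- makeFolds(y, k = 10L, seed = 1L)
  expect_length(f, 10L)
  expect_true(all(lengths(f) == 10L))
  expect_identical(sort(unlist(f, use.names = FALSE)), 1:100)
  f2 <- makeFolds(rep("A", 23L), k = 10L, seed = 2L)
  expect_true(all(lengths(f2) %in% 2:3))
  expect_equal(sum(lengths(f2)), 23L)
  expect_error(makeFolds(rep("A", 5L), k = 10L), "exceed")
})

test_that("SMOTE interpolates within parent segments", {
  set.seed(5)
  x <- matrix(runif(70L * 6L), 70L, 6L)
  syn <- smote(x, kNeighbors = 5L, percOver = 200, seed = 1L)
  expect_equal(nrow(syn), 140L)
  par <- attr(syn, "parents")
  for (r in seq_len(nrow(syn))) {
    lo <- pmin(x[par$base[r], ], x[par$neighbor[r], ])
    hi <- pmax(x[par$base[r], ], x[par$neighbor[r], ])
    expect_true(all(syn[r, ] >= lo - 1e-12 & syn[r, ] <= hi + 1e-12))
  }
  # degenerate: identical minority points give identical synthetics
  xd <- matrix(0.4, 5L, 3L)
  synd <- smote(xd, kNeighbors = 2L, percOver = 100, seed = 2L)
  expect_true(all(synd == 0.4))
  expect_error(smote(x[1:4, ], kNeighbors = 5L), "exceed kNeighbors")
  expect_error(smote(x, percOver = 150), "multiple of 100")
})

test_that("minority oversampling reaches the documented count", {
  set.seed(6)
  x <- matrix(runif(200L * 5L), 200L, 5L)
  y <- rep(c("WNT", "SHH", "Group3"), c(70L, 80L, 50L))
  bal <- smoteBalance(x, y, class = "WNT", percOver = 200, seed = 3L)
  expect_equal(sum(bal$y == "WNT"), 210L)
  expect_equal(nrow(bal$x), 200L + 140L)
  # balancing wrapper lifts every non-majority class to the majority size
  bal2 <- smoteBalance(x, y, toMajority = TRUE, seed = 4L)
  expect_true(all(table(bal2$y) == 80L))
})

test_that("gene collapsing takes medians and drops unannotated probes", {
  v <- matrix(c(0.2, 0.4, 0.9,
                0.1, 0.5, 0.8,
                0.7, 0.7, 0.7), 3L, 3L, byrow = FALSE,
              dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2", "s3")))
  ann <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    gene = c("G1", "G1", "G1"))
  out <- annotateCollapse(v, ann)
  expect_equal(unname(out["G1", ]), unname(apply(v, 2L, median)))
  # unannotated probe disappears
  ann2 <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                     gene = c("G1", "", "G2"))
  out2 <- annotateCollapse(v, ann2)
  expect_setequal(rownames(out2), c("G1", "G2"))
  expect_equal(unname(out2["G1", ]), unname(v["cg1", ]))
  # one probe per gene is an identity up to renaming
  ann3 <- data.frame(probe_id = rownames(v), gene = c("A", "B", "C"))
  out3 <- annotateCollapse(v, ann3)
  expect_equal(unname(out3), unname(v))
  expect_warning(
    annotateCollapse(v, data.frame(probe_id = rownames(v), gene = "")),
    "no probe")
})
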