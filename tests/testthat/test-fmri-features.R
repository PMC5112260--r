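test_that("PSC matches hand-evaluated cases", {
  # single voxel: structured mean 5, random mean 3 -> (5-3)/(5+3)
  expect_equal(computePSC(rbind(c(4, 6, 2, 4)), 1:2, 3:4), 0.25)
  # two voxels with PSC 0.25 and -0.25 average to zero
  y <- rbind(c(4, 6, 2, 4), c(2, 4, 4, 6))
  expect_equal(computePSC(y, 1:2, 3:4), 0)
  # equal condition means -> 0
  expect_equal(computePSC(rbind(c(1, 3, 2, 2)), 1:2, 3:4), 0)
  # textual variant divides by the averaged response (factor 2)
  expect_equal(computePSC(rbind(c(4, 6, 2, 4)), 1:2, 3:4,
                          denominator = "mean"), 0.5)
})

test_that("PSC is scale-free and rejects zero denominators", {
  set.seed(1)
  y <- matrix(rexp(60) + 1, nrow = 3)
  v <- computePSC(y, 1:10, 11:20)
  expect_equal(computePSC(7.3 * y, 1:10, 11:20), v)
  bad <- rbind(c(1, 1, -1, -1))
  expect_error(computePSC(bad, 1:2, 3:4), "voxel 1")
})

test_that("graph matrix equals brute-force Pearson and hand values", {
  set.seed(42)
  for (rep in 1:5) {
    y <- matrix(rnorm(200), nrow = 10)
    g <- computeGraphMatrix(y)
    expect_lt(max(abs(g - bruteForceGraph(y))), 1e-12)
    expect_equal(diag(g), rep(1, 10))
    expect_true(all(abs(g) <= 1))
    expect_identical(g, t(g))
  }
  expect_equal(computeGraphMatrix(rbind(c(1, 2, 3), c(1, 3, 2)))[1, 2], 0.5)
  expect_equal(computeGraphMatrix(rbind(c(1, 2, 3), -c(1, 2, 3)))[1, 2], -1)
  expect_error(computeGraphMatrix(rbind(c(1, 1, 1), c(1, 2, 3))), "voxel 1")
})

test_that("spatial basis recovers well-separated blobs", {
  set.seed(5)
  blob1 <- cbind(rnorm(15, -20), rnorm(15), rnorm(15))
  blob2 <- cbind(rnorm(15, 20), rnorm(15), rnorm(15))
  basis <- buildSpatialBasis(rbind(blob1, blob2), K = 2, seed = 1)
  cl <- clusterAssignments(basis)
  truth <- rep(1:2, each = 15)
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
  expect_equal(nKernels(basis), 2)
  expect_true(all(basis@P >= 0))
})

test_that("kernel count defaults follow the reference ROI sizes", {
  expect_equal(kernelCountForROI(32), 3L)
  expect_equal(kernelCountForROI(82), 4L)
  expect_equal(kernelCountForROI(126), 8L)
})

test_that("hemisphere split clusters each side independently", {
  set.seed(8)
  coords <- rbind(
    cbind(rnorm(40, -15, 4), rnorm(40), rnorm(40)),
    cbind(rnorm(40, 15, 4), rnorm(40), rnorm(40)))
  basis <- buildSpatialBasis(coords, K = 4, seed = 2, splitHemispheres = TRUE)
  cl <- clusterAssignments(basis)
  expect_true(all(cl[coords[, 1] < 0] %in% 1:2))
  expect_true(all(cl[coords[, 1] >= 0] %in% 3:4))
  expect_error(buildSpatialBasis(coords, K = 3, splitHemispheres = TRUE),
               "even")
})

test_that("degenerate K = 1 basis reduces to a single kernel", {
  set.seed(2)
  coords <- matrix(rnorm(30), ncol = 3)
  basis <- buildSpatialBasis(coords, K = 1, seed = 1)
  expect_equal(nKernels(basis), 1)
  g <- computeGraphMatrix(matrix(rnorm(100), nrow = 10))
  expect_equal(dim(reduceGraph(g, basis)), c(1L, 1L))
})

test_that("functional consensus recovers planted connectivity blocks", {
  set.seed(7)
  V <- 20
  block <- rep(1:2, each = 10)
  makeGraph <- function() {
    z <- matrix(rnorm(2 * 50), nrow = 2)
    y <- z[block, ] + matrix(rnorm(V * 50, sd = 0.4), V)
    computeGraphMatrix(y)
  }
  graphs <- lapply(1:6, function(i) makeGraph())
  coords <- cbind(rnorm(V), rnorm(V), rnorm(V))
  basis <- buildFunctionalBasis(graphs, coords, K = 2)
  cl <- clusterAssignments(basis)
  agree <- max(mean(cl == block), mean(cl == 3 - block))
  expect_equal(agree, 1)
  expect_equal(basis@mode, "functional")
  expect_error(buildFunctionalBasis(graphs[1], coords, K = 2),
               "at least 2 subjects")
})

test_that("unanimous per-subject clusterings pass through consensus", {
  # two exact blocks shared by all subjects -> co-association in {0, 1}
  V <- 12
  block <- rep(1:2, each = 6)
  g <- outer(block, block, function(a, b) ifelse(a == b, 1, -0.5))
  diag(g) <- 1
  graphs <- list(g, g, g)
  coassoc <- matrix(0, V, V)
  for (gg in graphs) {
    cl <- cutree(hclust(as.dist(1 - gg), method = "average"), k = 2)
    coassoc <- coassoc + outer(cl, cl, "==")
  }
  coassoc <- coassoc / 3
  expect_true(all(coassoc %in% c(0, 1)))
  basis <- buildFunctionalBasis(graphs, cbind(rnorm(V), rnorm(V), rnorm(V)),
                                K = 2)
  cl <- clusterAssignments(basis)
  expect_equal(max(mean(cl == block), mean(cl == 3 - block)), 1)
})

test_that("graph reduction is an exact congruence", {
  # hand example: V=2, K=1, P=(1,1)' collapses to the total sum
  g <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(reduceGraph(g, matrix(1, 2, 1)), matrix(3, 1, 1))
  # identity basis leaves the graph unchanged
  set.seed(3)
  y <- matrix(rnorm(90), nrow = 6)
  g6 <- computeGraphMatrix(y)
  expect_equal(reduceGraph(g6, diag(6)), g6)
  # symmetry to machine precision; at most K nonzero eigenvalues
  P <- matrix(rexp(18), 6, 3)
  x <- reduceGraph(g6, P)
  expect_identical(x, t(x))
  expect_lte(sum(abs(eigen(x, only.values = TRUE)$values) > 1e-10), 3)
  # permutation consistency: permuting voxels and P rows together
  perm <- sample(6)
  expect_equal(reduceGraph(g6[perm, perm], P[perm, ]), x)
  expect_error(reduceGraph(g6, matrix(1, 4, 2)), "does not match")
})

test_that("feature tables have canonical shape and integrity checks", {
  cells <- expand.grid(subject = sprintf("S%02d", 1:34),
                       roi = c("Cerebellar", "Frontal", "Subcortical"),
                       session = c("Pre", "Post"), stringsAsFactors = FALSE)
  cells$value <- seq_len(nrow(cells))
  tab <- assembleFeatureTable(cells, "PSC")
  expect_equal(dim(tab), c(34L, 6L))
  expect_equal(colnames(tab),
               c("PSC-Cerebellar-Pre", "PSC-Cerebellar-Post",
                 "PSC-Frontal-Pre", "PSC-Frontal-Post",
                 "PSC-Subcortical-Pre", "PSC-Subcortical-Post"))
  # empty input -> empty table
  empty <- assembleFeatureTable(cells[0, ], "PSC")
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 6L)
  # duplicates and missing cells are rejected
  expect_error(assembleFeatureTable(rbind(cells, cells[1, ]), "PSC"),
               "duplicate")
  expect_error(assembleFeatureTable(cells[-1, ], "PSC"), "missing cell")
})
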