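test_that("generalized distance and mu match hand evaluations", {
  expect_equal(gmlvqDistance(c(1, 1), c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2)), 3)
  expect_equal(gmlvqDistance(c(2, 3), c(2, 3), diag(2)), 0)
  # identity metric reduces to squared Euclidean distance
  x <- c(1, -2, 0.5); w <- c(0, 1, 1)
  expect_equal(gmlvqDistance(x, w, diag(3)), sum((x - w)^2))
  expect_error(gmlvqDistance(c(1, 2), c(1, 2, 3), diag(2)), "dimension")

  expect_equal(computeMu(1, 3), -0.5)
  expect_equal(computeMu(2, 2), 0)
  expect_equal(computeMu(0, 1), -1)
  expect_warning(v <- computeMu(0, 0), "zero")
  expect_equal(v, 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(21)
  for (rep in 1:5) {
    m <- sample(2:5, 1)
    x <- rnorm(m); wp <- rnorm(m); wm <- rnorm(m)
    om <- matrix(rnorm(m * m), m) / 2
    g <- gmlvqGradients(x, wp, wm, om)
    muf <- function(wp., wm., om.) {
      lam <- crossprod(om.)
      dp <- gmlvqDistance(x, wp., lam)
      dm <- gmlvqDistance(x, wm., lam)
      (dp - dm) / (dp + dm)
    }
    expect_lt(max(abs(g$gradWPlus -
      centralDifference(function(v) muf(v, wm, om), wp))), 1e-5)
    expect_lt(max(abs(g$gradWMinus -
      centralDifference(function(v) muf(wp, v, om), wm))), 1e-5)
    expect_lt(max(abs(as.numeric(g$gradOmega) -
      centralDifference(function(v) muf(wp, wm, matrix(v, m)), as.numeric(om)))),
      1e-5)
  }
})

test_that("compiled training loop agrees with a pure-R replay", {
  set.seed(22)
  n <- 12; m <- 3
  x <- rbind(matrix(rnorm(n / 2 * m), ncol = m),
             matrix(rnorm(n / 2 * m, 2), ncol = m))
  yi <- rep(1:2, each = n / 2)
  W0 <- rbind(colMeans(x[yi == 1, ]), colMeans(x[yi == 2, ]))
  Om0 <- diag(m) / sqrt(m)
  ord <- matrix(sample.int(n), ncol = 1)
  lrW <- 0.05; lrOm <- 0.01
  fit <- cognivq:::gmlvq_train_cpp(x, yi, W0, 1:2, Om0, lrW, lrOm, 1L, 0.1,
                                   ord, TRUE)
  # replay the same epoch in R via the analytic gradients
  W <- W0; Om <- Om0
  for (t in ord[, 1]) {
    g <- gmlvqGradients(x[t, ], W[yi[t], ], W[3 - yi[t], ], Om)
    W[yi[t], ] <- W[yi[t], ] - lrW * g$gradWPlus
    W[3 - yi[t], ] <- W[3 - yi[t], ] - lrW * g$gradWMinus
    Om <- Om - lrOm * g$gradOmega
    Om <- Om / sqrt(sum(diag(crossprod(Om))))
  }
  expect_equal(fit$W, W, tolerance = 1e-12)
  expect_equal(fit$Omega, Om, tolerance = 1e-12)
})

test_that("training separates separable blobs and keeps unit trace", {
  set.seed(23)
  x <- rbind(matrix(rnorm(60, sd = 0.3), ncol = 2),
             matrix(rnorm(60, 4, sd = 0.3), ncol = 2))
  y <- rep(c("a", "b"), each = 30)
  model <- gmlvqTrain(x, y, quickControl(seed = 5))
  expect_equal(gmlvqPredict(model, x)$label, y)
  expect_equal(sum(diag(metricTensor(model))), 1, tolerance = 1e-10)
  # epoch-mean cost is non-increasing in nearly every epoch
  dc <- diff(model@costTrace)
  expect_gte(mean(dc <= 1e-8), 0.95)
})

test_that("the relevant feature dominates the metric diagonal", {
  hits <- 0
  nRuns <- 20
  for (s in seq_len(nRuns)) {
    set.seed(s)
    n <- 30
    x <- cbind(c(rnorm(n), rnorm(n, 2.5)), matrix(rnorm(2 * n * 3), ncol = 3))
    model <- gmlvqTrain(x, rep(c("a", "b"), each = n),
                        quickControl(seed = s, epochs = 150))
    if (which.max(diag(metricTensor(model))) == 1) hits <- hits + 1
  }
  expect_gte(hits / nRuns, 0.9)
})

test_that("prediction depends only on relative distances", {
  set.seed(24)
  x <- rbind(matrix(rnorm(40), ncol = 2), matrix(rnorm(40, 3), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  model <- gmlvqTrain(x, y, quickControl(seed = 2))
  xNew <- matrix(rnorm(20, 1.5), ncol = 2)
  p1 <- gmlvqPredict(model, xNew)$label
  # scaling the metric by an arbitrary positive constant leaves the
  # winner-takes-all labels unchanged
  scaled <- model
  scaled@omega <- model@omega * 5
  expect_equal(gmlvqPredict(scaled, xNew)$label, p1)
})

test_that("prediction handles prototypes, ties and dimension errors", {
  model <- gmlvqTrain(rbind(c(0, 0), c(0.1, 0), c(2, 0), c(2.1, 0)),
                      c("a", "a", "b", "b"), quickControl(seed = 1, epochs = 20))
  # input at a prototype: that class, distance ~ 0
  p <- gmlvqPredict(model, model@center + model@prototypes[1, ] * model@scale)
  expect_equal(p$label, "a")
  expect_lt(p$winnerDistance, 1e-10)
  expect_error(gmlvqPredict(model, c(1, 2, 3)), "features")
  # constructed tie: two prototypes mirrored around the input
  tie <- new("GMLVQModel", prototypes = rbind(c(-1, 0), c(1, 0)),
             prototypeClasses = c("a", "b"), omega = diag(2) / sqrt(2),
             featureNames = c("f1", "f2"), center = c(0, 0), scale = c(1, 1),
             classLevels = c("a", "b"), costTrace = numeric(0))
  expect_warning(pt <- gmlvqPredict(tie, c(0, 5)), "tie")
  expect_equal(pt$label, "a")
})

test_that("metric normalization preserves eigenvectors and unit trace", {
  expect_equal(normalizeMetricTensor(2 * diag(2)), 0.5 * diag(2))
  expect_equal(normalizeMetricTensor(diag(c(3, 1))), diag(c(0.75, 0.25)))
  set.seed(25)
  for (rep in 1:5) {
    a <- matrix(rnorm(16), 4)
    lam <- crossprod(a)
    nrm <- normalizeMetricTensor(lam)
    expect_equal(sum(diag(nrm)), 1, tolerance = 1e-12)
    # same eigenvectors: normalization is simple rescaling by the trace
    expect_equal(nrm, lam / sum(diag(lam)), tolerance = 1e-10)
  }
  expect_error(normalizeMetricTensor(matrix(0, 2, 2)), "trace")
})

test_that("training rejects degenerate inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(gmlvqTrain(x, rep("a", 10)), "two classes")
  x[1, 1] <- NA
  expect_error(gmlvqTrain(x, rep(c("a", "b"), 5)), "finite")
  expect_error(gmlvqControl(lrPrototype = 0.001, lrOmega = 0.01), "exceed")
})
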