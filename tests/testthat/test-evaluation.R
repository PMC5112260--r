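canonicalSubjects <- function(protocol = "M-CD") {
  if (protocol == "M-PD") {
    data.frame(subject = sprintf("S%02d", 1:34),
               group = rep(c("patient", "control"), c(9, 25)),
               hasImaging = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(subject = sprintf("S%02d", 1:60),
               group = rep(c("patient", "control"), c(13, 47)),
               hasImaging = c(rep(TRUE, 9), rep(FALSE, 4),
                              rep(TRUE, 25), rep(FALSE, 22)),
               stringsAsFactors = FALSE)
  }
}

test_that("split plans enforce the protocol arithmetic", {
  planPD <- makeSplits(canonicalSubjects("M-PD"), "M-PD", nSplits = 10, seed = 3)
  for (s in planPD$splits) {
    expect_length(s$train, 23)  # 6 + 17
    expect_length(s$test, 11)   # 3 + 8
    grp <- canonicalSubjects("M-PD")
    expect_equal(sum(grp$group[grp$subject %in% s$test] == "patient"), 3)
    expect_equal(sum(grp$group[grp$subject %in% s$test] == "control"), 8)
    expect_length(intersect(s$train, s$test), 0)
  }
  planCD <- makeSplits(canonicalSubjects("M-CD"), "M-CD", nSplits = 10, seed = 3)
  for (s in planCD$splits) {
    expect_length(s$train, 42)  # 9 + 33
    expect_length(s$test, 18)
  }
  # imaging availability is balanced proportionally in M-CD training sets
  grp <- canonicalSubjects("M-CD")
  imgFrac <- vapply(planCD$splits, function(s)
    mean(grp$hasImaging[grp$subject %in% s$train]), numeric(1))
  expect_true(all(abs(imgFrac - 34 / 60) < 0.1))
})

test_that("split plans are deterministic and validate counts", {
  p1 <- makeSplits(canonicalSubjects(), "M-CD", nSplits = 5, seed = 9)
  p2 <- makeSplits(canonicalSubjects(), "M-CD", nSplits = 5, seed = 9)
  expect_identical(p1, p2)
  tiny <- data.frame(subject = c("a", "b"), group = c("patient", "control"),
                     hasImaging = NA)
  expect_error(makeSplits(tiny, "M-CD", trainPatients = 1, trainControls = 1),
               "insufficient")
})

test_that("balanced ensembles downsample the majority class", {
  set.seed(41)
  x <- matrix(rnorm(23 * 2), ncol = 2)
  rownames(x) <- sprintf("S%02d", 1:23)
  y <- rep(c("patient", "control"), c(6, 17))
  seen <- list()
  trainer <- function(xm, ym, seed) {
    seen[[length(seen) + 1]] <<- list(n = nrow(xm), tab = table(ym))
    gmlvqTrain(xm, ym, quickControl(seed = seed, epochs = 10))
  }
  ens <- trainBalancedEnsemble(x, y, trainer, nDownsamples = 8, seed = 2)
  expect_length(ens$members, 8)
  expect_equal(ens$minorityClass, "patient")
  for (s in seen) {
    expect_equal(s$n, 12)  # 6 minority + 6 sampled majority
    expect_equal(as.numeric(s$tab), c(6, 6))
  }
  # equal class sizes: every member sees identical data, votes unanimous
  yEq <- rep(c("patient", "control"), c(5, 5))
  ensEq <- trainBalancedEnsemble(x[1:10, ], yEq,
    function(xm, ym, seed) gmlvqTrain(xm, ym, quickControl(seed = 1, epochs = 10)),
    nDownsamples = 4, seed = 2)
  v <- cognivq:::ensembleVotes(ensEq, x[1:10, ])
  expect_true(all(apply(matrix(v$labels, ncol = 4), 1,
                        function(r) length(unique(r)) == 1)))
})

test_that("majority voting and tie-breaking follow the stated rules", {
  # hand-built members: prototype pairs voting deterministically
  mkModel <- function(flip = FALSE) {
    protos <- if (flip) rbind(c(1, 0), c(-1, 0)) else rbind(c(-1, 0), c(1, 0))
    new("GMLVQModel", prototypes = protos,
        prototypeClasses = c("control", "patient"),
        omega = diag(2) / sqrt(2), featureNames = c("f1", "f2"),
        center = c(0, 0), scale = c(1, 1),
        classLevels = c("control", "patient"), costTrace = numeric(0))
  }
  ens <- structure(list(members = c(replicate(3, mkModel(), simplify = FALSE),
                                    replicate(2, mkModel(TRUE), simplify = FALSE)),
                        minorityClass = "patient",
                        classLevels = c("control", "patient"), seed = 1),
                   class = "EnsembleClassifier")
  # 3 of 5 members vote patient for x = (1, 0)
  expect_equal(ensemblePredict(ens, c(1, 0)), "patient")
  # unanimity
  ensU <- ens; ensU$members <- replicate(4, mkModel(), simplify = FALSE)
  expect_equal(ensemblePredict(ensU, c(1, 0)), "patient")
  # 50/50 tie goes to the minority (patient) class
  ensT <- ens
  ensT$members <- c(replicate(2, mkModel(), simplify = FALSE),
                    replicate(2, mkModel(TRUE), simplify = FALSE))
  expect_equal(ensemblePredict(ensT, c(1, 0)), "patient")
})

test_that("two-classifier combination resolves disagreement by confidence", {
  mkModel <- function(protoPatient, protoControl) {
    new("GMLVQModel", prototypes = rbind(protoControl, protoPatient),
        prototypeClasses = c("control", "patient"),
        omega = diag(2) / sqrt(2), featureNames = c("f1", "f2"),
        center = c(0, 0), scale = c(1, 1),
        classLevels = c("control", "patient"), costTrace = numeric(0))
  }
  wrap <- function(model) structure(
    list(members = list(model), minorityClass = "patient",
         classLevels = c("control", "patient"), seed = 1),
    class = "EnsembleClassifier")
  # c1 says patient confidently (prototype at the test point), c2 says
  # control from farther away
  c1 <- wrap(mkModel(protoPatient = c(0, 0), protoControl = c(10, 10)))
  c2 <- wrap(mkModel(protoPatient = c(10, 10), protoControl = c(2, 0)))
  expect_equal(combineTwoClassifiers(c1, c2, c(0, 0)), "patient")
  # agreement passes through
  c3 <- wrap(mkModel(protoPatient = c(0.5, 0), protoControl = c(8, 8)))
  expect_equal(combineTwoClassifiers(c1, c3, c(0, 0)), "patient")
  # equal confidence falls back to the first classifier's label
  c4 <- wrap(mkModel(protoPatient = c(9, 9), protoControl = c(1, 0)))
  c5 <- wrap(mkModel(protoPatient = c(1, 0), protoControl = c(9, 9)))
  expect_equal(combineTwoClassifiers(c4, c5, c(0, 0)), "control")
})

test_that("confusion rates satisfy their identities", {
  r <- confusionRates(tp = 3, tn = 5, fp = 2, fn = 1)
  expect_equal(r$tpr, 0.75)
  expect_equal(r$tpr + r$fnr, 1)
  expect_equal(r$tnr + r$fpr, 1)
  rPerfect <- confusionRates(4, 6, 0, 0)
  expect_equal(rPerfect$tpr, 1)
  expect_equal(rPerfect$tnr, 1)
  expect_equal(rPerfect$fpr, 0)
  expect_error(confusionRates(0, 3, 1, 0), "undefined")
})

test_that("macroaveraged MAE matches hand evaluation and is balance-proof", {
  expect_equal(macroMAE(c("a", "a", "b", "b"), c("a", "a", "b", "b")), 0)
  # class a: 2 of 4 wrong; class b: 1 of 2 wrong -> (0.5 + 0.5) / 2
  expect_equal(macroMAE(rep(c("a", "b"), c(4, 2)),
                        c("b", "b", "a", "a", "b", "a")), 0.5)
  expect_equal(macroMAE(c("a", "b"), c("b", "a")), 1)
  # duplicating one class leaves the macro average unchanged
  yt <- rep(c("a", "b"), c(4, 2))
  yp <- c("b", "a", "a", "a", "b", "a")
  expect_equal(macroMAE(c(yt, rep("a", 4)), c(yp, c("b", "a", "a", "a"))),
               macroMAE(yt, yp))
  expect_error(macroMAE(c("a", "a"), c("a", "b")), "empty true class")
})

test_that("relative median reduction reproduces the reference arithmetic", {
  expect_equal(round(relativeMedianReduction(0.3942, 0.2381), 1), 39.6)
  expect_equal(round(relativeMedianReduction(0.3942, 0.3413), 1), 13.4)
  expect_equal(relativeMedianReduction(0.3, 0.3), 0)
  expect_error(relativeMedianReduction(0, 0.1), "positive")
})

test_that("model comparison p-values behave as a paired signed-rank test", {
  a <- seq(0.1, 0.6, length.out = 50)
  expect_equal(compareModels(a, a), 1)
  p <- compareModels(a, a + 0.2)
  expect_lt(p, 0.01)
  expect_equal(compareModels(a, a + 0.2), compareModels(a + 0.2, a))
  expect_error(compareModels(a, a[-1]), "equal length")
})
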