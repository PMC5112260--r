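test_that("cohort counts and imaging allocation follow the config", {
  cohort <- simulateCohort(simulationConfig(seed = 3))
  expect_equal(nrow(cohort$profiles), 60)
  expect_equal(sum(cohort$profiles$group == "patient"), 13)
  expect_equal(sum(cohort$profiles$hasImaging), 34)
  expect_equal(sum(!cohort$profiles$hasImaging), 26)
  expect_equal(sum(cohort$profiles$hasImaging &
                     cohort$profiles$group == "patient"), 9)
  # every imaging subject has all roi x session entries
  for (sid in names(cohort$imaging)) {
    expect_setequal(names(cohort$imaging[[sid]]),
                    c("Subcortical", "Cerebellar", "Frontal"))
    for (roi in names(cohort$imaging[[sid]]))
      expect_setequal(names(cohort$imaging[[sid]][[roi]]), c("Pre", "Post"))
  }
  expect_equal(nVoxels(cohort$imaging[[1]][["Frontal"]][["Pre"]]), 126)
})

test_that("identical config and seed give bit-identical cohorts", {
  c1 <- simulateCohort(smallSimConfig(seed = 11))
  c2 <- simulateCohort(smallSimConfig(seed = 11))
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(
    boldSignal(c1$imaging[[1]][["Beta"]][["Post"]]),
    boldSignal(c2$imaging[[1]][["Beta"]][["Post"]]))
  c3 <- simulateCohort(smallSimConfig(seed = 12))
  expect_false(identical(c1$profiles$n_dots, c3$profiles$n_dots))
})

test_that("cohort without imaging is degenerate but complete", {
  cfg <- smallSimConfig(seed = 1)
  cfg$nWithImaging <- 0L
  cfg$nImagingPatients <- 0L
  cohort <- simulateCohort(cfg)
  expect_length(cohort$imaging, 0)
  expect_equal(nrow(cohort$profiles), 20)
  expect_false(any(cohort$profiles$hasImaging))
})

test_that("invalid configs are rejected", {
  badCov <- diag(4)
  badCov[1, 2] <- badCov[2, 1] <- 2  # not positive definite
  expect_error(simulationConfig(cognitiveCov = badCov), "positive definite")
  expect_error(simulationConfig(nWithImaging = 100), "exceed")
  expect_error(
    simulationConfig(plantedEdges = data.frame(
      class = "patient", session = "Pre", roi = "Frontal",
      cluster1 = 1L, cluster2 = 2L, strength = 1.2)),
    "strengths")
  expect_error(simulateROISession(smallSimConfig(), "patient", "Nope", "Pre", 1),
               "unknown ROI")
  expect_error(simulateROISession(smallSimConfig(), "patient", "Alpha", "mid", 1),
               "unknown session")
})

test_that("zero-effect cognitive scores show no spurious class separation", {
  mu <- defaultCognitiveMeans()
  mu["patient", ] <- mu["control", ]
  reps <- 100L
  nonsig <- matrix(NA, reps, 4)
  for (s in seq_len(reps)) {
    cfg <- simulationConfig(nPatients = 10, nControls = 20, nWithImaging = 0,
                            nImagingPatients = 0, cognitiveMeans = mu,
                            seed = 1000L + s)
    p <- simulateCognitive(cfg)
    nonsig[s, ] <- vapply(cognitiveFeatureNames(), function(f)
      wilcox.test(p[[f]][p$group == "patient"],
                  p[[f]][p$group == "control"])$p.value, numeric(1)) > 0.05
  }
  for (f in 1:4) expect_gte(mean(nonsig[, f]), 0.9)
})

test_that("a strong divided-attention separation is linearly decodable", {
  mu <- defaultCognitiveMeans()
  mu["patient", ] <- mu["control", ]
  mu["patient", "t_disp_d"] <- mu["control", "t_disp_d"] +
    3 * sqrt(defaultCognitiveCov()["t_disp_d", "t_disp_d"])
  cfg <- simulationConfig(nPatients = 13, nControls = 47, nWithImaging = 0,
                          nImagingPatients = 0, cognitiveMeans = mu, seed = 4)
  p <- simulateCognitive(cfg)
  x <- as.matrix(p[cognitiveFeatureNames()])
  proj <- fitLDA(x, p$group)
  f <- projectVectors(proj, x)
  thr <- mean(c(mean(f[p$group == "control"]), mean(f[p$group == "patient"])))
  pred <- ifelse(f > thr, "patient", "control")
  expect_gte(mean(pred == p$group), 0.9)
})

test_that("null imaging generator yields PSC centred at zero", {
  cfg <- smallSimConfig()
  cfg$pscEffect$psc <- 0
  cfg$plantedEdges <- cfg$plantedEdges[0, ]
  vals <- vapply(1:50, function(s)
    computePSC(simulateROISession(cfg, "control", "Alpha", "Pre", seed = s)),
    numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("planted cluster correlation appears in the graph matrix", {
  cfg <- simulationConfig(
    nPatients = 2, nControls = 2, nWithImaging = 0, nImagingPatients = 0,
    roiSpecs = data.frame(roi = "Alpha", nVoxels = 24L, nKernels = 3L),
    plantedEdges = data.frame(class = "patient", session = "Pre",
                              roi = "Alpha", cluster1 = 1L, cluster2 = 2L,
                              strength = 0.8),
    pscEffect = data.frame(class = character(), session = character(),
                           roi = character(), psc = numeric()),
    clusterSignal = 2, noiseSd = 0.2, seed = 2)
  ts <- simulateROISession(cfg, "patient", "Alpha", "Pre", seed = 9)
  g <- computeGraphMatrix(ts)
  cl <- cognivq:::roiLayout(cfg, "Alpha")$clusters
  between <- g[cl == 1, cl == 2]
  expect_gte(mean(between), 0.6)
  # unplanted cluster pair stays near the noise floor
  off <- g[cl == 1, cl == 3]
  expect_lt(mean(off), 0.3)
})

test_that("simulated PSC tracks the configured offset", {
  cfg <- smallSimConfig(seed = 6)
  vals <- vapply(1:30, function(s)
    computePSC(simulateROISession(cfg, "patient", "Alpha", "Post", seed = s)),
    numeric(1))
  expect_lt(abs(mean(vals) - 0.035), 0.003)
})

test_that("cognitive CSV roundtrips through disk", {
  cohort <- simulateCohort(smallSimConfig(seed = 2))
  path <- tempfile(fileext = ".csv")
  writeCognitiveCSV(cohort, path)
  back <- readCognitiveCSV(path)
  expect_equal(back$n_dots, cohort$profiles$n_dots)
  expect_equal(back$group, cohort$profiles$group)
  unlink(path)
})

test_that("ROI time series TSV bundle roundtrips", {
  cohort <- simulateCohort(smallSimConfig(seed = 2))
  ts <- cohort$imaging[[1]][["Alpha"]][["Pre"]]
  prefix <- tempfile()
  writeROITimeSeriesTSV(ts, prefix)
  back <- readROITimeSeriesTSV(prefix, roi = "Alpha")
  expect_equal(unname(boldSignal(back)), unname(boldSignal(ts)),
               tolerance = 1e-10)
  expect_equal(back@structuredIdx, ts@structuredIdx)
  unlink(paste0(prefix, c("_bold.tsv", "_coords.tsv", "_volumes.tsv")))
})
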