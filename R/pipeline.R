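MODEL_NAMES <- c("M-CD", "M-PSC", "M-SGF", "M-FGF",
                 "M-PSC+SGF", "M-PSC+FGF",
                 "M+-CD-PSC", "M+-CD-SGF", "M+-CD-FGF",
                 "M+-CD-PSC+SGF", "M+-CD-PSC+FGF")

#' Experiment configuration
#'
#' Bundles everything needed to run one classifier experiment on a
#' (synthetic) cohort: the model name from the experiment taxonomy, the
#' cohort or its generating config, the split protocol scale, and the
#' training / privileged-information settings.
#'
#' Model taxonomy: `M-CD` is the cognitive-data baseline; `M-PSC`,
#' `M-SGF`, `M-FGF` classify directly from imaging features (percent
#' signal change, spatially / functionally grouped graph features);
#' `M+-CD-<PD>` classifies from cognitive data with the imaging features
#' as privileged information; `<A>+<B>` names combine two classifiers by
#' the confidence rule of [combineTwoClassifiers()].
#'
#' @param modelName one of `M-CD`, `M-PSC`, `M-SGF`, `M-FGF`,
#'   `M-PSC+SGF`, `M-PSC+FGF`, `M+-CD-PSC`, `M+-CD-SGF`, `M+-CD-FGF`,
#'   `M+-CD-PSC+SGF`, `M+-CD-PSC+FGF`.
#' @param simConfig a [simulationConfig()] (used when `cohort` is NULL).
#' @param cohort optional pre-built `SyntheticCohort`.
#' @param nSplits,nDownsamples protocol scale (50 splits x 100
#'   downsamples canonically; reduce for desk-scale runs).
#' @param trainControl a [gmlvqControl()].
#' @param piControl a [piControl()].
#' @param tuneBounds tune the percentile bounds on the first split only
#'   (then frozen) instead of using the fixed defaults.
#' @param keepMatrices store per-member metric tensors and balanced
#'   training errors for relevance analysis.
#' @param keepEnsembles store per-split ensembles (needed by hybrids).
#' @param seed master seed; every stage seed derives from it.
#' @return list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(modelName, simConfig = simulationConfig(),
                             cohort = NULL, nSplits = 50L,
                             nDownsamples = 100L,
                             trainControl = gmlvqControl(),
                             piControl = cognivq::piControl(),
                             tuneBounds = FALSE, keepMatrices = FALSE,
                             keepEnsembles = FALSE, seed = 1L) {
  if (!modelName %in% MODEL_NAMES)
    stop("unknown model name '", modelName, "'; expected one of: ",
         paste(MODEL_NAMES, collapse = ", "))
  structure(list(modelName = modelName, simConfig = simConfig,
                 cohort = cohort, nSplits = as.integer(nSplits),
                 nDownsamples = as.integer(nDownsamples),
                 trainControl = trainControl, piControl = piControl,
                 tuneBounds = isTRUE(tuneBounds),
                 keepMatrices = isTRUE(keepMatrices),
                 keepEnsembles = isTRUE(keepEnsembles),
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

parseModelName <- function(modelName) {
  if (grepl("^M\\+-CD-", modelName)) {
    pd <- sub("^M\\+-CD-", "", modelName)
    if (grepl("\\+", pd)) {
      parts <- strsplit(pd, "+", fixed = TRUE)[[1]]
      list(kind = "hybrid",
           constituents = paste0("M+-CD-", parts))
    } else {
      list(kind = "pi", protocol = "M-CD", input = "CD", pd = pd)
    }
  } else if (modelName == "M-CD") {
    list(kind = "plain", protocol = "M-CD", input = "CD")
  } else {
    pd <- sub("^M-", "", modelName)
    if (grepl("\\+", pd)) {
      parts <- strsplit(pd, "+", fixed = TRUE)[[1]]
      list(kind = "hybrid", constituents = paste0("M-", parts))
    } else {
      list(kind = "plain", protocol = "M-PD", input = pd)
    }
  }
}

#' Percent-signal-change feature table of a cohort
#'
#' @param cohort a `SyntheticCohort`.
#' @return data.frame, imaging subjects x 6 features `PSC-<ROI>-<Session>`.
#' @export
computePSCTable <- function(cohort) {
  rows <- list()
  for (sid in names(cohort$imaging))
    for (roi in names(cohort$imaging[[sid]]))
      for (session in names(cohort$imaging[[sid]][[roi]]))
        rows[[length(rows) + 1]] <- data.frame(
          subject = sid, roi = roi, session = session,
          value = computePSC(cohort$imaging[[sid]][[roi]][[session]]),
          stringsAsFactors = FALSE)
  assembleFeatureTable(do.call(rbind, rows), "PSC")
}

#' Kernel-reduced connectivity graphs of a cohort
#'
#' Computes per-subject, per-ROI, per-session graph matrices, builds one
#' smoothing basis per ROI (spatial k-means or functional consensus
#' clustering over all subject-session graphs), and returns the reduced
#' K x K matrices.
#'
#' @param cohort a `SyntheticCohort`.
#' @param grouping `"spatial"` or `"functional"`.
#' @param seed seed for the k-means restarts.
#' @return list with `reduced` (nested `[[subject]][[roi]][[session]]`
#'   K x K matrices) and `bases` (per-ROI [SmoothingBasis-class]).
#' @export
reducedGraphsForCohort <- function(cohort, grouping = c("spatial", "functional"),
                                   seed = 1L) {
  grouping <- match.arg(grouping)
  subjects <- names(cohort$imaging)
  if (length(subjects) == 0) stop("cohort has no imaging data")
  rois <- names(cohort$imaging[[subjects[1]]])
  graphs <- lapply(setNames(nm = subjects), function(sid)
    lapply(setNames(nm = rois), function(roi)
      lapply(cohort$imaging[[sid]][[roi]], computeGraphMatrix)))
  bases <- lapply(setNames(nm = rois), function(roi) {
    spec <- cohort$config$roiSpecs
    K <- spec$nKernels[spec$roi == roi]
    coords <- voxelCoords(cohort$imaging[[subjects[1]]][[roi]][[1]])
    if (grouping == "spatial") {
      split <- K %% 2 == 0 && nrow(coords) >= 100 &&
        any(coords[, 1] < 0) && any(coords[, 1] >= 0)
      buildSpatialBasis(coords, K, seed = seed, splitHemispheres = split)
    } else {
      allGraphs <- unlist(lapply(graphs, function(s) s[[roi]]),
                          recursive = FALSE)
      buildFunctionalBasis(allGraphs, coords, K, seed = seed)
    }
  })
  reduced <- lapply(graphs, function(s)
    lapply(setNames(nm = rois), function(roi)
      lapply(s[[roi]], function(g) reduceGraph(g, bases[[roi]]))))
  list(reduced = reduced, bases = bases)
}

# supervised per-split graph-feature extraction: 2D-LDA fit on the
# training subjects only, then projected over all subjects
graphFeatureTableForSplit <- function(reduced, labels, trainSubjects, family) {
  subjects <- names(reduced)
  rois <- names(reduced[[1]])
  rows <- list()
  projections <- list()
  for (roi in rois) for (session in c("Pre", "Post")) {
    trainIdx <- intersect(trainSubjects, subjects)
    mats <- lapply(trainIdx, function(s) reduced[[s]][[roi]][[session]])
    proj <- fit2DLDA(mats, labels[trainIdx])
    projections[[paste(roi, session, sep = "-")]] <- proj
    f <- projectGraphs(proj, lapply(subjects, function(s)
      reduced[[s]][[roi]][[session]]))
    rows[[length(rows) + 1]] <- data.frame(
      subject = subjects, roi = roi, session = session, value = f,
      stringsAsFactors = FALSE)
  }
  tab <- assembleFeatureTable(do.call(rbind, rows), family)
  attr(tab, "projections") <- projections
  tab
}

memberBalancedError <- function(member, x, y) {
  macroMAE(y, gmlvqPredict(member, x)$label)
}

#' Run one experiment of the model taxonomy
#'
#' Executes the full protocol for the named model: cohort generation (or
#' reuse), feature extraction, repeated stratified splits, per-split
#' downsampling-ensemble training (with privileged-information metric
#' fusion for `M+` models), and evaluation. Hybrid names run both
#' constituents on the same splits and combine them test point by test
#' point.
#'
#' @param config an [experimentConfig()].
#' @return list of class `EvaluationReport`: `model`, `perSplit`
#'   (data.frame of confusion counts, rates and MMAE per split), `mmae`,
#'   `summary` ([summarizeMMAE()]), plus optional `relevance` (per-split
#'   member matrices and errors for [selectReliableMembers()]),
#'   `ensembles`, `splits`.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  cohort <- config$cohort
  if (is.null(cohort)) cohort <- simulateCohort(config$simConfig)
  spec <- parseModelName(config$modelName)

  if (spec$kind == "hybrid") {
    sub <- lapply(spec$constituents, function(nm) {
      cfg <- config
      cfg$modelName <- nm
      cfg$cohort <- cohort
      cfg$keepEnsembles <- TRUE
      runExperiment(cfg)
    })
    return(combineReports(sub[[1]], sub[[2]], config$modelName))
  }

  profiles <- cohort$profiles
  labels <- setNames(profiles$group, profiles$subject)

  # model inputs
  inputTable <- NULL
  reduced <- NULL
  if (spec$input == "CD") {
    inputTable <- as.matrix(profiles[cognitiveFeatureNames()])
    rownames(inputTable) <- profiles$subject
  } else if (spec$input == "PSC") {
    inputTable <- as.matrix(computePSCTable(cohort))
  } else {
    reduced <- reducedGraphsForCohort(
      cohort, if (spec$input == "SGF") "spatial" else "functional",
      seed = config$seed)$reduced
  }

  # privileged features for M+ models
  pdTable <- NULL
  pdReduced <- NULL
  if (spec$kind == "pi") {
    if (spec$pd == "PSC") {
      pdTable <- as.matrix(computePSCTable(cohort))
    } else {
      pdReduced <- reducedGraphsForCohort(
        cohort, if (spec$pd == "SGF") "spatial" else "functional",
        seed = config$seed)$reduced
    }
  }

  splitPlan <- makeSplits(profiles, spec$protocol, config$nSplits,
                          seed = config$seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  splitSeeds <- sample.int(2147483646L, config$nSplits)

  piCfg <- config$piControl
  perSplit <- list()
  relevance <- list()
  ensembles <- list()
  for (s in seq_len(config$nSplits)) {
    split <- splitPlan$splits[[s]]

    if (!is.null(reduced)) {
      tab <- graphFeatureTableForSplit(reduced, labels, split$train,
                                       spec$input)
      x <- as.matrix(tab)
    } else {
      x <- inputTable
    }
    if (!is.null(pdReduced)) {
      pdTab <- graphFeatureTableForSplit(pdReduced, labels, split$train,
                                         spec$pd)
      pdTable <- as.matrix(pdTab)
    }

    baseControl <- config$trainControl
    if (spec$kind == "pi" && config$tuneBounds && s == 1L) {
      trIdx <- split$train
      pIdx <- which(trIdx %in% rownames(pdTable))
      piCfg <- tunePercentileBounds(
        x[trIdx, , drop = FALSE], labels[trIdx],
        pdTable[trIdx[pIdx], , drop = FALSE], pIdx, baseControl)
    }

    trainer <- if (spec$kind == "pi") {
      function(xm, ym, seed) {
        ctrl <- baseControl
        ctrl$seed <- seed
        sub <- rownames(xm)
        has <- sub %in% rownames(pdTable)
        if (sum(has) < 4 || length(unique(ym[has])) < 2)
          return(gmlvqTrain(xm, ym, ctrl))
        trainPIGMLVQ(xm, ym, pdTable[sub[has], , drop = FALSE],
                     which(has), piCfg, ctrl)
      }
    } else {
      function(xm, ym, seed) {
        ctrl <- baseControl
        ctrl$seed <- seed
        gmlvqTrain(xm, ym, ctrl)
      }
    }

    xTrain <- x[split$train, , drop = FALSE]
    yTrain <- labels[split$train]
    ens <- trainBalancedEnsemble(xTrain, yTrain, trainer,
                                 config$nDownsamples, seed = splitSeeds[s])
    xTest <- x[split$test, , drop = FALSE]
    yTest <- labels[split$test]
    pred <- ensemblePredict(ens, xTest)
    cm <- confusionRates(
      tp = sum(pred == "patient" & yTest == "patient"),
      tn = sum(pred == "control" & yTest == "control"),
      fp = sum(pred == "patient" & yTest == "control"),
      fn = sum(pred == "control" & yTest == "patient"))
    perSplit[[s]] <- data.frame(split = s, as.data.frame(cm),
                                mmae = macroMAE(yTest, pred))
    if (config$keepMatrices) {
      relevance[[s]] <- list(
        matrices = lapply(ens$members, function(m) {
          lam <- metricTensor(m)
          dimnames(lam) <- list(m@featureNames, m@featureNames)
          lam
        }),
        errors = vapply(ens$members, memberBalancedError,
                        numeric(1), x = xTrain, y = yTrain))
    }
    if (config$keepEnsembles)
      ensembles[[s]] <- list(ensemble = ens, test = split$test,
                             xTest = xTest, yTest = yTest)
  }
  perSplit <- do.call(rbind, perSplit)
  structure(list(
    model = config$modelName, perSplit = perSplit, mmae = perSplit$mmae,
    summary = summarizeMMAE(perSplit$mmae),
    relevance = if (config$keepMatrices) relevance,
    ensembles = if (config$keepEnsembles) ensembles,
    splits = splitPlan),
    class = "EvaluationReport")
}

combineReports <- function(r1, r2, modelName) {
  if (is.null(r1$ensembles) || is.null(r2$ensembles))
    stop("hybrid combination requires kept ensembles")
  perSplit <- list()
  for (s in seq_along(r1$ensembles)) {
    e1 <- r1$ensembles[[s]]
    e2 <- r2$ensembles[[s]]
    common <- intersect(e1$test, e2$test)
    pred <- combineTwoClassifiers(
      e1$ensemble, e2$ensemble,
      e1$xTest[match(common, e1$test), , drop = FALSE],
      e2$xTest[match(common, e2$test), , drop = FALSE])
    yTest <- e1$yTest[match(common, e1$test)]
    cm <- confusionRates(
      tp = sum(pred == "patient" & yTest == "patient"),
      tn = sum(pred == "control" & yTest == "control"),
      fp = sum(pred == "patient" & yTest == "control"),
      fn = sum(pred == "control" & yTest == "patient"))
    perSplit[[s]] <- data.frame(split = s, as.data.frame(cm),
                                mmae = macroMAE(yTest, pred))
  }
  perSplit <- do.call(rbind, perSplit)
  structure(list(model = modelName, perSplit = perSplit,
                 mmae = perSplit$mmae,
                 summary = summarizeMMAE(perSplit$mmae),
                 constituents = list(r1, r2)),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "EvaluationReport %s: %d splits\n  MMAE mean %.4f, sd %.4f, median %.4f, (25%%, 75%%) = (%.4f, %.4f)\n",
    x$model, nrow(x$perSplit), s["mean"], s["sd"], s["median"],
    s["q25"], s["q75"]))
  invisible(x)
}

#' Summary tables over several experiment reports
#'
#' Builds the two standard result tables: per-model MMAE summaries (mean,
#' sd, median, 25/75 percentiles) with paired signed-rank p-values and
#' relative median reductions against a baseline model, and overall
#' TPR/TNR from confusion counts pooled over splits.
#'
#' @param reports list of `EvaluationReport`s.
#' @param baseline model name used as comparison baseline (default
#'   `"M-CD"` if present).
#' @return list with data.frames `mmae` and `rates`.
#' @export
summarizeTables <- function(reports, baseline = "M-CD") {
  names(reports) <- vapply(reports, `[[`, character(1), "model")
  ns <- vapply(reports, function(r) length(r$mmae), integer(1))
  if (length(unique(ns)) != 1)
    stop("reports have mismatched split counts: ",
         paste(unique(ns), collapse = ", "))
  base <- if (baseline %in% names(reports)) reports[[baseline]] else NULL
  mmae <- do.call(rbind, lapply(reports, function(r) {
    s <- r$summary
    data.frame(
      model = r$model, mean = s["mean"], sd = s["sd"], median = s["median"],
      q25 = s["q25"], q75 = s["q75"],
      pValue = if (!is.null(base) && r$model != base$model)
        compareModels(base$mmae, r$mmae) else NA_real_,
      relMedianReductionPct = if (!is.null(base) && r$model != base$model)
        relativeMedianReduction(base$summary["median"], s["median"])
      else NA_real_,
      row.names = NULL)
  }))
  rates <- do.call(rbind, lapply(reports, function(r) {
    ps <- r$perSplit
    data.frame(model = r$model,
               tpr = sum(ps$tp) / sum(ps$tp + ps$fn),
               tnr = sum(ps$tn) / sum(ps$tn + ps$fp),
               row.names = NULL)
  }))
  list(mmae = mmae, rates = rates)
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys: `model`, `n_splits`, `n_downsamples`, `seed`,
#' `tune_bounds`, nested `simulation` (passed to [simulationConfig()]),
#' `train` (passed to [gmlvqControl()]) and `pi` (passed to
#' [piControl()]).
#'
#' @param path YAML file.
#' @return an [experimentConfig()].
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(simulationConfig, as.list(y$simulation))
  tc <- do.call(gmlvqControl, as.list(y$train))
  pc <- do.call(piControl, as.list(y$pi))
  experimentConfig(
    modelName = y$model, simConfig = sim,
    nSplits = if (!is.null(y$n_splits)) y$n_splits else 50L,
    nDownsamples = if (!is.null(y$n_downsamples)) y$n_downsamples else 100L,
    trainControl = tc, piControl = pc,
    tuneBounds = isTRUE(y$tune_bounds),
    seed = if (!is.null(y$seed)) y$seed else 1L)
}
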