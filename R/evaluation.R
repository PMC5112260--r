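#' Stratified training/test split plan
#'
#' Creates repeated stratified splits of a two-class cohort. Under the
#' `"M-PD"` protocol only subjects with imaging enter, and the canonical
#' training set holds 6 patients and 17 controls (of 9/25). Under
#' `"M-CD"` all subjects enter, the canonical training set holds 9
#' patients and 33 controls (of 13/47), and sampling additionally
#' balances imaging availability between training and test sets. For
#' cohorts of other sizes the training counts default to the same
#' fractions (about two thirds per class), rounded.
#'
#' @param subjects data.frame with columns `subject`, `group`
#'   (`"patient"`/`"control"`) and `hasImaging` (logical; may be `NA` for
#'   `"M-PD"` input restricted upstream).
#' @param protocol `"M-PD"` or `"M-CD"`.
#' @param nSplits number of splits (default 50).
#' @param seed integer seed.
#' @param trainPatients,trainControls per-class training counts;
#'   defaults follow the protocol.
#' @return list of class `SplitPlan`: `splits` (list of
#'   `list(train, test)` subject-id vectors), `protocol`, counts, `seed`.
#' @export
makeSplits <- function(subjects, protocol = c("M-CD", "M-PD"), nSplits = 50L,
                       seed = 1L, trainPatients = NULL, trainControls = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "M-PD") {
    if (!all(is.na(subjects$hasImaging)))
      subjects <- subjects[subjects$hasImaging %in% TRUE, , drop = FALSE]
  }
  pat <- subjects$subject[subjects$group == "patient"]
  con <- subjects$subject[subjects$group == "control"]
  canonical <- if (protocol == "M-PD") {
    list(pool = c(9L, 25L), train = c(6L, 17L))
  } else {
    list(pool = c(13L, 47L), train = c(9L, 33L))
  }
  if (is.null(trainPatients)) {
    trainPatients <- if (length(pat) == canonical$pool[1]) canonical$train[1]
      else max(1L, round(length(pat) * canonical$train[1] / canonical$pool[1]))
  }
  if (is.null(trainControls)) {
    trainControls <- if (length(con) == canonical$pool[2]) canonical$train[2]
      else max(1L, round(length(con) * canonical$train[2] / canonical$pool[2]))
  }
  if (trainPatients >= length(pat) || trainControls >= length(con))
    stop(sprintf(
      "insufficient subjects: %d patients / %d controls for training %d / %d",
      length(pat), length(con), trainPatients, trainControls))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sampleClass <- function(ids, k) {
    if (protocol == "M-CD" && !all(is.na(subjects$hasImaging))) {
      # preserve the with/without-imaging ratio in the training set
      has <- subjects$hasImaging[match(ids, subjects$subject)] %in% TRUE
      kImg <- round(k * sum(has) / length(ids))
      kImg <- min(max(kImg, k - sum(!has)), sum(has))
      c(sample(ids[has], kImg), sample(ids[!has], k - kImg))
    } else {
      sample(ids, k)
    }
  }
  splits <- lapply(seq_len(nSplits), function(s) {
    tr <- c(sampleClass(pat, trainPatients), sampleClass(con, trainControls))
    list(train = tr, test = setdiff(c(pat, con), tr))
  })
  structure(list(splits = splits, protocol = protocol,
                 trainPatients = trainPatients,
                 trainControls = trainControls, seed = seed),
            class = "SplitPlan")
}

#' Downsampling ensemble for imbalanced two-class data
#'
#' Trains `nDownsamples` classifiers, each on the full minority-class
#' training set plus an equal-size random draw of the majority class, and
#' combines them by majority voting. Per-member seeds derive from the
#' master seed.
#'
#' @param x n x m training feature matrix.
#' @param y class labels.
#' @param trainer function `(x, y, seed) -> model`; the model must be
#'   accepted by [gmlvqPredict()] (any [GMLVQModel-class] works).
#' @param nDownsamples ensemble size N_d (default 100).
#' @param seed master seed.
#' @return list of class `EnsembleClassifier` with `members`,
#'   `minorityClass`, `classLevels`.
#' @export
trainBalancedEnsemble <- function(x, y, trainer, nDownsamples = 100L,
                                  seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  lv <- sortedBinaryLevels(y)
  counts <- table(factor(y, levels = lv))
  minority <- lv[which.min(counts)]
  majority <- setdiff(lv, minority)
  if (counts[minority] > counts[majority]) {
    warning("minority class larger than majority; classes swapped")
    tmp <- minority; minority <- majority; majority <- tmp
  }
  minIdx <- which(y == minority)
  majIdx <- which(y == majority)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  memberSeeds <- sample.int(2147483646L, nDownsamples)
  members <- lapply(seq_len(nDownsamples), function(d) {
    set.seed(memberSeeds[d])
    majTake <- if (length(majIdx) == length(minIdx)) majIdx
      else sample(majIdx, length(minIdx))
    take <- c(minIdx, majTake)
    trainer(x[take, , drop = FALSE], y[take], memberSeeds[d])
  })
  structure(list(members = members, minorityClass = minority,
                 classLevels = lv, seed = seed),
            class = "EnsembleClassifier")
}

# per-member votes and winner distances for a matrix of inputs
ensembleVotes <- function(ens, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  preds <- lapply(ens$members, function(m) gmlvqPredict(m, x))
  list(
    labels = vapply(preds, function(p) p$label, character(nrow(x))),
    distances = vapply(preds, function(p) p$winnerDistance,
                       numeric(nrow(x)))
  )
}

#' Majority-vote prediction of a downsampling ensemble
#'
#' @param ens an [trainBalancedEnsemble()] result.
#' @param x feature matrix (or single vector).
#' @return character vector of predicted labels; vote ties go to the
#'   minority (patient) class.
#' @export
ensemblePredict <- function(ens, x) {
  v <- ensembleVotes(ens, x)
  labels <- matrix(v$labels, ncol = length(ens$members))
  apply(labels, 1, function(row) {
    tab <- table(factor(row, levels = ens$classLevels))
    if (length(unique(tab)) == 1 && length(tab) > 1) {
      ens$minorityClass
    } else {
      names(tab)[which.max(tab)]
    }
  })
}

# mean winner distance over members that voted the given label
claimDistance <- function(votes, row, label) {
  sel <- votes$labels[row, ] == label
  if (!any(sel)) return(Inf)
  mean(votes$distances[row, sel])
}

#' Combine two ensemble classifiers operating on the same inputs
#'
#' If both ensembles agree on a test point, their shared label is output.
#' On disagreement the label claimed with more confidence wins: for each
#' ensemble, the mean distance of the test input to the closest prototype
#' across the members voting its label is computed (member metrics are
#' trace-normalized, making distances comparable), and the smaller mean
#' distance decides. Equal means fall back to the first classifier's
#' label.
#'
#' @param c1,c2 [trainBalancedEnsemble()] results.
#' @param x feature matrix fed to `c1`.
#' @param x2 feature matrix fed to `c2` (defaults to `x`; differs when
#'   the two classifiers take different input representations of the same
#'   test subjects).
#' @return character vector of combined labels.
#' @export
combineTwoClassifiers <- function(c1, c2, x, x2 = x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(x2))) x2 <- matrix(x2, nrow = 1)
  if (nrow(x) != nrow(x2)) stop("x and x2 must describe the same test points")
  v1 <- ensembleVotes(c1, x)
  v2 <- ensembleVotes(c2, x2)
  p1 <- ensemblePredict(c1, x)
  p2 <- ensemblePredict(c2, x2)
  v1$labels <- matrix(v1$labels, ncol = length(c1$members))
  v2$labels <- matrix(v2$labels, ncol = length(c2$members))
  v1$distances <- matrix(v1$distances, ncol = length(c1$members))
  v2$distances <- matrix(v2$distances, ncol = length(c2$members))
  vapply(seq_len(nrow(x)), function(i) {
    if (p1[i] == p2[i]) return(p1[i])
    d1 <- claimDistance(v1, i, p1[i])
    d2 <- claimDistance(v2, i, p2[i])
    if (d1 <= d2) p1[i] else p2[i]
  }, character(1))
}

#' Confusion rates for a two-class problem
#'
#' Patients are the positive class. TPR = TP/(TP+FN), TNR = TN/(TN+FP),
#' FPR = FP/(FP+TN), FNR = FN/(FN+TP); TPR+FNR = 1 and TNR+FPR = 1 by
#' construction.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named list with the four rates and the counts.
#' @export
confusionRates <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative")
  if (tp + fn == 0 || tn + fp == 0)
    stop("rates undefined: a true class is empty")
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       tpr = tp / (tp + fn), tnr = tn / (tn + fp),
       fpr = fp / (fp + tn), fnr = fn / (fn + tp))
}

#' Macroaveraged mean absolute error
#'
#' The mean over classes of the class-conditional mean absolute label
#' error, with labels encoded 1..C in sorted order. For binary labels this
#' is the average of the two per-class error rates (one minus balanced
#' accuracy), which makes it robust to class imbalance: duplicating every
#' member of one class leaves it unchanged.
#'
#' @param trueLabels,predictedLabels label vectors over a shared finite
#'   label set; every true class must be non-empty.
#' @return scalar in \[0, C - 1\].
#' @export
macroMAE <- function(trueLabels, predictedLabels) {
  lv <- sort(unique(c(as.character(trueLabels), as.character(predictedLabels))))
  yt <- match(as.character(trueLabels), lv)
  yp <- match(as.character(predictedLabels), lv)
  classes <- seq_along(lv)
  if (!all(classes %in% yt))
    stop("empty true class: ", paste(lv[!classes %in% yt], collapse = ", "))
  mean(vapply(classes, function(c) mean(abs(yt[yt == c] - yp[yt == c])),
              numeric(1)))
}

#' Relative reduction of a median error
#'
#' 100 * (baseline - model) / baseline, the percentage by which a model's
#' median error undercuts the baseline's.
#'
#' @param baselineMedian positive baseline value.
#' @param modelMedian model value.
#' @return percentage (positive when the model improves).
#' @examples
#' relativeMedianReduction(0.3942, 0.2381) # 39.6
#' @export
relativeMedianReduction <- function(baselineMedian, modelMedian) {
  if (baselineMedian <= 0) stop("baseline median must be positive")
  100 * (baselineMedian - modelMedian) / baselineMedian
}

#' Paired comparison of per-split error distributions
#'
#' Two-sided paired Wilcoxon signed-rank test on per-split error values of
#' two models evaluated over identical splits.
#'
#' @param mmaeA,mmaeB equal-length numeric vectors (paired by split).
#' @return p-value; exactly 1 when all differences are zero.
#' @export
compareModels <- function(mmaeA, mmaeB) {
  if (length(mmaeA) != length(mmaeB))
    stop("paired samples must have equal length")
  d <- mmaeA - mmaeB
  if (all(d == 0)) return(1)
  suppressWarnings(wilcox.test(mmaeA, mmaeB, paired = TRUE)$p.value)
}

#' Summary statistics of per-split errors
#'
#' @param mmae numeric vector of per-split error values.
#' @return named vector: mean, sd, median, 25% and 75% percentiles.
#' @export
summarizeMMAE <- function(mmae) {
  c(mean = mean(mmae), sd = sd(mmae), median = median(mmae),
    q25 = as.numeric(quantile(mmae, 0.25)),
    q75 = as.numeric(quantile(mmae, 0.75)))
}
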