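#' Control parameters for privileged-information metric learning
#'
#' Percentile bounds and ITML settings for shaping the cognitive-space
#' metric with constraints derived from the privileged (imaging) space.
#' `aStar`/`bStar` are the lower/upper percentile bounds (in percent) of
#' the privileged-space distance distribution defining similar and
#' dissimilar pairs; `a`/`b` play the same role for the target distance
#' bounds l, u in the original space. The canonical tuning grid is
#' a, aStar in \{5, 10, 15\} and b, bStar in \{85, 90, 95\}.
#'
#' @param aStar,bStar lower/upper percentiles for the privileged space
#'   (percent, 0 < aStar < bStar < 100).
#' @param a,b lower/upper percentiles for the original-space distance
#'   bounds.
#' @param slack ITML slack parameter gamma (trade-off between staying
#'   close to the prior metric and satisfying constraints).
#' @param maxSweeps maximum cyclic-projection sweeps.
#' @param tol convergence threshold on the maximum constraint violation.
#' @return list of class `PIControl`.
#' @export
piControl <- function(aStar = 10, bStar = 90, a = 10, b = 90,
                      slack = 1, maxSweeps = 1000L, tol = 1e-3) {
  if (!(aStar > 0 && aStar < bStar && bStar < 100))
    stop("need 0 < aStar < bStar < 100")
  if (!(a > 0 && a < b && b < 100)) stop("need 0 < a < b < 100")
  if (slack <= 0) stop("slack must be positive")
  structure(list(aStar = aStar, bStar = bStar, a = a, b = b,
                 slack = slack, maxSweeps = as.integer(maxSweeps),
                 tol = tol),
            class = "PIControl")
}

pairwiseMahalanobis <- function(x, lambda) {
  x <- as.matrix(x)
  n <- nrow(x)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  d <- apply(pairs, 1, function(p) {
    v <- x[p[1], ] - x[p[2], ]
    as.numeric(t(v) %*% lambda %*% v)
  })
  list(pairs = unname(pairs), d = as.numeric(d))
}

#' Similarity constraint sets from the privileged space
#'
#' Computes all pairwise distances between privileged feature vectors
#' under the privileged-space metric tensor, derives distance thresholds
#' l* (the `aStar` percentile) and u* (the `bStar` percentile), and
#' assigns pairs to the similar set S+ (distance <= l* and same class
#' label) or the dissimilar set S- (distance >= u* and different class
#' label). Pairs meeting neither rule are unconstrained.
#'
#' @param privVectors n x p matrix of privileged features (in the units in
#'   which `lambdaStar` operates, typically z-scored).
#' @param labels class labels (length n).
#' @param lambdaStar positive semi-definite privileged-space metric.
#' @param config a [piControl()].
#' @return list of class `PairConstraintSets` with elements `sPlus`,
#'   `sMinus` (2-column index matrices, i < j), `lStar`, `uStar`,
#'   `aStar`, `bStar`.
#' @export
buildPairSets <- function(privVectors, labels, lambdaStar, config = piControl()) {
  privVectors <- as.matrix(privVectors)
  if (nrow(privVectors) < 2) stop("need at least 2 subjects")
  labels <- as.character(labels)
  pw <- pairwiseMahalanobis(privVectors, lambdaStar)
  lStar <- as.numeric(quantile(pw$d, config$aStar / 100))
  uStar <- as.numeric(quantile(pw$d, config$bStar / 100))
  if (uStar <= lStar && any(pw$d > 0))
    stop("u* <= l*; choose different percentile bounds")
  same <- labels[pw$pairs[, 1]] == labels[pw$pairs[, 2]]
  inPlus <- pw$d <= lStar & same
  inMinus <- pw$d >= uStar & !same & pw$d > lStar
  structure(list(
    sPlus = pw$pairs[inPlus, , drop = FALSE],
    sMinus = pw$pairs[inMinus, , drop = FALSE],
    lStar = lStar, uStar = uStar,
    aStar = config$aStar, bStar = config$bStar
  ), class = "PairConstraintSets")
}

#' Information-theoretic metric learning by Bregman projections
#'
#' Learns a positive semi-definite metric close (in LogDet divergence) to
#' a prior metric, subject to slack-relaxed pairwise distance constraints:
#' distances of similar pairs (S+) pushed below `l`, distances of
#' dissimilar pairs (S-) pushed above `u`. Solved by cyclic Bregman
#' projections onto the individual constraints (rank-one metric updates),
#' which keep the metric positive semi-definite by construction. With
#' empty constraint sets the prior is returned unchanged.
#'
#' @param x n x m matrix of original-space vectors (same scaling as the
#'   prior metric).
#' @param constraints a [buildPairSets()] result (indices into rows of
#'   `x`).
#' @param priorLambda positive definite prior metric.
#' @param l,u target distance bounds, l < u.
#' @param config a [piControl()] (slack, sweeps, tolerance).
#' @return positive semi-definite metric tensor of the same dimension.
#' @export
itmlFit <- function(x, constraints, priorLambda, l, u, config = piControl()) {
  x <- as.matrix(x)
  priorLambda <- as.matrix(priorLambda)
  ev <- eigen((priorLambda + t(priorLambda)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("prior metric must be positive semi-definite")
  if (l >= u) stop("need l < u")
  cons <- rbind(
    if (nrow(constraints$sPlus))
      cbind(constraints$sPlus, delta = 1, target = l),
    if (nrow(constraints$sMinus))
      cbind(constraints$sMinus, delta = -1, target = u)
  )
  if (is.null(cons) || nrow(cons) == 0) return(priorLambda)

  A <- (priorLambda + t(priorLambda)) / 2
  nc <- nrow(cons)
  lam <- numeric(nc)
  xi <- cons[, "target"]
  gamma <- config$slack
  best <- A
  bestViol <- Inf
  for (sweep in seq_len(config$maxSweeps)) {
    for (c in seq_len(nc)) {
      i <- cons[c, 1]; j <- cons[c, 2]
      delta <- cons[c, "delta"]
      v <- x[i, ] - x[j, ]
      p <- as.numeric(t(v) %*% A %*% v)
      if (p < .Machine$double.eps) next
      # Bregman projection onto one slack-relaxed constraint; gamma/(1+gamma)
      # interpolates between ignoring the constraint (gamma -> 0) and the
      # exact projection (gamma -> Inf)
      alpha <- min(lam[c], delta * gamma / (gamma + 1) * (1 / p - 1 / xi[c]))
      beta <- delta * alpha / (1 - delta * alpha * p)
      xi[c] <- gamma * xi[c] / (gamma + delta * alpha * xi[c])
      lam[c] <- lam[c] - alpha
      Av <- A %*% v
      A <- A + beta * tcrossprod(Av)
    }
    A <- (A + t(A)) / 2
    # violation against the slack-adjusted targets xi
    viol <- vapply(seq_len(nc), function(c) {
      v <- x[cons[c, 1], ] - x[cons[c, 2], ]
      d <- as.numeric(t(v) %*% A %*% v)
      if (cons[c, "delta"] > 0) max(0, d - xi[c]) else max(0, xi[c] - d)
    }, numeric(1))
    mv <- max(viol)
    if (mv < bestViol) {
      bestViol <- mv
      best <- A
    }
    if (mv < config$tol) return(A)
  }
  warning("ITML did not converge in ", config$maxSweeps,
          " sweeps (max violation ", signif(bestViol, 3),
          "); returning best iterate")
  best
}

scaleWithModel <- function(model, x) {
  sweep(sweep(as.matrix(x), 2, model@center), 2, model@scale, "/")
}

#' Train a privileged-information guided GMLVQ classifier
#'
#' Five-stage procedure for incorporating privileged features (available
#' for a subset of training subjects, absent at test time) into a GMLVQ
#' classifier operating on the original features:
#' \enumerate{
#'   \item train GMLVQ in the privileged space, yielding its metric
#'     Lambda*;
#'   \item train a baseline GMLVQ in the original space (metric Lambda,
#'     prototypes);
#'   \item derive similar/dissimilar pair sets from privileged-space
#'     distances under Lambda* ([buildPairSets()]);
#'   \item learn a new original-space metric by ITML with prior Lambda,
#'     with target bounds l, u set to the (`a`, `b`) percentiles of the
#'     original-space pairwise distances under Lambda ([itmlFit()]);
#'   \item fix the (trace-normalized) new metric and retrain prototypes
#'     only.
#' }
#' The returned model predicts from the original features alone.
#'
#' @param x n x m original feature matrix (all training subjects).
#' @param y class labels (length n).
#' @param xStar privileged feature matrix for a subset of subjects.
#' @param privIdx row indices of `x` to which the rows of `xStar`
#'   correspond.
#' @param config a [piControl()].
#' @param trainControl a [gmlvqControl()].
#' @return a [GMLVQModel-class] in the original feature space. The
#'   privileged-space model is attached as attribute
#'   `privilegedModel`.
#' @export
trainPIGMLVQ <- function(x, y, xStar, privIdx, config = piControl(),
                         trainControl = gmlvqControl()) {
  x <- as.matrix(x)
  xStar <- as.matrix(xStar)
  y <- as.character(y)
  if (nrow(xStar) != length(privIdx))
    stop("privIdx must align rows of xStar with rows of x")
  if (length(privIdx) == 0)
    stop("no subject has both modalities")
  yPriv <- y[privIdx]
  if (length(unique(yPriv)) < 2)
    stop("privileged subset must contain both classes")

  # stage 1: privileged-space metric
  mStar <- gmlvqTrain(xStar, yPriv, trainControl)
  lambdaStar <- metricTensor(mStar)

  # stage 2: baseline original-space model
  m0 <- gmlvqTrain(x, y, trainControl)
  lambda0 <- metricTensor(m0)

  # stage 3: pair sets from privileged proximity
  cs <- buildPairSets(scaleWithModel(mStar, xStar), yPriv, lambdaStar, config)
  cs$sPlus <- matrix(privIdx[cs$sPlus], ncol = 2)
  cs$sMinus <- matrix(privIdx[cs$sMinus], ncol = 2)

  # stage 4: ITML in the original space
  xs <- scaleWithModel(m0, x)
  d0 <- pairwiseMahalanobis(xs, lambda0)$d
  l <- as.numeric(quantile(d0, config$a / 100))
  u <- as.numeric(quantile(d0, config$b / 100))
  if (u <= l) u <- l + max(l, .Machine$double.eps)
  lambdaNew <- itmlFit(xs, cs, lambda0, l, u, config)

  # stage 5: prototype-only retraining under the new metric
  lambdaNew <- normalizeMetricTensor(lambdaNew)
  model <- gmlvqTrain(x, y, trainControl, omega = sqrtSPD(lambdaNew),
                      updateOmega = FALSE,
                      center = m0@center, scale = m0@scale)
  attr(model, "privilegedModel") <- mStar
  model
}

#' Tune percentile bounds by cross-validation on one split
#'
#' Grid search over the percentile bounds (a, a*) in `lowerGrid` and
#' (b, b*) in `upperGrid` for [trainPIGMLVQ()], scored by leave-group-out
#' cross-validation (macroaveraged MAE) on a single training set — the
#' protocol of tuning on the first sub-split only and freezing thereafter.
#'
#' @param x,y,xStar,privIdx as in [trainPIGMLVQ()].
#' @param trainControl a [gmlvqControl()].
#' @param lowerGrid,upperGrid candidate percentile values.
#' @param nFolds cross-validation folds.
#' @return the winning [piControl()].
#' @export
tunePercentileBounds <- function(x, y, xStar, privIdx,
                                 trainControl = gmlvqControl(),
                                 lowerGrid = c(5, 10, 15),
                                 upperGrid = c(85, 90, 95),
                                 nFolds = 3L) {
  x <- as.matrix(x)
  y <- as.character(y)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(trainControl$seed)
  folds <- makeStratifiedFolds(y, nFolds)
  best <- NULL
  bestScore <- Inf
  for (lo in lowerGrid) for (up in upperGrid) {
    cfg <- piControl(aStar = lo, bStar = up, a = lo, b = up)
    scores <- vapply(seq_len(nFolds), function(f) {
      tr <- which(folds != f)
      te <- which(folds == f)
      pIdx <- which(privIdx %in% tr)
      if (length(pIdx) < 2 || length(unique(y[te])) < 2 ||
          length(unique(y[privIdx[pIdx]])) < 2)
        return(NA_real_)
      mod <- tryCatch(
        trainPIGMLVQ(x[tr, , drop = FALSE], y[tr],
                     xStar[pIdx, , drop = FALSE],
                     match(privIdx[pIdx], tr), cfg, trainControl),
        error = function(e) NULL)
      if (is.null(mod)) return(NA_real_)
      macroMAE(y[te], gmlvqPredict(mod, x[te, , drop = FALSE])$label)
    }, numeric(1))
    sc <- mean(scores, na.rm = TRUE)
    if (is.finite(sc) && sc < bestScore) {
      bestScore <- sc
      best <- cfg
    }
  }
  if (is.null(best)) piControl() else best
}

makeStratifiedFolds <- function(y, nFolds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  folds
}
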