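regularizeScatter <- function(s) {
  d <- nrow(s)
  tr <- sum(diag(s))
  eps <- if (tr > 0) 1e-6 * tr / d else 1e-6
  s + diag(d) * eps
}

sortedBinaryLevels <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("exactly two classes required, got ", length(lv))
  lv
}

#' Fisher linear discriminant direction
#'
#' Fits the one-dimensional linear discriminant for two classes by
#' maximizing the Fisher criterion J(w) = (w' S_B w)/(w' S_W w), where S_B
#' is the between-class and S_W the total within-class scatter. The
#' closed-form maximizer is w proportional to S_W^{-1} (m2 - m1), with
#' S_W ridge-regularized for small-sample stability. The sign of w is
#' fixed so the projected mean of the second (alphabetically later) class
#' is the larger one.
#'
#' @param x numeric n x d matrix of feature vectors.
#' @param labels binary class labels (length n).
#' @return an [LDAProjection-class].
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
#' fitLDA(x, rep(c("a", "b"), each = 10))
#' @export
fitLDA <- function(x, labels) {
  x <- as.matrix(x)
  lv <- sortedBinaryLevels(labels)
  labels <- as.character(labels)
  x1 <- x[labels == lv[1], , drop = FALSE]
  x2 <- x[labels == lv[2], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  sw <- crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))
  swr <- regularizeScatter(sw)
  w <- tryCatch(solve(swr, m2 - m1),
                error = function(e) stop("within-class scatter singular after regularization"))
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    # identical class means: any direction has J = 0
    w <- c(1, rep(0, ncol(x) - 1))
  } else {
    w <- w / nw
  }
  if (sum(w * (m2 - m1)) < 0) w <- -w
  j <- as.numeric((sum(w * (m2 - m1)))^2 / (t(w) %*% swr %*% w))
  new("LDAProjection", w = as.numeric(w), fisherJ = max(j, 0), classLevels = lv)
}

#' @rdname fitLDA
#' @param proj an [LDAProjection-class]
#' @return `projectVectors`: numeric vector of projected features w' x.
#' @export
projectVectors <- function(proj, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(proj@w)) stop("dimension mismatch")
  as.numeric(x %*% proj@w)
}

#' Bilinear discriminant analysis on symmetric matrices (2D-LDA)
#'
#' Finds unit projection vectors a, b maximizing
#' \deqn{J(a, b) = \frac{(a' (M_2 - M_1) b)^2}
#'   {\sum_n (a' (X_n - M_{c(n)}) b)^2}}
#' over matrix-valued observations X_n with class means M_1, M_2 — the
#' between-class over within-class squared bilinear distances. The 2d free
#' parameters (vs d^2 for standard LDA on vectorized matrices) make the
#' fit feasible for small samples. Optimization alternates over a and b:
#' with one vector fixed, the objective is a generalized Rayleigh quotient
#' with a rank-one numerator, solved exactly in closed form, so J never
#' decreases. The extracted feature of a matrix X is `a' X b`.
#'
#' The bilinear form leaves a joint sign ambiguity; the fit flips the pair
#' so the mean feature of the second (alphabetically later) class is the
#' larger one, and pins the remaining (a,b) vs (-a,-b) ambiguity by making
#' the first nonzero component of a positive.
#'
#' @param matrices list of d x d symmetric matrices.
#' @param labels binary class labels.
#' @param tol relative tolerance on the change of J for convergence.
#' @param maxIter maximum number of alternating iterations.
#' @return a [TwoDLDAProjection-class].
#' @export
fit2DLDA <- function(matrices, labels, tol = 1e-8, maxIter = 100L) {
  lv <- sortedBinaryLevels(labels)
  labels <- as.character(labels)
  d <- nrow(matrices[[1]])
  for (m in matrices) {
    if (!isSymmetric(unname(as.matrix(m)), tol = 1e-8))
      stop("all input matrices must be symmetric")
    if (any(dim(m) != d)) stop("all input matrices must share dimensions")
  }
  M1 <- Reduce(`+`, matrices[labels == lv[1]]) / sum(labels == lv[1])
  M2 <- Reduce(`+`, matrices[labels == lv[2]]) / sum(labels == lv[2])
  Dm <- M2 - M1
  centered <- lapply(seq_along(matrices), function(n)
    matrices[[n]] - if (labels[n] == lv[1]) M1 else M2)
  if (max(vapply(centered, function(m) max(abs(m)), numeric(1))) < 1e-12 &&
      max(abs(Dm)) < 1e-12)
    stop("degenerate input: all matrices identical, J undefined")

  evalJ <- function(a, b) {
    db <- as.numeric(t(a) %*% Dm %*% b)^2
    dw <- sum(vapply(centered, function(m)
      as.numeric(t(a) %*% m %*% b)^2, numeric(1)))
    db / (dw + 1e-12 * max(db, 1))
  }
  solveStep <- function(fixed) {
    # maximize (v' mvec)^2 / (v' SW v): v = SW^{-1} mvec
    mvec <- Dm %*% fixed
    u <- matrix(vapply(centered, function(m) as.numeric(m %*% fixed),
                       numeric(d)), nrow = d)
    sw <- regularizeScatter(tcrossprod(u))
    v <- solve(sw, mvec)
    nv <- sqrt(sum(v^2))
    if (nv == 0) fixed else as.numeric(v / nv)
  }

  b <- rep(1, d) / sqrt(d)
  a <- solveStep(b)
  jTrace <- evalJ(a, b)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    b <- solveStep(a)
    a <- solveStep(b)
    j <- evalJ(a, b)
    jTrace <- c(jTrace, max(j, jTrace[length(jTrace)]))
    if (abs(j - jTrace[length(jTrace) - 1]) <=
        tol * max(abs(j), .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  # orient: mean feature of second class >= first class
  f1 <- as.numeric(t(a) %*% M1 %*% b)
  f2 <- as.numeric(t(a) %*% M2 %*% b)
  if (f2 < f1) b <- -b
  nz <- which(abs(a) > 1e-12)[1]
  if (!is.na(nz) && a[nz] < 0) {
    a <- -a
    b <- -b
  }
  new("TwoDLDAProjection", a = a, b = b, jTrace = jTrace,
      converged = converged, classLevels = lv)
}

#' Project matrices through a bilinear discriminant
#'
#' @param proj a [TwoDLDAProjection-class].
#' @param matrices list of d x d matrices (or a single matrix).
#' @return numeric vector of scalar features `a' X b`.
#' @export
projectGraphs <- function(proj, matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  d <- length(proj@a)
  vapply(matrices, function(m) {
    if (any(dim(m) != d)) stop("dimension mismatch: expected ", d, " x ", d)
    as.numeric(t(proj@a) %*% m %*% proj@b)
  }, numeric(1))
}

#' Edge importance matrix of a bilinear discriminant
#'
#' The symmetric matrix I = (a b' + b a')/2 derived from a fitted 2D-LDA
#' projection; its off-diagonal entries weigh how much each graph edge
#' contributes to the discriminative feature a' X b.
#'
#' @param proj a [TwoDLDAProjection-class].
#' @return symmetric d x d importance matrix.
#' @export
importanceMatrix <- function(proj) {
  (tcrossprod(proj@a, proj@b) + tcrossprod(proj@b, proj@a)) / 2
}
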