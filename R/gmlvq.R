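#' Adaptive Mahalanobis distance of GMLVQ
#'
#' The squared generalized distance d_Lambda(x, w) = (x - w)' Lambda
#' (x - w) under a positive semi-definite metric tensor Lambda.
#'
#' @param x,w numeric vectors of equal length.
#' @param lambda m x m positive semi-definite matrix.
#' @return non-negative scalar.
#' @examples
#' gmlvqDistance(c(1, 1), c(0, 0), matrix(c(1, .5, .5, 1), 2)) # 3
#' @export
gmlvqDistance <- function(x, w, lambda) {
  if (length(x) != length(w) || any(dim(lambda) != length(x)))
    stop("dimension mismatch between x, w and lambda")
  d <- x - w
  as.numeric(t(d) %*% lambda %*% d)
}

#' Relative distance cost of one sample
#'
#' mu = (d+ - d-)/(d+ + d-), where d+ is the distance to the closest
#' prototype of the sample's own class and d- to the closest prototype of
#' any other class. mu is in \[-1, 1\] and negative when the correct-class
#' prototype is closer; summed over samples (through a monotone link, here
#' the identity) it is the cost minimized during training.
#'
#' @param dPlus,dMinus non-negative distances.
#' @return scalar in \[-1, 1\].
#' @export
computeMu <- function(dPlus, dMinus) {
  if (dPlus < 0 || dMinus < 0) stop("distances must be non-negative")
  if (dPlus + dMinus == 0) {
    warning("both distances zero; mu defined as 0")
    return(0)
  }
  (dPlus - dMinus) / (dPlus + dMinus)
}

#' Training control parameters for GMLVQ
#'
#' @param lrPrototype prototype learning rate (start value).
#' @param lrOmega metric learning rate (start value; must not exceed
#'   `lrPrototype`).
#' @param epochs number of passes over the training set.
#' @param decayTo fraction of the initial learning rates reached (by
#'   linear decay) in the final epoch.
#' @param prototypeInitFraction fraction of each class's training points
#'   averaged for the initial prototype.
#' @param seed integer seed controlling prototype initialization and
#'   presentation order.
#' @return list of class `GMLVQControl`.
#' @export
gmlvqControl <- function(lrPrototype = 0.01, lrOmega = 0.001, epochs = 300L,
                         decayTo = 0.1, prototypeInitFraction = 0.5,
                         seed = 1L) {
  if (lrOmega > lrPrototype)
    stop("lrOmega must not exceed lrPrototype")
  if (prototypeInitFraction <= 0 || prototypeInitFraction > 1)
    stop("prototypeInitFraction must be in (0, 1]")
  structure(list(lrPrototype = lrPrototype, lrOmega = lrOmega,
                 epochs = as.integer(epochs), decayTo = decayTo,
                 prototypeInitFraction = prototypeInitFraction,
                 seed = as.integer(seed)),
            class = "GMLVQControl")
}

# matrix square root of an SPD matrix via eigen-decomposition
sqrtSPD <- function(lambda) {
  e <- eigen((lambda + t(lambda)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Train a GMLVQ classifier
#'
#' Online steepest-descent training of a Generalized Matrix LVQ model:
#' one prototype per class, a full adaptive metric tensor
#' Lambda = Omega' Omega, and per-sample updates of the winning correct
#' and incorrect prototypes and of Omega along the gradient of the
#' relative-distance cost [computeMu()]. Lambda is trace-normalized after
#' every learning step so its eigenvalues always sum to 1. Inputs are
#' z-scored internally with training-set statistics (stored in the model),
#' since features may carry heterogeneous units. Prototypes are
#' initialized as means of random class subsets.
#'
#' @param x numeric n x m feature matrix.
#' @param y class labels (length n, two or more classes, at least one
#'   example each).
#' @param control a [gmlvqControl()].
#' @param omega optional initial m x m Omega (default: identity scaled to
#'   unit-trace Lambda).
#' @param updateOmega if `FALSE` the metric is held fixed and only
#'   prototypes are trained (used when a metric learned elsewhere is
#'   imposed).
#' @param center,scale optional externally supplied z-scoring statistics;
#'   by default estimated from `x`.
#' @return a [GMLVQModel-class].
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' m <- gmlvqTrain(x, rep(c("a", "b"), each = 20),
#'                 gmlvqControl(epochs = 50))
#' table(gmlvqPredict(m, x)$label)
#' @export
gmlvqTrain <- function(x, y, control = gmlvqControl(), omega = NULL,
                       updateOmega = TRUE, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in training data")
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) < 2) stop("need at least two classes")
  counts <- table(factor(y, levels = lv))
  if (any(counts == 0)) stop("a class has no training examples")
  m <- ncol(x)
  featureNames <- colnames(x)
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(m))

  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(control$seed)

  yi <- match(y, lv)
  W <- t(vapply(seq_along(lv), function(k) {
    idx <- which(yi == k)
    take <- sample(idx, max(1L, ceiling(control$prototypeInitFraction *
                                          length(idx))))
    colMeans(xs[take, , drop = FALSE])
  }, numeric(m)))
  if (is.null(omega)) {
    omega <- diag(m) / sqrt(m)
  } else {
    omega <- as.matrix(omega)
    tr <- sum(diag(crossprod(omega)))
    if (tr <= 0) stop("initial omega must give a nonzero metric")
    omega <- omega / sqrt(tr)
  }

  n <- nrow(xs)
  order <- vapply(seq_len(control$epochs), function(e) sample.int(n),
                  integer(n))
  fit <- gmlvq_train_cpp(xs, yi, W, seq_along(lv), omega,
                         control$lrPrototype, control$lrOmega,
                         control$epochs, control$decayTo,
                         order, updateOmega)
  new("GMLVQModel",
      prototypes = fit$W, prototypeClasses = lv, omega = fit$Omega,
      featureNames = featureNames, center = as.numeric(center),
      scale = as.numeric(scale), classLevels = lv,
      costTrace = as.numeric(fit$cost))
}

#' Predict with a GMLVQ model
#'
#' Winner-takes-all classification: the label of the prototype closest to
#' the (z-scored) input under the model's metric tensor. Ties are broken
#' deterministically toward the smaller (sorted-first) class label, with a
#' warning.
#'
#' @param model a [GMLVQModel-class].
#' @param x numeric vector of length m or an n x m matrix.
#' @return data.frame with columns `label` and `winnerDistance` (distance
#'   to the winning prototype, usable as an inverse confidence).
#' @export
gmlvqPredict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  m <- ncol(model@prototypes)
  if (ncol(x) != m)
    stop("input has ", ncol(x), " features; model expects ", m)
  xs <- sweep(sweep(x, 2, model@center), 2, model@scale, "/")
  lam <- metricTensor(model)
  d <- vapply(seq_len(nrow(model@prototypes)), function(q) {
    dd <- sweep(xs, 2, model@prototypes[q, ])
    rowSums((dd %*% lam) * dd)
  }, numeric(nrow(xs)))
  d <- matrix(d, nrow = nrow(xs))
  winner <- apply(d, 1, which.min)
  tied <- apply(d, 1, function(r) sum(r == min(r)) > 1)
  if (any(tied))
    warning("equidistant prototypes for ", sum(tied),
            " input(s); tie broken toward the first class label")
  data.frame(
    label = model@prototypeClasses[winner],
    winnerDistance = d[cbind(seq_len(nrow(d)), winner)],
    stringsAsFactors = FALSE)
}

#' Normalize a metric tensor to unit eigenvalue sum
#'
#' Eigen-decomposes a symmetric positive semi-definite tensor and rescales
#' its eigenvalues to sum to 1, leaving the eigenvectors untouched. Used
#' to make winner distances comparable between independently trained
#' classifiers, whose metrics are otherwise only defined up to scale.
#'
#' @param lambda symmetric positive semi-definite matrix with positive
#'   trace.
#' @return matrix with the same eigenvectors and unit trace.
#' @examples
#' normalizeMetricTensor(diag(c(3, 1))) # diag(0.75, 0.25)
#' @export
normalizeMetricTensor <- function(lambda) {
  lambda <- as.matrix(lambda)
  if (!isSymmetric(unname(lambda), tol = 1e-8))
    stop("metric tensor must be symmetric")
  e <- eigen((lambda + t(lambda)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1)))
    stop("metric tensor must be positive semi-definite")
  s <- sum(e$values)
  if (s <= 0) stop("metric tensor has non-positive trace")
  e$vectors %*% ((e$values / s) * t(e$vectors))
}

#' Analytic gradients of the per-sample GMLVQ cost
#'
#' Gradients of mu = (d+ - d-)/(d+ + d-) with respect to the two winning
#' prototypes and Omega, used by the training loop; exposed for
#' verification against finite differences.
#'
#' @param x sample (z-scored feature units).
#' @param wPlus,wMinus winning correct/incorrect prototypes.
#' @param omega current Omega with Lambda = Omega' Omega.
#' @return list with `mu`, `gradWPlus`, `gradWMinus`, `gradOmega`.
#' @export
gmlvqGradients <- function(x, wPlus, wMinus, omega) {
  lam <- crossprod(omega)
  dp <- gmlvqDistance(x, wPlus, lam)
  dm <- gmlvqDistance(x, wMinus, lam)
  s <- dp + dm
  mu <- if (s == 0) 0 else (dp - dm) / s
  gp <- if (s == 0) 0 else 2 * dm / s^2   # d mu / d d+
  gm <- if (s == 0) 0 else -2 * dp / s^2  # d mu / d d-
  ep <- x - wPlus
  em <- x - wMinus
  list(
    mu = mu,
    gradWPlus = as.numeric(-2 * gp * lam %*% ep),
    gradWMinus = as.numeric(-2 * gm * lam %*% em),
    gradOmega = 2 * omega %*% (gp * tcrossprod(ep) + gm * tcrossprod(em))
  )
}
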