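#' @import methods
#' @importFrom stats as.dist cor cov cutree dist hclust kmeans quantile
#'   rnorm sd wilcox.test median setNames predict
#' @importFrom utils read.csv write.csv read.table write.table head
#' @useDynLib cognivq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ROI voxel time series
#'
#' Container for the BOLD signal of a single region of interest (ROI) in one
#' scanning session of one subject: a voxel-by-volume matrix together with
#' voxel positions and the partition of volumes into "structured" and
#' "random" stimulus conditions of the block design.
#'
#' @slot bold numeric matrix, V voxels x T volumes.
#' @slot coords numeric matrix, V x 3 voxel centre positions in mm.
#' @slot structuredIdx integer vector of volume indices acquired under the
#'   structured-sequence condition.
#' @slot randomIdx integer vector of volume indices acquired under the
#'   random-sequence condition.
#' @slot roi character, ROI name.
#' @slot session character, `"Pre"` or `"Post"` (before/after training).
#' @slot subject character, subject identifier.
#'
#' @seealso [ROITimeSeries()] for the validating constructor,
#'   [computePSC()], [computeGraphMatrix()].
#' @export
setClass("ROITimeSeries",
  representation(
    bold = "matrix",
    coords = "matrix",
    structuredIdx = "integer",
    randomIdx = "integer",
    roi = "character",
    session = "character",
    subject = "character"
  )
)

setValidity("ROITimeSeries", function(object) {
  msg <- character()
  V <- nrow(object@bold)
  T <- ncol(object@bold)
  if (!is.numeric(object@bold)) msg <- c(msg, "'bold' must be numeric")
  if (nrow(object@coords) != V || ncol(object@coords) != 3)
    msg <- c(msg, sprintf("'coords' must be %d x 3", V))
  is_ <- object@structuredIdx
  ir <- object@randomIdx
  if (length(intersect(is_, ir)) > 0)
    msg <- c(msg, "structured and random volume index sets overlap")
  if (length(is_) < 2 || length(ir) < 2)
    msg <- c(msg, "need at least 2 volumes per condition")
  if (any(c(is_, ir) < 1) || any(c(is_, ir) > T))
    msg <- c(msg, "volume indices out of range")
  if (!object@session %in% c("Pre", "Post"))
    msg <- c(msg, "session must be 'Pre' or 'Post'")
  if (length(msg)) msg else TRUE
})

#' Construct an ROITimeSeries
#'
#' @param bold numeric matrix, V voxels x T volumes.
#' @param coords numeric V x 3 matrix of voxel positions (mm).
#' @param structuredIdx volume indices of the structured condition.
#' @param randomIdx volume indices of the random condition.
#' @param roi,session,subject identifying tags; `session` is `"Pre"` or
#'   `"Post"`.
#' @param checkVariance if `TRUE` (default), reject voxels with zero
#'   temporal variance, naming the first offending voxel.
#' @return an [ROITimeSeries-class] object.
#' @examples
#' y <- matrix(rnorm(40), nrow = 2)
#' ts <- ROITimeSeries(y, matrix(0, 2, 3), 1:10, 11:20,
#'                     roi = "Frontal", session = "Pre", subject = "s1")
#' nVoxels(ts)
#' @export
ROITimeSeries <- function(bold, coords, structuredIdx, randomIdx,
                          roi = "ROI", session = "Pre", subject = "subject",
                          checkVariance = TRUE) {
  bold <- as.matrix(bold)
  if (checkVariance) {
    v <- apply(bold, 1, sd)
    if (any(v == 0))
      stop("voxel ", which(v == 0)[1], " has zero temporal variance")
  }
  new("ROITimeSeries",
    bold = bold, coords = as.matrix(coords),
    structuredIdx = as.integer(structuredIdx),
    randomIdx = as.integer(randomIdx),
    roi = as.character(roi), session = as.character(session),
    subject = as.character(subject))
}

#' @describeIn ROITimeSeries number of voxels
#' @param object an `ROITimeSeries`
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' @rdname ROITimeSeries
#' @export
setMethod("nVoxels", "ROITimeSeries", function(object) nrow(object@bold))

#' @describeIn ROITimeSeries number of volumes
#' @export
setGeneric("nVolumes", function(object) standardGeneric("nVolumes"))

#' @rdname ROITimeSeries
#' @export
setMethod("nVolumes", "ROITimeSeries", function(object) ncol(object@bold))

#' @describeIn ROITimeSeries the V x T BOLD matrix
#' @export
setGeneric("boldSignal", function(object) standardGeneric("boldSignal"))

#' @rdname ROITimeSeries
#' @export
setMethod("boldSignal", "ROITimeSeries", function(object) object@bold)

#' @describeIn ROITimeSeries the V x 3 voxel coordinates
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))

#' @rdname ROITimeSeries
#' @export
setMethod("voxelCoords", "ROITimeSeries", function(object) object@coords)

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf(
    "ROITimeSeries: subject %s, ROI %s, session %s\n  %d voxels x %d volumes (%d structured, %d random)\n",
    object@subject, object@roi, object@session,
    nrow(object@bold), ncol(object@bold),
    length(object@structuredIdx), length(object@randomIdx)))
})

#' Gaussian smoothing basis over voxel space
#'
#' A set of K Gaussian kernels in voxel-coordinate space used to reduce a
#' V x V voxel connectivity graph to a K x K matrix. Kernels arise either
#' from spatial k-means clustering of voxel positions ("spatial" grouping)
#' or from consensus clustering of per-subject functional clusterings
#' ("functional" grouping).
#'
#' @slot P numeric V x K matrix of kernel density evaluations at the voxel
#'   positions.
#' @slot centers K x 3 matrix of kernel centres (mm).
#' @slot covariances list of K 3 x 3 positive-definite kernel covariance
#'   matrices (mm^2).
#' @slot clusters integer vector of length V, cluster membership of each
#'   voxel.
#' @slot mode `"spatial"` or `"functional"`.
#' @seealso [buildSpatialBasis()], [buildFunctionalBasis()], [reduceGraph()]
#' @export
setClass("SmoothingBasis",
  representation(
    P = "matrix",
    centers = "matrix",
    covariances = "list",
    clusters = "integer",
    mode = "character"
  )
)

setValidity("SmoothingBasis", function(object) {
  msg <- character()
  K <- ncol(object@P)
  if (any(object@P < 0)) msg <- c(msg, "kernel evaluations must be non-negative")
  if (K >= nrow(object@P)) msg <- c(msg, "need K < V")
  if (nrow(object@centers) != K) msg <- c(msg, "centers must have K rows")
  if (length(object@covariances) != K) msg <- c(msg, "need K covariance matrices")
  if (!object@mode %in% c("spatial", "functional"))
    msg <- c(msg, "mode must be 'spatial' or 'functional'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SmoothingBasis number of kernels
#' @param object a `SmoothingBasis`
#' @export
setGeneric("nKernels", function(object) standardGeneric("nKernels"))

#' @rdname SmoothingBasis
#' @export
setMethod("nKernels", "SmoothingBasis", function(object) ncol(object@P))

#' @describeIn SmoothingBasis voxel cluster membership
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))

#' @rdname SmoothingBasis
#' @export
setMethod("clusterAssignments", "SmoothingBasis", function(object) object@clusters)

setMethod("show", "SmoothingBasis", function(object) {
  cat(sprintf("SmoothingBasis (%s grouping): %d kernels over %d voxels\n",
              object@mode, ncol(object@P), nrow(object@P)))
})

#' One-dimensional Fisher discriminant projection
#'
#' @slot w unit-norm projection vector.
#' @slot fisherJ achieved value of the Fisher criterion
#'   J(w) = (w' S_B w) / (w' S_W w).
#' @slot classLevels the two class labels, sorted; the sign of `w` is fixed
#'   so the projected mean of the second level is the larger one.
#' @seealso [fitLDA()]
#' @export
setClass("LDAProjection",
  representation(w = "numeric", fisherJ = "numeric", classLevels = "character"))

setValidity("LDAProjection", function(object) {
  if (abs(sqrt(sum(object@w^2)) - 1) > 1e-8) return("'w' must be unit norm")
  if (object@fisherJ < 0) return("Fisher criterion must be non-negative")
  TRUE
})

setMethod("show", "LDAProjection", function(object) {
  cat(sprintf("LDAProjection: d = %d, J = %.4g\n", length(object@w), object@fisherJ))
})

#' Bilinear (2D-LDA) discriminant projection for matrix-valued data
#'
#' Left/right unit projection vectors a, b maximizing the ratio of
#' between-class to within-class squared bilinear distances for symmetric
#' matrix inputs; the extracted scalar feature of a matrix X is a' X b.
#'
#' @slot a,b unit-norm projection vectors.
#' @slot jTrace value of the objective J(a, b) after each alternating
#'   iteration (non-decreasing).
#' @slot converged whether the relative change of J fell below tolerance.
#' @slot classLevels the two class labels, sorted; sign convention makes
#'   the second level's mean feature the larger one.
#' @seealso [fit2DLDA()], [projectGraphs()], [importanceMatrix()]
#' @export
setClass("TwoDLDAProjection",
  representation(a = "numeric", b = "numeric", jTrace = "numeric",
                 converged = "logical", classLevels = "character"))

setValidity("TwoDLDAProjection", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@a^2)) - 1) > 1e-8) msg <- c(msg, "'a' must be unit norm")
  if (abs(sqrt(sum(object@b^2)) - 1) > 1e-8) msg <- c(msg, "'b' must be unit norm")
  if (length(object@jTrace) > 1 &&
      any(diff(object@jTrace) < -1e-8 * max(abs(object@jTrace))))
    msg <- c(msg, "J trace must be non-decreasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TwoDLDAProjection", function(object) {
  cat(sprintf(
    "TwoDLDAProjection: d = %d, J = %.4g after %d iterations (%s)\n",
    length(object@a), object@jTrace[length(object@jTrace)],
    length(object@jTrace),
    if (object@converged) "converged" else "not converged"))
})

#' Generalized Matrix LVQ model
#'
#' A prototype-based classifier with an adaptive full metric tensor
#' Lambda = Omega' Omega. Distances between (z-scored) inputs and class
#' prototypes are squared Mahalanobis forms under Lambda; classification is
#' winner-takes-all. Lambda is kept trace-normalized (sum of its
#' eigenvalues equal to 1) throughout training, so its diagonal elements
#' are directly interpretable as feature relevances and its off-diagonal
#' elements as pairwise feature interplay.
#'
#' @slot prototypes L x m matrix of class prototypes (in z-scored feature
#'   units).
#' @slot prototypeClasses character vector of length L, class of each
#'   prototype.
#' @slot omega m x m matrix with Lambda = Omega' Omega.
#' @slot featureNames names of the m input features.
#' @slot center,scale per-feature z-scoring statistics estimated from the
#'   training set.
#' @slot classLevels sorted class labels.
#' @slot costTrace mean cost function value per training epoch.
#' @seealso [gmlvqTrain()], [gmlvqPredict()], [metricTensor()]
#' @export
setClass("GMLVQModel",
  representation(
    prototypes = "matrix",
    prototypeClasses = "character",
    omega = "matrix",
    featureNames = "character",
    center = "numeric",
    scale = "numeric",
    classLevels = "character",
    costTrace = "numeric"
  )
)

setValidity("GMLVQModel", function(object) {
  msg <- character()
  m <- ncol(object@prototypes)
  if (!all(dim(object@omega) == c(m, m)))
    msg <- c(msg, "'omega' must be m x m")
  lam <- crossprod(object@omega)
  if (abs(sum(diag(lam)) - 1) > 1e-6)
    msg <- c(msg, "metric tensor must be trace-normalized")
  if (!all(object@classLevels %in% object@prototypeClasses))
    msg <- c(msg, "every class needs at least one prototype")
  if (length(object@center) != m || length(object@scale) != m)
    msg <- c(msg, "scaler statistics must have length m")
  if (length(msg)) msg else TRUE
})

#' Extract the metric tensor of a GMLVQ model
#'
#' @param object a [GMLVQModel-class]
#' @return the m x m positive semi-definite matrix Lambda = Omega' Omega
#'   (unit trace).
#' @export
setGeneric("metricTensor", function(object) standardGeneric("metricTensor"))

#' @rdname metricTensor
#' @export
setMethod("metricTensor", "GMLVQModel", function(object) {
  lam <- crossprod(object@omega)
  lam <- (lam + t(lam)) / 2
  dimnames(lam) <- list(object@featureNames, object@featureNames)
  lam
})

#' @describeIn GMLVQModel prototype matrix (z-scored feature units)
#' @param object a `GMLVQModel`
#' @export
setGeneric("prototypes", function(object) standardGeneric("prototypes"))

#' @rdname GMLVQModel
#' @export
setMethod("prototypes", "GMLVQModel", function(object) {
  p <- object@prototypes
  rownames(p) <- object@prototypeClasses
  colnames(p) <- object@featureNames
  p
})

setMethod("show", "GMLVQModel", function(object) {
  rel <- diag(metricTensor(object))
  cat(sprintf("GMLVQModel: %d prototypes, %d features (classes: %s)\n",
              nrow(object@prototypes), ncol(object@prototypes),
              paste(object@classLevels, collapse = ", ")))
  cat("  diagonal relevances:",
      paste(sprintf("%s=%.3f", object@featureNames, rel), collapse = ", "),
      "\n")
})

#' @rdname gmlvqPredict
#' @param object a [GMLVQModel-class]
#' @param ... passed on to [gmlvqPredict()]
#' @export
setMethod("predict", "GMLVQModel", function(object, ...) gmlvqPredict(object, ...))
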