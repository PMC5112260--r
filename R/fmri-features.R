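#' Percent signal change of an ROI
#'
#' For every voxel, the difference between its mean BOLD response over the
#' structured-condition volumes and over the random-condition volumes is
#' scaled by the sum of the two condition means; the ROI value is the
#' average of the per-voxel terms:
#' \deqn{PSC = \frac{1}{V} \sum_v \frac{\bar y_v^{(s)} - \bar y_v^{(r)}}
#'   {\bar y_v^{(s)} + \bar y_v^{(r)}}.}
#'
#' The `"sum"` denominator (default) uses the sum of the two condition
#' means; `"mean"` divides by their average instead (a factor-2 variant
#' corresponding to scaling by the averaged response).
#'
#' @param ts an [ROITimeSeries-class], or a numeric V x T matrix (then
#'   `structuredIdx`/`randomIdx` must be given).
#' @param structuredIdx,randomIdx volume index sets (matrix input only).
#' @param denominator `"sum"` or `"mean"`.
#' @return a single numeric PSC value (unitless; 0.02 means 2%).
#' @examples
#' y <- rbind(c(4, 6, 2, 4))
#' computePSC(y, structuredIdx = 1:2, randomIdx = 3:4) # 0.25
#' @export
computePSC <- function(ts, structuredIdx = NULL, randomIdx = NULL,
                       denominator = c("sum", "mean")) {
  denominator <- match.arg(denominator)
  if (is(ts, "ROITimeSeries")) {
    y <- ts@bold
    structuredIdx <- ts@structuredIdx
    randomIdx <- ts@randomIdx
  } else {
    y <- as.matrix(ts)
    if (is.null(structuredIdx) || is.null(randomIdx))
      stop("matrix input requires structuredIdx and randomIdx")
  }
  ms <- rowMeans(y[, structuredIdx, drop = FALSE])
  mr <- rowMeans(y[, randomIdx, drop = FALSE])
  den <- ms + mr
  if (any(den == 0))
    stop("voxel ", which(den == 0)[1],
         " has zero summed condition means (division by zero)")
  if (denominator == "mean") den <- den / 2
  mean((ms - mr) / den)
}

#' Voxel connectivity graph matrix
#'
#' The V x V matrix of pairwise Pearson correlations between voxel time
#' series over all volumes: functional connectivity of the ROI. The
#' diagonal is exactly 1 and entries lie in \[-1, 1\].
#'
#' @param ts an [ROITimeSeries-class] or a numeric V x T matrix.
#' @return symmetric V x V correlation matrix.
#' @examples
#' computeGraphMatrix(rbind(c(1, 2, 3), c(1, 3, 2)))
#' @export
computeGraphMatrix <- function(ts) {
  y <- if (is(ts, "ROITimeSeries")) ts@bold else as.matrix(ts)
  v <- apply(y, 1, sd)
  if (any(v == 0))
    stop("voxel ", which(v == 0)[1], " has zero variance")
  g <- cor(t(y))
  g[g > 1] <- 1
  g[g < -1] <- -1
  g <- (g + t(g)) / 2
  diag(g) <- 1
  unname(g)
}

# kernel covariance from member voxel positions, ridge-regularized so that
# 2-voxel clusters (rank-deficient covariance) stay invertible
kernelCovariance <- function(pts) {
  if (nrow(pts) < 2) {
    return(diag(3))
  }
  s <- cov(pts)
  tr <- sum(diag(s))
  if (tr <= 0) return(diag(3))
  s + diag(3) * 1e-6 * tr / 3
}

gaussianDensity <- function(x, mu, sigma) {
  d <- sweep(x, 2, mu)
  ch <- chol(sigma)
  q <- rowSums((d %*% chol2inv(ch) * d))
  exp(-0.5 * q) / ((2 * pi)^(3 / 2) * prod(diag(ch)))
}

basisFromClusters <- function(coords, clusters, mode) {
  K <- max(clusters)
  centers <- t(vapply(seq_len(K), function(k)
    colMeans(coords[clusters == k, , drop = FALSE]), numeric(3)))
  covs <- lapply(seq_len(K), function(k)
    kernelCovariance(coords[clusters == k, , drop = FALSE]))
  P <- vapply(seq_len(K), function(k)
    gaussianDensity(coords, centers[k, ], covs[[k]]), numeric(nrow(coords)))
  new("SmoothingBasis", P = P, centers = centers, covariances = covs,
      clusters = as.integer(clusters), mode = mode)
}

#' Default kernel count for an ROI
#'
#' Calibrated to the three reference ROI sizes (32, 82 and 126 voxels
#' mapping to 3, 4 and 8 kernels): small ROIs get 3 kernels, mid-sized 4,
#' and large bi-hemispheric ROIs 8 (4 per hemisphere).
#'
#' @param nVoxels ROI size.
#' @return integer kernel count.
#' @export
kernelCountForROI <- function(nVoxels) {
  if (nVoxels >= 100) 8L else if (nVoxels >= 50) 4L else 3L
}

#' Spatially grouped smoothing basis
#'
#' Clusters voxel positions with k-means into K groups; each group defines
#' a Gaussian kernel with the cluster mean as centre and the (regularized)
#' within-cluster position covariance as shape. For bi-hemispheric ROIs,
#' `splitHemispheres = TRUE` clusters each hemisphere (sign of the x
#' coordinate) independently into K/2 groups.
#'
#' @param coords V x 3 voxel positions (mm).
#' @param K number of kernels (`K < V`); defaults to
#'   [kernelCountForROI()] of the ROI size.
#' @param seed integer seed for the k-means restarts.
#' @param splitHemispheres cluster hemispheres independently (requires
#'   even K).
#' @param nstart k-means restarts.
#' @return a [SmoothingBasis-class] with `mode = "spatial"`.
#' @export
buildSpatialBasis <- function(coords, K = kernelCountForROI(nrow(coords)),
                              seed = 1L, splitHemispheres = FALSE,
                              nstart = 50L) {
  coords <- as.matrix(coords)
  if (K < 1 || K >= nrow(coords)) stop("need 1 <= K < V")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  runKmeans <- function(x, k) {
    if (k == 1) return(rep(1L, nrow(x)))
    if (nrow(unique(x)) < k)
      stop("fewer distinct voxel positions than clusters; use smaller K")
    km <- suppressWarnings(kmeans(x, centers = k, nstart = nstart,
                                  iter.max = 100))
    if (any(km$size == 0)) stop("empty k-means cluster; use smaller K")
    km$cluster
  }
  if (splitHemispheres) {
    if (K %% 2 != 0) stop("splitHemispheres requires even K")
    left <- coords[, 1] < 0
    if (!any(left) || all(left))
      stop("hemisphere split requires voxels on both sides of x = 0")
    cl <- integer(nrow(coords))
    cl[left] <- runKmeans(coords[left, , drop = FALSE], K / 2)
    cl[!left] <- runKmeans(coords[!left, , drop = FALSE], K / 2) + K / 2
  } else {
    cl <- runKmeans(coords, K)
  }
  basisFromClusters(coords, cl, "spatial")
}

#' Functionally grouped smoothing basis via consensus clustering
#'
#' Each subject's voxels are clustered into K groups by average-linkage
#' hierarchical clustering of the connectivity dissimilarity 1 - G. The
#' per-subject groupings are merged through a co-association matrix (the
#' fraction of subjects placing a voxel pair in the same group), which is
#' itself clustered (average linkage on 1 - co-association) into K
#' consensus groups. Kernel centres/covariances come from the member voxel
#' positions of the consensus groups.
#'
#' @param cohortGraphs list of V x V graph matrices sharing voxel order
#'   (at least 2 subjects).
#' @param coords V x 3 voxel positions.
#' @param K number of consensus clusters.
#' @param seed kept for interface symmetry; the procedure is
#'   deterministic.
#' @return a [SmoothingBasis-class] with `mode = "functional"`.
#' @export
buildFunctionalBasis <- function(cohortGraphs, coords, K, seed = 1L) {
  if (length(cohortGraphs) < 2)
    stop("consensus clustering requires at least 2 subjects")
  coords <- as.matrix(coords)
  V <- nrow(coords)
  if (K >= V) stop("need K < V")
  if (any(vapply(cohortGraphs, function(g) any(dim(g) != V), logical(1))))
    stop("all graph matrices must share the voxel order of 'coords'")
  coassoc <- matrix(0, V, V)
  for (g in cohortGraphs) {
    cl <- cutree(hclust(as.dist(1 - g), method = "average"), k = K)
    coassoc <- coassoc + outer(cl, cl, "==")
  }
  coassoc <- coassoc / length(cohortGraphs)
  consensus <- cutree(hclust(as.dist(1 - coassoc), method = "average"), k = K)
  basisFromClusters(coords, consensus, "functional")
}

#' Reduce a graph matrix through a smoothing basis
#'
#' Congruence reduction of the V x V connectivity matrix G to the K x K
#' matrix `t(P) G P`, where P holds the kernel evaluations at the voxels.
#' Symmetry is preserved exactly.
#'
#' @param g V x V symmetric graph matrix.
#' @param basis a [SmoothingBasis-class] built on the same voxel order, or
#'   a V x K numeric matrix of kernel weights.
#' @return K x K symmetric matrix.
#' @examples
#' g <- matrix(c(1, 0.5, 0.5, 1), 2)
#' reduceGraph(g, matrix(1, 2, 1)) # 3
#' @export
reduceGraph <- function(g, basis) {
  P <- if (is(basis, "SmoothingBasis")) basis@P else as.matrix(basis)
  g <- as.matrix(g)
  if (nrow(g) != ncol(g)) stop("graph matrix must be square")
  if (nrow(P) != nrow(g))
    stop("basis voxel dimension (", nrow(P),
         ") does not match graph dimension (", nrow(g), ")")
  x <- crossprod(P, g %*% P)
  (x + t(x)) / 2
}

#' Assemble a per-subject feature table
#'
#' Collects one scalar feature per (subject, ROI, session) cell into a
#' subjects x 6 table with canonical column names
#' `<family>-<ROI>-<Pre|Post>`, ROIs in alphabetical order (Cerebellar,
#' Frontal, Subcortical for the reference set).
#'
#' @param values data.frame with columns `subject`, `roi`, `session`,
#'   `value`.
#' @param family feature family label (`"PSC"`, `"SGF"`, `"FGF"`, ...).
#' @return data.frame of features, one row per subject (rownames =
#'   subject ids).
#' @export
assembleFeatureTable <- function(values, family) {
  need <- c("subject", "roi", "session", "value")
  if (!all(need %in% names(values)))
    stop("'values' needs columns ", paste(need, collapse = ", "))
  key <- paste(values$subject, values$roi, values$session)
  if (anyDuplicated(key))
    stop("duplicate (subject, roi, session) cell: ", key[duplicated(key)][1])
  rois <- if (nrow(values)) sort(unique(values$roi))
    else c("Cerebellar", "Frontal", "Subcortical")
  sessions <- c("Pre", "Post")
  cols <- as.vector(t(outer(rois, sessions,
                            function(r, s) paste(family, r, s, sep = "-"))))
  subjects <- unique(values$subject)
  out <- matrix(NA_real_, length(subjects), length(cols),
                dimnames = list(subjects, cols))
  for (i in seq_len(nrow(values))) {
    cn <- paste(family, values$roi[i], values$session[i], sep = "-")
    out[values$subject[i], cn] <- values$value[i]
  }
  if (nrow(out) && any(is.na(out))) {
    bad <- which(is.na(out), arr.ind = TRUE)[1, ]
    stop("missing cell for subject ", subjects[bad[1]],
         ", column ", cols[bad[2]])
  }
  as.data.frame(out)
}
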