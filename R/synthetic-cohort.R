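#' Configuration of a synthetic two-class cohort
#'
#' Defines the statistical structure of a simulated patient/control cohort
#' with cognitive test scores for every subject and ROI voxel time series
#' (two sessions, several ROIs) for a subset. The defaults emulate the
#' structure of a memory-clinic study cohort: 13 patients and 47 controls
#' with four cognitive scores, 34 subjects (9 patients, 25 controls) with
#' additional imaging; patients score worse on divided attention (higher
#' `t_disp_d`), slightly worse on working memory (lower `n_dots`) and
#' inhibition (lower `t_delay`); training increases overall activation
#' (percent signal change) for patients only, while a planted
#' connectivity subnetwork differs between classes before training and is
#' attenuated after training.
#'
#' @param nPatients,nControls class sizes.
#' @param nWithImaging number of subjects with imaging data.
#' @param nImagingPatients how many of the imaging subjects are patients;
#'   the default reproduces the canonical 9/25 split when the cohort has
#'   the default size, otherwise imaging is split as evenly over classes
#'   as the class sizes permit.
#' @param cognitiveMeans 2 x 4 matrix of class-conditional means, rows
#'   `control` and `patient`, columns `n_dots` (dots), `t_delay`,
#'   `t_disp_d`, `t_disp_s` (ms).
#' @param cognitiveCov shared within-class 4 x 4 covariance matrix
#'   (symmetric positive definite).
#' @param roiSpecs data.frame with columns `roi`, `nVoxels`, `nKernels`.
#' @param nStructured,nRandom number of volumes per condition.
#' @param pscEffect data.frame with columns `class`, `session`, `roi`,
#'   `psc`: the percent-signal-change offset (unitless, e.g. 0.02 for 2%)
#'   planted for that cell.
#' @param plantedEdges data.frame with columns `class`, `session`, `roi`,
#'   `cluster1`, `cluster2`, `strength`: correlation in (-1, 1) planted
#'   between the latent signals of two voxel clusters.
#' @param clusterSignal standard deviation of the shared latent signal of
#'   each voxel cluster (BOLD units).
#' @param baseline baseline BOLD level.
#' @param noiseSd standard deviation of i.i.d. voxel noise.
#' @param seed integer master seed; all randomness in the generated cohort
#'   derives from it.
#' @return a list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nPatients = 5, nControls = 10, nWithImaging = 6)
#' cohort <- simulateCohort(cfg)
#' head(cohort$profiles)
#' @export
simulationConfig <- function(nPatients = 13, nControls = 47,
                             nWithImaging = 34, nImagingPatients = NULL,
                             cognitiveMeans = defaultCognitiveMeans(),
                             cognitiveCov = defaultCognitiveCov(),
                             roiSpecs = defaultRoiSpecs(),
                             nStructured = 30, nRandom = 30,
                             pscEffect = defaultPscEffect(roiSpecs),
                             plantedEdges = defaultPlantedEdges(),
                             clusterSignal = 2, baseline = 100,
                             noiseSd = 1.5, seed = 1L) {
  if (nWithImaging > nPatients + nControls)
    stop("nWithImaging cannot exceed the cohort size")
  if (is.null(nImagingPatients)) {
    nImagingPatients <- if (nPatients == 13 && nControls == 47 &&
                            nWithImaging == 34) {
      9L
    } else {
      min(nPatients, ceiling(nWithImaging / 2))
    }
  }
  if (nImagingPatients > nPatients ||
      nWithImaging - nImagingPatients > nControls)
    stop("imaging allocation exceeds class sizes")
  cognitiveCov <- as.matrix(cognitiveCov)
  if (!isSymmetric(unname(cognitiveCov), tol = 1e-10) ||
      inherits(try(chol(cognitiveCov), silent = TRUE), "try-error"))
    stop("cognitive covariance must be symmetric positive definite")
  if (nrow(pscEffect) && any(abs(pscEffect$psc) >= 1))
    stop("PSC offsets must lie in (-1, 1)")
  if (nrow(plantedEdges) && any(abs(plantedEdges$strength) >= 1))
    stop("planted correlation strengths must lie in (-1, 1)")
  if (any(roiSpecs$nKernels >= roiSpecs$nVoxels))
    stop("each ROI needs fewer kernels than voxels")
  if (noiseSd <= 0) stop("noiseSd must be positive")
  structure(list(
    nPatients = as.integer(nPatients), nControls = as.integer(nControls),
    nWithImaging = as.integer(nWithImaging),
    nImagingPatients = as.integer(nImagingPatients),
    cognitiveMeans = cognitiveMeans, cognitiveCov = cognitiveCov,
    roiSpecs = roiSpecs, nStructured = as.integer(nStructured),
    nRandom = as.integer(nRandom), pscEffect = pscEffect,
    plantedEdges = plantedEdges, clusterSignal = clusterSignal,
    baseline = baseline, noiseSd = noiseSd, seed = as.integer(seed)
  ), class = "SimulationConfig")
}

#' Names of the four cognitive score features
#'
#' Working memory (`n_dots`, dots), cognitive inhibition (`t_delay`, ms),
#' divided attention (`t_disp_d`, ms), selective attention (`t_disp_s`,
#' ms).
#'
#' @return character vector of length 4.
#' @export
cognitiveFeatureNames <- function() c("n_dots", "t_delay", "t_disp_d", "t_disp_s")

#' @rdname simulationConfig
#' @export
defaultCognitiveMeans <- function() {
  m <- rbind(
    control = c(n_dots = 5.2, t_delay = 230, t_disp_d = 62, t_disp_s = 62),
    patient = c(n_dots = 4.5, t_delay = 210, t_disp_d = 95, t_disp_s = 68)
  )
  m
}

#' @rdname simulationConfig
#' @export
defaultCognitiveCov <- function() {
  sds <- c(n_dots = 1.0, t_delay = 35, t_disp_d = 22, t_disp_s = 18)
  r <- diag(4)
  dimnames(r) <- list(names(sds), names(sds))
  # mild within-class correlations between memory/inhibition and the two
  # attention scores
  r["n_dots", "t_delay"] <- r["t_delay", "n_dots"] <- 0.3
  r["t_disp_d", "t_disp_s"] <- r["t_disp_s", "t_disp_d"] <- 0.3
  s <- diag(sds) %*% r %*% diag(sds)
  dimnames(s) <- dimnames(r)
  s
}

#' @rdname simulationConfig
#' @export
defaultRoiSpecs <- function() {
  data.frame(roi = c("Subcortical", "Cerebellar", "Frontal"),
             nVoxels = c(32L, 82L, 126L),
             nKernels = c(3L, 4L, 8L),
             stringsAsFactors = FALSE)
}

#' @rdname simulationConfig
#' @param roiSpecs ROI table used to enumerate (class, session, roi) cells.
#' @export
defaultPscEffect <- function(roiSpecs = defaultRoiSpecs()) {
  g <- expand.grid(class = c("control", "patient"),
                   session = c("Pre", "Post"),
                   roi = roiSpecs$roi,
                   stringsAsFactors = FALSE)
  # activation rises markedly after training for patients only
  g$psc <- ifelse(g$class == "patient" & g$session == "Post", 0.035, 0.01)
  g
}

#' @rdname simulationConfig
#' @export
defaultPlantedEdges <- function() {
  data.frame(
    class = c("patient", "control", "patient", "control"),
    session = c("Pre", "Pre", "Post", "Post"),
    roi = "Frontal",
    cluster1 = 1L, cluster2 = 2L,
    strength = c(0.7, 0.15, 0.45, 0.4),
    stringsAsFactors = FALSE
  )
}

# deterministic voxel layout for one ROI: K Gaussian blobs on a 3-D
# integer grid; identical for every subject and session so that graph
# matrices share voxel order
roiLayout <- function(config, roi) {
  spec <- config$roiSpecs[config$roiSpecs$roi == roi, ]
  if (nrow(spec) != 1) stop("unknown ROI: ", roi)
  V <- spec$nVoxels
  K <- spec$nKernels
  seed <- (config$seed + 7919L * match(roi, config$roiSpecs$roi)) %% 2147483647L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # blob centres: spread along x (split over hemispheres when K is even
  # and the ROI is large), staggered in y/z
  cx <- 14 * (seq_len(K) - (K + 1) / 2)
  cy <- 8 * (seq_len(K) %% 2)
  cz <- 6 * (seq_len(K) %/% 3)
  centres <- cbind(cx, cy, cz)
  sizes <- rep(V %/% K, K)
  if (V %% K > 0) sizes[seq_len(V %% K)] <- sizes[seq_len(V %% K)] + 1L
  cl <- rep(seq_len(K), times = sizes)
  coords <- centres[cl, , drop = FALSE] +
    matrix(round(rnorm(V * 3, sd = 2.5)), ncol = 3)
  colnames(coords) <- c("x", "y", "z")
  list(coords = coords, clusters = cl, K = K, V = V)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate cognitive test scores for a two-class cohort
#'
#' Draws `nPatients + nControls` four-dimensional cognitive profiles from
#' class-conditional multivariate Gaussians with shared within-class
#' covariance.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with columns `subject`, `group` (`"patient"` /
#'   `"control"`), the four scores, and `hasImaging` (filled by
#'   [simulateCohort()]; `NA` here).
#' @export
simulateCognitive <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  L <- chol(config$cognitiveCov)
  n <- config$nPatients + config$nControls
  group <- c(rep("patient", config$nPatients), rep("control", config$nControls))
  z <- matrix(rnorm(n * 4), ncol = 4)
  mu <- config$cognitiveMeans[group, , drop = FALSE]
  x <- mu + z %*% L
  colnames(x) <- cognitiveFeatureNames()
  out <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                    group = group, x, hasImaging = NA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate the ROI time series of one subject/session
#'
#' The voxels of the ROI are laid out as K spatial blobs (shared across
#' subjects). The BOLD signal of a voxel is
#' baseline + activation offset on structured volumes + the latent signal
#' of its blob + white noise. Planted between-cluster correlations are
#' induced by mixing the latent cluster signals; the activation offset is
#' calibrated so that the expected percent signal change equals the
#' configured `psc` value for the (class, session, roi) cell.
#'
#' @param config a [simulationConfig()].
#' @param subjectClass `"patient"` or `"control"`.
#' @param roi ROI name present in `config$roiSpecs`.
#' @param session `"Pre"` or `"Post"`.
#' @param seed integer seed for this subject/session draw.
#' @param subject subject identifier stored in the result.
#' @return an [ROITimeSeries-class].
#' @export
simulateROISession <- function(config, subjectClass, roi, session, seed,
                               subject = "subject") {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!roi %in% config$roiSpecs$roi) stop("unknown ROI: ", roi)
  if (!session %in% c("Pre", "Post")) stop("unknown session: ", session)
  if (!subjectClass %in% c("patient", "control"))
    stop("unknown class: ", subjectClass)
  layout <- roiLayout(config, roi)
  ns <- config$nStructured
  nr <- config$nRandom
  T <- ns + nr
  # block design: alternating blocks of 5 volumes, structured first
  lab <- blockConditionLabels(ns, nr)
  Is <- which(lab == "structured")
  Ir <- which(lab == "random")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647L)

  # latent cluster signals with planted cross-cluster correlation
  K <- layout$K
  Z <- matrix(rnorm(K * T), nrow = K)
  pe <- config$plantedEdges
  pe <- pe[pe$class == subjectClass & pe$session == session & pe$roi == roi, ,
           drop = FALSE]
  if (nrow(pe)) {
    for (e in seq_len(nrow(pe))) {
      k1 <- pe$cluster1[e]; k2 <- pe$cluster2[e]; rho <- pe$strength[e]
      if (max(k1, k2) > K) stop("planted edge refers to missing cluster")
      Z[k2, ] <- rho * Z[k1, ] + sqrt(1 - rho^2) * Z[k2, ]
    }
  }
  Z <- Z * config$clusterSignal

  # activation offset delta with PSC = delta / (2 baseline + delta) = p
  p <- config$pscEffect
  p <- p$psc[p$class == subjectClass & p$session == session & p$roi == roi]
  p <- if (length(p)) p[1] else 0
  delta <- 2 * config$baseline * p / (1 - p)

  act <- rep(0, T)
  act[Is] <- delta
  V <- layout$V
  bold <- matrix(config$baseline, V, T) +
    matrix(act, V, T, byrow = TRUE) +
    Z[layout$clusters, , drop = FALSE] +
    matrix(rnorm(V * T, sd = config$noiseSd), V, T)
  ROITimeSeries(bold, layout$coords, Is, Ir, roi = roi, session = session,
                subject = subject, checkVariance = FALSE)
}

#' @rdname simulateROISession
#' @param ns,nr volumes per condition
#' @export
blockConditionLabels <- function(ns, nr, blockLength = 5L) {
  lab <- character(0)
  left <- c(structured = ns, random = nr)
  cond <- "structured"
  while (sum(left) > 0) {
    take <- min(blockLength, left[cond])
    lab <- c(lab, rep(cond, take))
    left[cond] <- left[cond] - take
    other <- setdiff(c("structured", "random"), cond)
    if (left[other] > 0) cond <- other
  }
  lab
}

#' Simulate a full synthetic cohort
#'
#' Composes [simulateCognitive()] and [simulateROISession()]: every subject
#' receives a cognitive profile and `nWithImaging` subjects (allocated over
#' classes per the config) receive ROI time series for every ROI and both
#' sessions. All randomness derives from the single master seed through
#' per-subject substreams, so the same config yields a bit-identical
#' cohort.
#'
#' @param config a [simulationConfig()].
#' @return a list of class `SyntheticCohort` with elements
#'   \describe{
#'     \item{profiles}{cognitive score data.frame with `hasImaging` flag}
#'     \item{imaging}{nested list `imaging[[subject]][[roi]][[session]]` of
#'       [ROITimeSeries-class] objects}
#'     \item{truth}{record of planted effects: informative cognitive
#'       dimensions, PSC offsets, planted edges, per-ROI cluster truth}
#'     \item{config}{the generating config}
#'   }
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  profiles <- simulateCognitive(config)
  pat <- which(profiles$group == "patient")
  con <- which(profiles$group == "control")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  nIP <- config$nImagingPatients
  nIC <- config$nWithImaging - nIP
  imgIdx <- sort(c(pat[seq_len(nIP)], con[seq_len(nIC)]))
  profiles$hasImaging <- seq_len(nrow(profiles)) %in% imgIdx

  # per-(subject, roi, session) seeds drawn from one substream
  nCells <- length(imgIdx) * nrow(config$roiSpecs) * 2L
  cellSeeds <- sample.int(2147483646L, nCells)
  imaging <- list()
  cell <- 0L
  for (i in imgIdx) {
    sid <- profiles$subject[i]
    imaging[[sid]] <- list()
    for (roi in config$roiSpecs$roi) {
      imaging[[sid]][[roi]] <- list()
      for (session in c("Pre", "Post")) {
        cell <- cell + 1L
        imaging[[sid]][[roi]][[session]] <- simulateROISession(
          config, profiles$group[i], roi, session,
          seed = cellSeeds[cell], subject = sid)
      }
    }
  }

  meanDiff <- config$cognitiveMeans["patient", ] - config$cognitiveMeans["control", ]
  pooledSd <- sqrt(diag(config$cognitiveCov))
  truth <- list(
    informativeCognitive = cognitiveFeatureNames()[abs(meanDiff) / pooledSd ==
                                                     max(abs(meanDiff) / pooledSd)],
    cognitiveEffectSizes = meanDiff / pooledSd,
    pscEffect = config$pscEffect,
    plantedEdges = config$plantedEdges,
    clusterTruth = lapply(setNames(nm = config$roiSpecs$roi),
                          function(r) roiLayout(config, r)$clusters)
  )
  structure(list(profiles = profiles, imaging = imaging, truth = truth,
                 config = config),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf(
    "SyntheticCohort: %d subjects (%d patients, %d controls), %d with imaging\n",
    nrow(x$profiles), sum(x$profiles$group == "patient"),
    sum(x$profiles$group == "control"), sum(x$profiles$hasImaging)))
  invisible(x)
}

#' Write / read cohort cognitive scores as CSV
#'
#' The CSV has columns `subject_id, group, n_dots, t_delay, t_disp_d,
#' t_disp_s, has_imaging`.
#'
#' @param cohort a `SyntheticCohort` (or its `profiles` data.frame).
#' @param path output file.
#' @export
writeCognitiveCSV <- function(cohort, path) {
  p <- if (inherits(cohort, "SyntheticCohort")) cohort$profiles else cohort
  out <- data.frame(subject_id = p$subject, group = p$group,
                    p[cognitiveFeatureNames()],
                    has_imaging = p$hasImaging)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCognitiveCSV
#' @export
readCognitiveCSV <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", cognitiveFeatureNames())
  if (!all(need %in% names(x)))
    stop("missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  data.frame(subject = x$subject_id, group = x$group,
             x[cognitiveFeatureNames()],
             hasImaging = if ("has_imaging" %in% names(x)) x$has_imaging else NA,
             stringsAsFactors = FALSE)
}

#' Export one ROI time series bundle as plain-text TSV files
#'
#' Writes `<prefix>_bold.tsv` (V x T), `<prefix>_coords.tsv` (V x 3) and
#' `<prefix>_volumes.tsv` (volume_index, condition), a text
#' interoperability format mirroring the in-memory [ROITimeSeries-class].
#'
#' @param ts an [ROITimeSeries-class]
#' @param prefix path prefix for the three files.
#' @export
writeROITimeSeriesTSV <- function(ts, prefix) {
  write.table(boldSignal(ts), paste0(prefix, "_bold.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  write.table(voxelCoords(ts), paste0(prefix, "_coords.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  cond <- rep(NA_character_, nVolumes(ts))
  cond[ts@structuredIdx] <- "structured"
  cond[ts@randomIdx] <- "random"
  write.table(data.frame(volume_index = seq_along(cond), condition = cond),
              paste0(prefix, "_volumes.tsv"), sep = "\t", row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeROITimeSeriesTSV
#' @param roi,session,subject tags for the reconstructed object.
#' @export
readROITimeSeriesTSV <- function(prefix, roi = "ROI", session = "Pre",
                                 subject = "subject") {
  bold <- as.matrix(read.table(paste0(prefix, "_bold.tsv"), sep = "\t"))
  coords <- as.matrix(read.table(paste0(prefix, "_coords.tsv"), sep = "\t"))
  vols <- read.table(paste0(prefix, "_volumes.tsv"), sep = "\t", header = TRUE)
  ROITimeSeries(bold, coords,
                structuredIdx = vols$volume_index[vols$condition == "structured"],
                randomIdx = vols$volume_index[vols$condition == "random"],
                roi = roi, session = session, subject = subject)
}
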