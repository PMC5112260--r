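#' Pool metric tensors from reliable ensemble members
#'
#' Many members of a downsampling ensemble are trained on tiny samples and
#' may classify poorly; their metric tensors should not enter relevance
#' analysis. A data split is retained if and only if the `Nb`-th best
#' member of its ensemble (by error) has error at most `Emax`; all members
#' of retained splits are pooled.
#'
#' @param splitResults list with one element per split, each a list with
#'   `matrices` (list of per-member matrices: metric tensors or
#'   importance matrices) and `errors` (numeric per-member errors in
#'   \[0, 1\]; here the member's balanced training-set error, so no test
#'   data leaks into the selection).
#' @param Nb rank threshold (default 15).
#' @param Emax error threshold (default 0.25).
#' @return list of class `RelevanceSelection`: `matrices` (pooled),
#'   `retainedSplits`, `Nb`, `Emax`.
#' @export
selectReliableMembers <- function(splitResults, Nb = 15L, Emax = 0.25) {
  retained <- vapply(splitResults, function(s) {
    err <- s$errors
    if (any(err < 0 | err > 1, na.rm = TRUE))
      stop("member errors must lie in [0, 1]")
    if (Nb > length(err))
      stop("Nb (", Nb, ") exceeds ensemble size (", length(err), ")")
    sort(err)[Nb] <= Emax
  }, logical(1))
  mats <- unlist(lapply(splitResults[retained], `[[`, "matrices"),
                 recursive = FALSE)
  if (!any(retained))
    warning("no split passed the reliability filter; selection is empty")
  structure(list(matrices = mats, retainedSplits = which(retained),
                 Nb = as.integer(Nb), Emax = Emax),
            class = "RelevanceSelection")
}

#' Feature relevance histogram from pooled metric diagonals
#'
#' Pools the diagonal elements of all selected metric tensors, computes
#' their 90th percentile, and counts per feature how many of its diagonal
#' values strictly exceed that percentile. High counts mark features whose
#' relevance is repeatedly in the top decile.
#'
#' @param selection a [selectReliableMembers()] result (or any list with
#'   `matrices`).
#' @param probs percentile defining "top" relevance (default 0.9).
#' @return named integer vector of counts per feature.
#' @export
diagonalRelevanceHistogram <- function(selection, probs = 0.9) {
  mats <- selection$matrices
  if (length(mats) == 0) stop("empty selection")
  diags <- t(vapply(mats, diag, numeric(nrow(mats[[1]]))))
  thr <- as.numeric(quantile(as.numeric(diags), probs))
  counts <- colSums(diags > thr)
  nm <- colnames(mats[[1]])
  names(counts) <- if (!is.null(nm)) nm else paste0("f", seq_along(counts))
  counts
}

#' One-sided signed-rank tests on pooled off-diagonal metric elements
#'
#' For every feature pair (i, j), tests whether the pooled off-diagonal
#' metric elements Lambda_ij are significantly positive or significantly
#' negative (one-sided Wilcoxon signed-rank tests of the median against
#' zero). A significantly negative off-diagonal element indicates an
#' interplay that enhances class separation for negatively between-class
#' correlated feature pairs, and vice versa.
#'
#' @param selection a [selectReliableMembers()] result; needs at least 6
#'   pooled matrices.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `feature1`, `feature2`, `pPositive`,
#'   `pNegative`, `verdict` (`"positive"`, `"negative"` or `"none"`).
#' @export
offdiagonalSignTests <- function(selection, alpha = 0.05) {
  mats <- selection$matrices
  if (length(mats) < 6) stop("need at least 6 pooled matrices")
  m <- nrow(mats[[1]])
  nm <- colnames(mats[[1]])
  if (is.null(nm)) nm <- paste0("f", seq_len(m))
  out <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    s <- vapply(mats, function(x) x[i, j], numeric(1))
    if (all(s == s[1]) && s[1] == 0) {
      pp <- pn <- 1
    } else if (all(s == s[1])) {
      # constant nonzero sample: one-sided certainty by sign
      pp <- if (s[1] > 0) 0 else 1
      pn <- if (s[1] < 0) 0 else 1
    } else {
      pp <- suppressWarnings(wilcox.test(s, alternative = "greater")$p.value)
      pn <- suppressWarnings(wilcox.test(s, alternative = "less")$p.value)
    }
    verdict <- if (pp < alpha) "positive" else if (pn < alpha) "negative" else "none"
    out[[length(out) + 1]] <- data.frame(
      feature1 = nm[i], feature2 = nm[j],
      pPositive = pp, pNegative = pn, verdict = verdict,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Between-class correlation screen of cognitive features
#'
#' For each feature, one-sided two-sample rank-sum tests determine whether
#' patient values are significantly larger or smaller than control
#' values. For each feature pair, if both per-feature tests are
#' significant, the pair's between-class correlation is called positive
#' when the directions agree and negative when they oppose; otherwise
#' insignificant.
#'
#' @param profiles data.frame with a `group` column
#'   (`"patient"`/`"control"`) and numeric feature columns (by default the
#'   four cognitive scores).
#' @param alpha significance level.
#' @param features feature column names.
#' @return list with `featureTests` (per-feature direction and p-values)
#'   and `pairVerdicts` (per-pair verdict data.frame).
#' @export
betweenClassCorrelationScreen <- function(profiles, alpha = 0.05,
                                          features = cognitiveFeatureNames()) {
  pat <- profiles[profiles$group == "patient", , drop = FALSE]
  con <- profiles[profiles$group == "control", , drop = FALSE]
  if (nrow(pat) < 3 || nrow(con) < 3)
    stop("need at least 3 subjects per class")
  ft <- do.call(rbind, lapply(features, function(f) {
    pg <- suppressWarnings(
      wilcox.test(pat[[f]], con[[f]], alternative = "greater")$p.value)
    pl <- suppressWarnings(
      wilcox.test(pat[[f]], con[[f]], alternative = "less")$p.value)
    dir <- if (pg < alpha) 1L else if (pl < alpha) -1L else 0L
    data.frame(feature = f, pGreater = pg, pLess = pl, direction = dir,
               stringsAsFactors = FALSE)
  }))
  out <- list()
  for (i in seq_along(features)[-length(features)])
    for (j in (i + 1):length(features)) {
      di <- ft$direction[i]; dj <- ft$direction[j]
      verdict <- if (di != 0 && dj != 0) {
        if (di == dj) "positive" else "negative"
      } else "insignificant"
      out[[length(out) + 1]] <- data.frame(
        feature1 = features[i], feature2 = features[j], verdict = verdict,
        stringsAsFactors = FALSE)
    }
  list(featureTests = ft, pairVerdicts = do.call(rbind, out))
}

#' Pre/post shifts of edge importance
#'
#' For each edge (i, j) of the reduced connectivity graph, tests whether
#' pooled post-training importance values are significantly larger
#' ("increased") or smaller ("reduced") than the pre-training ones. When
#' the pre and post pools are matched member-by-member, paired one-sided
#' signed-rank tests are used; otherwise unpaired rank-sum tests.
#'
#' @param preSelection,postSelection [selectReliableMembers()] results
#'   holding importance matrices of the pre- and post-training sessions
#'   (matched node sets).
#' @param alpha significance level.
#' @return data.frame with columns `node1`, `node2`, `pIncreased`,
#'   `pReduced`, `verdict` (`"increased"`, `"reduced"`, `"none"`).
#' @export
edgeImportanceShift <- function(preSelection, postSelection, alpha = 0.05) {
  pre <- preSelection$matrices
  post <- postSelection$matrices
  if (length(pre) == 0 || length(post) == 0) stop("empty selection")
  k <- nrow(pre[[1]])
  if (nrow(post[[1]]) != k)
    stop("mismatched node sets: ", k, " vs ", nrow(post[[1]]))
  paired <- length(pre) == length(post)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sPre <- vapply(pre, function(x) x[i, j], numeric(1))
    sPost <- vapply(post, function(x) x[i, j], numeric(1))
    if (paired && all(sPost - sPre == 0)) {
      pi_ <- pr <- 1
    } else if (paired) {
      pi_ <- suppressWarnings(
        wilcox.test(sPost, sPre, paired = TRUE, alternative = "greater")$p.value)
      pr <- suppressWarnings(
        wilcox.test(sPost, sPre, paired = TRUE, alternative = "less")$p.value)
    } else {
      pi_ <- suppressWarnings(
        wilcox.test(sPost, sPre, alternative = "greater")$p.value)
      pr <- suppressWarnings(
        wilcox.test(sPost, sPre, alternative = "less")$p.value)
    }
    verdict <- if (pi_ < alpha) "increased" else if (pr < alpha) "reduced" else "none"
    out[[length(out) + 1]] <- data.frame(
      node1 = i, node2 = j, pIncreased = pi_, pReduced = pr,
      verdict = verdict, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
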