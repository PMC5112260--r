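# shared fixtures and independent oracles, built in code

# small cohort config: fast to simulate, keeps the canonical structure
smallSimConfig <- function(seed = 1L, ...) {
  simulationConfig(
    nPatients = 6, nControls = 14, nWithImaging = 10, nImagingPatients = 4,
    roiSpecs = data.frame(roi = c("Alpha", "Beta"),
                          nVoxels = c(20L, 30L), nKernels = c(3L, 4L)),
    seed = seed, ...)
}

quickControl <- function(seed = 1L, epochs = 100L) {
  gmlvqControl(epochs = epochs, seed = seed)
}

# brute-force Pearson correlation matrix (double loop, no cor())
bruteForceGraph <- function(y) {
  V <- nrow(y)
  g <- matrix(NA_real_, V, V)
  for (i in seq_len(V)) for (j in seq_len(V)) {
    yi <- y[i, ] - mean(y[i, ])
    yj <- y[j, ] - mean(y[j, ])
    g[i, j] <- sum(yi * yj) / sqrt(sum(yi^2) * sum(yj^2))
  }
  g
}

# brute-force maximizer of the Fisher criterion over directions in 2-D
bruteForceFisher <- function(x, labels, nAngles = 200000L) {
  lv <- sort(unique(labels))
  x1 <- x[labels == lv[1], , drop = FALSE]
  x2 <- x[labels == lv[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  sw <- crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2))
  sw <- sw + diag(2) * 1e-6 * sum(diag(sw)) / 2
  best <- -Inf
  for (th in seq(0, pi, length.out = nAngles)) {
    w <- c(cos(th), sin(th))
    j <- (sum(w * (m2 - m1)))^2 / as.numeric(t(w) %*% sw %*% w)
    if (j > best) best <- j
  }
  best
}

# exact one-sided signed-rank p-value by enumeration of sign assignments
# (no ties, no zeros; n <= 12)
exactSignedRankP <- function(x, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  stopifnot(n <= 12, all(x != 0), !anyDuplicated(abs(x)))
  r <- rank(abs(x))
  wObs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.numeric(signs %*% r)
  if (alternative == "greater") mean(w >= wObs) else mean(w <= wObs)
}

# symmetric random matrix cohort with an optional planted class offset
symMatCohort <- function(n, d, offset = NULL, sd = 0.3) {
  base <- function() {
    m <- matrix(rnorm(d * d, sd = sd), d)
    (m + t(m)) / 2
  }
  a <- lapply(seq_len(n), function(i) base())
  b <- lapply(seq_len(n), function(i) {
    m <- base()
    if (!is.null(offset)) m <- m + offset
    m
  })
  list(matrices = c(a, b), labels = rep(c("a", "b"), each = n))
}

centralDifference <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    e <- x * 0
    e[i] <- eps
    g[i] <- (f(x + e) - f(x - e)) / (2 * eps)
  }
  g
}
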