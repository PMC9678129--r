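# Independent brute-force oracles used to validate the implementation.
# These are written from the definitions, not from the package code paths.

# feature-wise knn imputation: for one missing cell, enumerate every other
# feature, compute Euclidean distance over mutually observed samples,
# average the k closest eligible neighbours (observed at the target sample)
oracleKnnImpute <- function(X, k) {
  out <- X
  p <- ncol(X)
  for (j in seq_len(p)) {
    for (i in which(is.na(X[, j]))) {
      cand <- data.frame(feat = integer(0), dist = numeric(0))
      for (l in seq_len(p)) {
        if (l == j || is.na(X[i, l])) next
        shared <- which(!is.na(X[, j]) & !is.na(X[, l]))
        if (!length(shared)) next
        cand <- rbind(cand, data.frame(
          feat = l, dist = sqrt(sum((X[shared, j] - X[shared, l])^2))))
      }
      if (!nrow(cand)) {
        out[i, j] <- mean(X[, j], na.rm = TRUE)
      } else {
        cand <- cand[order(cand$dist, cand$feat), ]
        nn <- cand$feat[seq_len(min(k, nrow(cand)))]
        out[i, j] <- mean(X[i, nn])
      }
    }
  }
  out
}

# Benjamini-Hochberg step-up from the definition: q_(i) = min over j >= i
# of p_(j) * m / j, capped at 1
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[o] <- pmin(adj, 1)
  q
}

# AUC as the exhaustive concordant-pair count (ties count 1/2)
oracleAuc <- function(x, y01) {
  cases <- x[y01 == 1]
  controls <- x[y01 == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# point-in-convex-polygon (ray casting on the hull vertices, CCW from chull)
inConvexHull <- function(pt, xy) {
  h <- grDevices::chull(xy)
  poly <- xy[h, , drop = FALSE]
  n <- nrow(poly)
  sgn <- 0
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[i %% n + 1, ]
    cr <- (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
    if (abs(cr) < 1e-12) next
    s <- sign(cr)
    if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
  }
  TRUE
}

# small two-class matrix with planted mean shifts in the first columns
toyClassData <- function(n0 = 10, n1 = 11, p = 20, nSignal = 2,
                         shift = 3, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm((n0 + n1) * p, sd = sd), n0 + n1, p)
    X[seq_len(n1) + n0, seq_len(nSignal)] <-
      X[seq_len(n1) + n0, seq_len(nSignal)] + shift
    colnames(X) <- paste0("f", seq_len(p))
    y <- factor(rep(c("control", "lame"), c(n0, n1)),
                levels = c("control", "lame"))
    list(X = X, y = y)
  })
}

# extract the day-8 cow matrix (samples x features) from a generated study
extractStudyMatrix <- function(study, intensityThreshold = 1e5,
                               ppmWindow = 5, maxMissing = 0.2, k = 10,
                               polarity = "positive") {
  rows <- which(study$samples$polarity == polarity)
  pls <- lapply(rows, function(i)
    thresholdPeaks(study$peakLists[[paste(study$samples$sample_id[i],
                                          polarity, sep = "_")]],
                   intensityThreshold))
  fm <- knnImpute(filterMissing(alignFeatures(pls, ppmWindow), maxMissing), k)
  t(SummarizedExperiment::assay(fm, "intensity"))
}
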