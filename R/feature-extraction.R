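#' Read a peak list from delimited text
#'
#' Expects two numeric columns (m/z, intensity), comma- or tab-separated,
#' with or without a header line. Rows are sorted by m/z; duplicate m/z
#' values are kept. Malformed rows raise an error naming the line; an empty
#' file yields an empty [PeakList-class] with a warning.
#'
#' @param path file path.
#' @param sampleId sample identifier to attach.
#' @param polarity `"positive"` or `"negative"`.
#' @param day extraction-day index.
#' @return A [PeakList-class].
#' @export
loadPeakList <- function(path, sampleId = basename(path),
                         polarity = "positive", day = 1L) {
  if (!file.exists(path)) stop("peak list file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  offset <- 0L
  if (length(lines)) {
    # a header line has no numeric field at all; a row with some numeric
    # fields but a malformed one is an error, not a header
    f1 <- strsplit(lines[1], "[,\t;]\\s*|\\s+")[[1]]
    if (all(is.na(suppressWarnings(as.numeric(f1))))) {
      lines <- lines[-1]
      offset <- 1L
    }
  }
  if (!length(lines)) {
    warning("empty peak list: ", path)
    return(PeakList(numeric(0), numeric(0), sampleId, polarity, day))
  }
  parts <- strsplit(lines, "[,\t;]\\s*|\\s+")
  mz <- numeric(length(lines))
  intensity <- numeric(length(lines))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:2]))
    if (length(parts[[i]]) < 2L || anyNA(v))
      stop("malformed peak-list row at line ", i + offset, " of ", path,
           ": '", lines[i], "'")
    mz[i] <- v[1]; intensity[i] <- v[2]
  }
  PeakList(mz, intensity, sampleId, polarity, day)
}

#' Read a centroided mzML spectrum as a peak list
#'
#' Thin optional reader (requires the mzR package): all spectra in the file
#' are averaged by pooling their centroided peaks, mirroring a one-minute
#' direct-infusion acquisition summarised as a single peak list.
#'
#' @inheritParams loadPeakList
#' @return A [PeakList-class].
#' @export
readMzmlPeaks <- function(path, sampleId = basename(path),
                          polarity = "positive", day = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("readMzmlPeaks() requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  pk <- mzR::peaks(h)
  if (!is.list(pk)) pk <- list(pk)
  m <- do.call(rbind, pk)
  PeakList(m[, 1], m[, 2], sampleId, polarity, day)
}

#' Intensity-threshold a peak list
#'
#' Retains peaks with intensity strictly greater than `minIntensity`
#' (default 100 000, the DIMS peak-picking floor).
#'
#' @param pl a [PeakList-class].
#' @param minIntensity non-negative threshold.
#' @return A filtered [PeakList-class].
#' @export
thresholdPeaks <- function(pl, minIntensity = 1e5) {
  stopifnot(is(pl, "PeakList"), minIntensity >= 0)
  keep <- pl@intensity > minIntensity
  PeakList(pl@mz[keep], pl@intensity[keep], pl@sampleId, pl@polarity, pl@day)
}

# split a pooled, m/z-sorted peak block at consecutive relative gaps larger
# than the window (ppm computed against the lower value); then verify every
# member against the intensity-weighted centroid and re-split recursively at
# the largest internal gap if any member deviates by more than the window
splitBlocks <- function(mz, ppmWindow) {
  n <- length(mz)
  if (n < 2L) return(rep(1L, n))
  gapPpm <- diff(mz) / mz[-n] * 1e6
  cumsum(c(1L, as.integer(gapPpm > ppmWindow)))
}

refineBlock <- function(mz, intensity, ppmWindow) {
  centroid <- sum(mz * intensity) / sum(intensity)
  if (all(abs(ppmDev(mz, centroid)) <= ppmWindow))
    return(list(list(idx = seq_along(mz), centroid = centroid)))
  cut <- which.max(diff(mz))
  left <- seq_len(cut)
  right <- seq(cut + 1L, length(mz))
  c(lapply(refineBlock(mz[left], intensity[left], ppmWindow),
           function(b) list(idx = left[b$idx], centroid = b$centroid)),
    lapply(refineBlock(mz[right], intensity[right], ppmWindow),
           function(b) list(idx = right[b$idx], centroid = b$centroid)))
}

#' Align peak lists into a feature matrix
#'
#' Pools all peaks across samples, sorts by m/z, splits at consecutive gaps
#' wider than `ppmWindow` (relative to the lower value), and refines each
#' block against its intensity-weighted centroid, re-splitting at the widest
#' internal gap until every member lies within the window of its centroid.
#' If a sample contributes several peaks to one feature, the most intense is
#' kept (and centroids are computed from the kept peaks). Cells are NA where
#' a sample contributed no peak.
#'
#' @param pls list of [PeakList-class], all of one polarity.
#' @param ppmWindow alignment window in ppm (default 5).
#' @return A [FeatureSet-class] with one column per input peak list.
#' @export
alignFeatures <- function(pls, ppmWindow = 5) {
  stopifnot(length(pls) >= 1L, ppmWindow > 0)
  pol <- unique(vapply(pls, function(p) p@polarity, character(1)))
  if (length(pol) != 1L)
    stop("all peak lists must share one polarity; got: ",
         paste(pol, collapse = ", "))
  ids <- vapply(pls, function(p) p@sampleId, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")

  mz <- unlist(lapply(pls, function(p) p@mz), use.names = FALSE)
  intensity <- unlist(lapply(pls, function(p) p@intensity), use.names = FALSE)
  src <- rep(seq_along(pls), vapply(pls, function(p) length(p@mz), integer(1)))
  if (!length(mz)) {
    m <- matrix(NA_real_, nrow = 0, ncol = length(pls),
                dimnames = list(NULL, ids))
    return(FeatureSet(m, numeric(0), character(0)))
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; src <- src[o]

  # gap-split, refine against intensity-weighted centroids, then keep one
  # peak per sample per feature (most intense), recompute centroids from the
  # kept peaks and re-refine any feature whose kept members now violate the
  # window (rare: dropping peaks can only move the centroid slightly)
  blocks <- splitBlocks(mz, ppmWindow)
  work <- lapply(unique(blocks), function(b) which(blocks == b))
  centroids <- numeric(0)
  members <- list()
  while (length(work)) {
    sel <- work[[1]]
    work <- work[-1]
    for (r in refineBlock(mz[sel], intensity[sel], ppmWindow)) {
      idx <- sel[r$idx]
      # per-sample dedup within this feature
      kept <- unlist(lapply(split(idx, src[idx]),
                            function(ss) ss[which.max(intensity[ss])]),
                     use.names = FALSE)
      kept <- sort(kept)
      cen <- sum(mz[kept] * intensity[kept]) / sum(intensity[kept])
      if (all(abs(ppmDev(mz[kept], cen)) <= ppmWindow)) {
        centroids <- c(centroids, cen)
        members[[length(members) + 1L]] <- kept
      } else {
        work[[length(work) + 1L]] <- kept
      }
    }
  }
  o <- order(centroids)
  centroids <- centroids[o]; members <- members[o]

  m <- matrix(NA_real_, nrow = length(centroids), ncol = length(pls),
              dimnames = list(NULL, ids))
  for (f in seq_along(members)) {
    idx <- members[[f]]
    m[f, src[idx]] <- intensity[idx]
  }
  FeatureSet(m, centroids, pol)
}

#' Drop features with excessive missingness
#'
#' Removes features whose missing fraction across all samples (QCs included)
#' is strictly greater than `maxMissingFrac`; a feature missing in exactly
#' that fraction is retained. Idempotent; feature order preserved.
#'
#' @param fs a [FeatureSet-class].
#' @param maxMissingFrac fraction in \[0, 1\] (default 0.2).
#' @return The filtered [FeatureSet-class].
#' @export
filterMissing <- function(fs, maxMissingFrac = 0.2) {
  stopifnot(is(fs, "FeatureSet"),
            maxMissingFrac >= 0, maxMissingFrac <= 1)
  frac <- rowMeans(SummarizedExperiment::assay(fs, "missing"))
  fs[frac <= maxMissingFrac, ]
}

# brute-force-simple feature-wise knn imputation core on a samples x
# features matrix; exported surface below works on FeatureSet too
knnImputeMatrix <- function(X, k = 10) {
  p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0))
    stop("feature(s) with zero observed values: ",
         paste(which(colSums(obs) == 0), collapse = ", "),
         " (filter before imputing)")
  out <- X
  featMeans <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(!obs) > 0)) {
    missRows <- which(!obs[, j])
    # distances from feature j to every other feature over mutually
    # observed samples
    d <- rep(NA_real_, p)
    for (l in seq_len(p)) {
      if (l == j) next
      shared <- obs[, j] & obs[, l]
      if (!any(shared)) next
      d[l] <- sqrt(sum((X[shared, j] - X[shared, l])^2))
    }
    for (i in missRows) {
      elig <- which(!is.na(d) & obs[i, ])
      if (!length(elig)) {
        out[i, j] <- featMeans[j]
        next
      }
      ord <- elig[order(d[elig], elig)]     # tie-break by feature order
      nn <- ord[seq_len(min(k, length(ord)))]
      out[i, j] <- mean(X[i, nn])
    }
  }
  out
}

#' k-nearest-neighbour imputation
#'
#' Imputes each missing cell as the unweighted mean of the k nearest
#' features (Euclidean distance computed over mutually observed samples),
#' restricted to features observed in the target sample; ties in distance
#' are broken by feature order. With fewer than k eligible neighbours all
#' available ones are used; with none, the feature's observed mean.
#'
#' @param fs a [FeatureSet-class] (or plain samples x features matrix).
#' @param k neighbour count (default 10).
#' @return Object of the same type with no missing values.
#' @export
knnImpute <- function(fs, k = 10) {
  stopifnot(k >= 1)
  if (is.matrix(fs)) return(knnImputeMatrix(fs, k))
  stopifnot(is(fs, "FeatureSet"))
  X <- knnImputeMatrix(t(SummarizedExperiment::assay(fs, "intensity")), k)
  out <- fs
  SummarizedExperiment::assay(out, "intensity") <- t(X)
  SummarizedExperiment::assay(out, "missing")[] <- FALSE
  validObject(out)
  out
}

#' Fuse positive- and negative-mode feature matrices
#'
#' Low-level data fusion: feature-wise concatenation of the two polarities'
#' matrices over an identical, identically ordered sample set. Feature
#' descriptors keep their polarity tags.
#'
#' @param pos,neg [FeatureSet-class] objects for the two polarities.
#' @return The fused [FeatureSet-class].
#' @export
fusePolarities <- function(pos, neg) {
  stopifnot(is(pos, "FeatureSet"), is(neg, "FeatureSet"))
  if (!identical(colnames(pos), colnames(neg))) {
    onlyP <- setdiff(colnames(pos), colnames(neg))
    onlyN <- setdiff(colnames(neg), colnames(pos))
    if (length(onlyP) || length(onlyN))
      stop("sample sets differ; only in positive: [",
           paste(onlyP, collapse = ", "), "], only in negative: [",
           paste(onlyN, collapse = ", "), "]")
    stop("sample order differs between polarities: ",
         paste(head(colnames(pos)), collapse = ", "), " vs ",
         paste(head(colnames(neg)), collapse = ", "))
  }
  if (nrow(neg) == 0L) return(pos)
  if (nrow(pos) == 0L) return(neg)
  ints <- rbind(SummarizedExperiment::assay(pos, "intensity"),
                SummarizedExperiment::assay(neg, "intensity"))
  rd <- rbind(SummarizedExperiment::rowData(pos),
              SummarizedExperiment::rowData(neg))
  rownames(ints) <- make.unique(c(rownames(pos), rownames(neg)), sep = "_")
  cd <- SummarizedExperiment::colData(pos)
  fused <- FeatureSet(ints, rd$mz, rd$polarity)
  SummarizedExperiment::colData(fused) <- cd
  fused
}

#' Write a feature matrix and its missingness mask as CSV
#'
#' The matrix file carries a two-row header (centroid m/z, polarity) above
#' the samples x features table; the mask file is the logical missingness
#' matrix.
#'
#' @param fs a [FeatureSet-class].
#' @param path output CSV path for the matrix; the mask is written next to
#'   it with suffix `_mask.csv`.
#' @return Invisibly, `path`.
#' @export
writeFeatureSet <- function(fs, path) {
  ints <- t(SummarizedExperiment::assay(fs, "intensity"))
  rd <- SummarizedExperiment::rowData(fs)
  con <- file(path, "w")
  writeLines(c(paste(c("mz", sprintf("%.5f", rd$mz)), collapse = ","),
               paste(c("polarity", rd$polarity), collapse = ",")), con)
  write.table(data.frame(sample = rownames(ints), ints,
                         check.names = FALSE),
              con, sep = ",", row.names = FALSE, col.names = FALSE,
              qmethod = "double")
  close(con)
  mask <- t(SummarizedExperiment::assay(fs, "missing"))
  write.csv(data.frame(sample = rownames(mask), mask, check.names = FALSE),
            sub("\\.csv$", "_mask.csv", path), row.names = FALSE)
  invisible(path)
}
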