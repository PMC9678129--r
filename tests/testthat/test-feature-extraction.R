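test_that("peak-list loading sorts, warns on empty files and errors on bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "100.1,2e5", "90.0,3e5"), f)
  pl <- loadPeakList(f)
  expect_equal(pl@mz, c(90.0, 100.1))
  expect_equal(pl@intensity, c(3e5, 2e5))

  writeLines(character(0), f)
  expect_warning(empty <- loadPeakList(f), "empty")
  expect_length(empty@mz, 0)

  writeLines(c("abc, 1", "100, 2"), f)
  expect_error(loadPeakList(f), "line 1")
})

test_that("intensity thresholding keeps strictly-above peaks only", {
  pl <- PeakList(c(200, 300), c(99999, 100001))
  kept <- thresholdPeaks(pl, 1e5)
  expect_equal(kept@mz, 300)
  expect_equal(kept@intensity, 100001)
  expect_length(thresholdPeaks(PeakList(numeric(0), numeric(0)), 1e5)@mz, 0)
  all_up <- PeakList(c(1, 2), c(2e5, 3e5))
  expect_equal(thresholdPeaks(all_up, 1e5)@mz, all_up@mz)
})

test_that("ppm alignment merges within-window peaks and splits across gaps", {
  mk <- function(mz, id) PeakList(mz, rep(1e6, length(mz)), id)
  # three samples, one identical peak each -> one feature everywhere
  fs <- alignFeatures(list(mk(500, "a"), mk(500, "b"), mk(500, "c")), 5)
  expect_equal(nrow(fs), 1)
  expect_equal(SummarizedExperiment::rowData(fs)$mz, 500)
  expect_false(any(SummarizedExperiment::assay(fs, "missing")))

  # 500.0000 and 500.0010 are ~2 ppm apart (merge); 500.0060 is ~10 ppm
  # beyond the second (split) -> exactly two features
  fs2 <- alignFeatures(list(mk(c(500.0000, 500.0060), "a"),
                            mk(500.0010, "b")), 5)
  expect_equal(nrow(fs2), 2)
  mz <- SummarizedExperiment::rowData(fs2)$mz
  expect_lt(abs(mz[1] - 500.0005), 0.0006)
  expect_equal(mz[2], 500.0060)

  # no peaks -> zero features
  expect_equal(nrow(alignFeatures(list(mk(numeric(0), "a")), 5)), 0)

  expect_error(alignFeatures(list(mk(100, "a"),
                                  PeakList(100, 1, "b", "negative")), 5),
               "polarity")
})

test_that("a sample contributing two peaks to a feature keeps the stronger", {
  a <- PeakList(c(500.0000, 500.0005), c(1e6, 3e6), "a")
  b <- PeakList(500.0002, 2e6, "b")
  fs <- alignFeatures(list(a, b), 5)
  expect_equal(nrow(fs), 1)
  expect_equal(unname(SummarizedExperiment::assay(fs, "intensity")[1, ]),
               c(3e6, 2e6))
})

test_that("aligned members stay within the window and centroids are a fixed point", {
  d <- studyDesign(nFeaturesPerPolarity = 60, ppmJitterSd = 1, seed = 13)
  st <- generateStudy(d, NULL)
  rows <- which(st$samples$polarity == "positive")
  pls <- lapply(rows, function(i)
    st$peakLists[[paste(st$samples$sample_id[i], "positive", sep = "_")]])
  fs <- alignFeatures(pls, 5)
  cent <- SummarizedExperiment::rowData(fs)$mz
  ints <- SummarizedExperiment::assay(fs, "intensity")
  # reassign every original peak to its nearest centroid: must land within
  # the window, and the intensity-weighted centroid of the assignment must
  # reproduce the stored centroid (fixed point)
  allMz <- unlist(lapply(pls, function(p) p@mz))
  allInt <- unlist(lapply(pls, function(p) p@intensity))
  nearest <- vapply(allMz, function(m) which.min(abs(cent - m)), integer(1))
  ppm <- (allMz - cent[nearest]) / cent[nearest] * 1e6
  expect_lt(max(abs(ppm)), 5 + 1e-9)
  recomputed <- vapply(seq_along(cent), function(f) {
    sel <- nearest == f
    sum(allMz[sel] * allInt[sel]) / sum(allInt[sel])
  }, numeric(1))
  expect_equal(recomputed, cent, tolerance = 1e-9)
})

test_that("jitter-free alignment recovers the generator's exact feature count", {
  d <- studyDesign(nFeaturesPerPolarity = 70, ppmJitterSd = 0,
                   missingParams = list(mid = 0, width = 1, maxRate = 0),
                   seed = 31)
  st <- generateStudy(d, NULL)
  rows <- which(st$samples$polarity == "negative")
  pls <- lapply(rows, function(i)
    st$peakLists[[paste(st$samples$sample_id[i], "negative", sep = "_")]])
  fs <- alignFeatures(pls, 5)
  expect_equal(nrow(fs), 70)
  expect_equal(SummarizedExperiment::rowData(fs)$mz,
               st$truth$featureMz[st$truth$featurePolarity == "negative"],
               tolerance = 1e-10)
})

test_that("missingness filter applies a strict >20% rule and is idempotent", {
  m <- matrix(1, nrow = 3, ncol = 48)
  m[1, 1:10] <- NA            # 20.8% missing -> dropped
  m[2, 1:9] <- NA             # 18.75% -> kept
  colnames(m) <- paste0("s", 1:48)
  fs <- FeatureSet(m, mz = c(100, 200, 300), polarity = "positive")
  filtered <- filterMissing(fs, 0.2)
  expect_equal(SummarizedExperiment::rowData(filtered)$mz, c(200, 300))

  # exactly 20% missing is retained
  m2 <- matrix(1, 1, 10); m2[1, 1:2] <- NA
  colnames(m2) <- paste0("s", 1:10)
  fs2 <- FeatureSet(m2, 100, "positive")
  expect_equal(nrow(filterMissing(fs2, 0.2)), 1)

  expect_identical(filterMissing(filtered, 0.2), filtered)
  expect_identical(nrow(filterMissing(fs, 1)), 3L)
})

test_that("knn imputation matches the brute-force oracle on a toy", {
  # 3 samples x 4 features, one missing cell, k = 2
  X <- rbind(c(1, 2, 10, 1.5), c(2, 3, 20, 2.4), c(3, NA, 30, 3.6))
  colnames(X) <- paste0("f", 1:4)
  imp <- knnImpute(X, k = 2)
  expect_false(anyNA(imp))
  expect_equal(imp, oracleKnnImpute(X, 2))

  # complete matrix unchanged
  Xc <- matrix(rnorm(12), 3, 4)
  expect_identical(knnImpute(Xc, 10), Xc)

  # k exceeding the candidate count -> mean over all other features
  X2 <- rbind(c(1, 4, 7), c(2, 5, 8), c(NA, 6, 9))
  expect_equal(knnImpute(X2, k = 10)[3, 1], mean(c(6, 9)))

  # a feature with no observed values should have been filtered upstream
  X3 <- cbind(c(NA, NA), c(1, 2))
  expect_error(knnImpute(X3, 2), "zero observed")
})

test_that("polarity fusion concatenates features over an identical sample set", {
  mkfs <- function(nf, pol, samples) {
    m <- matrix(seq_len(nf * length(samples)), nf, length(samples),
                dimnames = list(NULL, samples))
    FeatureSet(m, mz = seq_len(nf) * 100, polarity = pol)
  }
  pos <- mkfs(3, "positive", c("s1", "s2", "s3", "s4", "s5"))
  neg <- mkfs(2, "negative", c("s1", "s2", "s3", "s4", "s5"))
  fused <- fusePolarities(pos, neg)
  expect_equal(dim(fused), c(5L, 5L))
  expect_equal(SummarizedExperiment::rowData(fused)$polarity,
               c(rep("positive", 3), rep("negative", 2)))

  empty <- mkfs(0, "negative", c("s1", "s2", "s3", "s4", "s5"))
  expect_equal(nrow(fusePolarities(pos, empty)), 3)

  swapped <- mkfs(2, "negative", c("s2", "s1", "s3", "s4", "s5"))
  expect_error(fusePolarities(pos, swapped), "order")
  other <- mkfs(2, "negative", c("s1", "s2", "s3", "s4", "s9"))
  expect_error(fusePolarities(pos, other), "s9")
})
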