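#' @import methods
#' @importFrom stats sd var cor cov prcomp p.adjust t.test rnorm runif rlnorm
#'   plogis predict quantile setNames aggregate binomial coef glm
#' @importFrom utils read.csv write.csv head tail
NULL

#' Single-sample peak list
#'
#' One direct-infusion acquisition for one sample in one ionisation polarity:
#' parallel m/z and intensity vectors plus acquisition metadata. Peaks are
#' kept sorted by m/z.
#'
#' @slot sampleId single character identifier.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot day extraction-day index (integer, e.g. 8 or 16).
#' @slot mz numeric vector of m/z values (Th), strictly positive, ascending.
#' @slot intensity numeric vector of ion counts, non-negative, same length.
#'
#' @exportClass PeakList
setClass("PeakList",
  representation(
    sampleId = "character",
    polarity = "character",
    day = "integer",
    mz = "numeric",
    intensity = "numeric"
  )
)

setValidity("PeakList", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz)) {
    if (any(!is.finite(object@mz)) || any(object@mz <= 0))
      msg <- c(msg, "m/z values must be finite and strictly positive")
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      msg <- c(msg, "intensities must be finite and non-negative")
    if (is.unsorted(object@mz)) msg <- c(msg, "m/z must be ascending")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakList
#'
#' Peaks are sorted by m/z on construction; duplicate m/z values are kept.
#'
#' @param mz,intensity numeric vectors of equal length.
#' @param sampleId sample identifier.
#' @param polarity `"positive"` or `"negative"`.
#' @param day extraction-day index.
#' @return A [PeakList-class] object.
#' @export
PeakList <- function(mz, intensity, sampleId = "sample",
                     polarity = "positive", day = 1L) {
  o <- order(mz)
  new("PeakList", sampleId = as.character(sampleId), polarity = polarity,
      day = as.integer(day), mz = as.numeric(mz)[o],
      intensity = as.numeric(intensity)[o])
}

setMethod("show", "PeakList", function(object) {
  cat("PeakList:", object@sampleId, sprintf("(%s mode, day %d)\n",
      object@polarity, object@day))
  cat(" ", length(object@mz), "peaks")
  if (length(object@mz))
    cat(sprintf(", m/z %.4f-%.4f", min(object@mz), max(object@mz)))
  cat("\n")
})

#' Aligned feature matrix
#'
#' Samples-by-features container built on [SummarizedExperiment]: features are
#' rows (with centroid m/z and polarity in `rowData`), samples are columns.
#' Two assays: `intensity` (NA where a sample contributed no peak) and
#' `missing` (logical mask, `TRUE` exactly where intensity is NA).
#'
#' @exportClass FeatureSet
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("intensity", "missing") %in% an))
    return("assays 'intensity' and 'missing' are required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mz", "polarity") %in% colnames(rd)))
    return("rowData must contain 'mz' and 'polarity'")
  ints <- SummarizedExperiment::assay(object, "intensity")
  miss <- SummarizedExperiment::assay(object, "missing")
  if (!identical(dim(ints), dim(miss)))
    msg <- c(msg, "assay dimensions differ")
  else if (!identical(unname(is.na(ints)), unname(miss == TRUE)))
    msg <- c(msg, "missing mask must be TRUE exactly where intensity is NA")
  for (pol in unique(rd$polarity)) {
    if (is.unsorted(rd$mz[rd$polarity == pol]))
      msg <- c(msg, sprintf("centroid m/z not ascending within %s polarity", pol))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureSet
#'
#' @param intensity features x samples numeric matrix, NA for missing cells.
#' @param mz numeric centroid m/z per feature.
#' @param polarity character polarity per feature (recycled if length 1).
#' @param sampleData optional `data.frame` of per-sample metadata
#'   (rownames/order must match the columns of `intensity`).
#' @return A [FeatureSet-class].
#' @export
FeatureSet <- function(intensity, mz, polarity, sampleData = NULL) {
  intensity <- as.matrix(intensity)
  if (length(polarity) == 1L) polarity <- rep(polarity, nrow(intensity))
  stopifnot(length(mz) == nrow(intensity),
            length(polarity) == nrow(intensity))
  rd <- S4Vectors::DataFrame(mz = as.numeric(mz),
                             polarity = as.character(polarity))
  if (is.null(rownames(intensity)))
    rownames(intensity) <- make.unique(
      sprintf("%s_%.4f", substr(polarity, 1, 3), mz), sep = "_")
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(intensity))
  } else {
    S4Vectors::DataFrame(sampleData, row.names = colnames(intensity))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity, missing = is.na(intensity)),
    rowData = rd, colData = cd)
  new("FeatureSet", se)
}

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", ncol(object), "samples x", nrow(object), "features\n")
  pol <- table(SummarizedExperiment::rowData(object)$polarity)
  cat("  polarity:", paste(sprintf("%s=%d", names(pol), pol), collapse = ", "), "\n")
  m <- SummarizedExperiment::assay(object, "missing")
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(m)))
})

#' Study design for the synthetic dried-milk-spot generator
#'
#' Encodes the emulated study: lame and control cow counts, extraction days
#' with a global later-day signal attenuation, pooled QC samples, feature
#' counts per polarity, m/z range, ppm-scale mass jitter, log-normal
#' intensity parameters and intensity-dependent (MNAR) dropout.
#'
#' @slot nLame,nControl cows per class.
#' @slot extractionDays day indices (first day is the reference; later days
#'   are attenuated).
#' @slot nQcPerDay pooled QC acquisitions per day.
#' @slot nFeaturesPerPolarity true features simulated per polarity.
#' @slot mzRange numeric length-2, Th.
#' @slot dayAttenuation multiplicative factor in (0, 1] applied to
#'   intensities on days after the first.
#' @slot dayEffectSd per-feature spread (log scale) of the day effect
#'   around `log(dayAttenuation)`; storage loss is compound-dependent, and
#'   a purely global factor would be cancelled exactly by TIC
#'   normalisation.
#' @slot ppmJitterSd per-peak m/z jitter standard deviation, ppm.
#' @slot baseLogMean,baseLogSd natural-log scale location of feature mean
#'   intensities and per-observation residual sd.
#' @slot featureLogSd spread of per-feature mean log intensities.
#' @slot missingParams list with `mid`, `width`, `maxRate` of the logistic
#'   dropout curve in log intensity.
#' @slot qcDriftAmplitude,qcNoiseSd QC drift amplitude and multiplicative
#'   noise sd.
#' @slot seed integer RNG seed.
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(
    nLame = "integer", nControl = "integer",
    extractionDays = "numeric", nQcPerDay = "integer",
    nFeaturesPerPolarity = "integer", mzRange = "numeric",
    dayAttenuation = "numeric", dayEffectSd = "numeric",
    ppmJitterSd = "numeric",
    baseLogMean = "numeric", baseLogSd = "numeric", featureLogSd = "numeric",
    missingParams = "list",
    qcDriftAmplitude = "numeric", qcNoiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (object@nLame < 1L || object@nControl < 1L)
    msg <- c(msg, "need at least one cow per class")
  if (length(object@mzRange) != 2L || object@mzRange[1] >= object@mzRange[2])
    msg <- c(msg, "mzRange must be (low, high) with low < high")
  if (object@dayAttenuation <= 0 || object@dayAttenuation > 1)
    msg <- c(msg, "dayAttenuation must be in (0, 1]")
  if (object@ppmJitterSd < 0) msg <- c(msg, "ppmJitterSd must be >= 0")
  if (object@nQcPerDay < 0L) msg <- c(msg, "nQcPerDay must be >= 0")
  if (!all(c("mid", "width", "maxRate") %in% names(object@missingParams)))
    msg <- c(msg, "missingParams needs 'mid', 'width', 'maxRate'")
  bad <- vapply(object@missingParams, function(p) !is.finite(p), logical(1))
  if (any(bad)) msg <- c(msg, "missingParams must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDesign
#'
#' Defaults emulate the dried-milk-spot lameness study: 10 lame + 11 control
#' cows, extraction days 8 and 16 with a global day-16 attenuation, 3 pooled
#' QC runs per day, m/z 70-1050, ppm-scale jitter, log-normal intensities and
#' logistic intensity-dependent dropout.
#'
#' @param nLame,nControl cows per class.
#' @param extractionDays extraction day indices.
#' @param nQcPerDay pooled QC acquisitions per day.
#' @param nFeaturesPerPolarity simulated features per polarity.
#' @param mzRange m/z range (Th).
#' @param dayAttenuation factor in (0,1] multiplying later-day intensities.
#' @param dayEffectSd per-feature log-scale spread of the day effect.
#' @param ppmJitterSd m/z jitter sd in ppm.
#' @param baseLogMean,baseLogSd,featureLogSd log-normal intensity parameters.
#' @param missingParams logistic dropout parameters (`mid`, `width`,
#'   `maxRate`): dropout probability is
#'   `maxRate * plogis(-(log(I) - mid)/width)`.
#' @param qcDriftAmplitude,qcNoiseSd QC drift and noise.
#' @param seed RNG seed.
#' @return A [StudyDesign-class].
#' @export
studyDesign <- function(nLame = 10, nControl = 11,
                        extractionDays = c(8, 16), nQcPerDay = 3,
                        nFeaturesPerPolarity = 500,
                        mzRange = c(70, 1050),
                        dayAttenuation = 0.7, dayEffectSd = 0.3,
                        ppmJitterSd = 1,
                        baseLogMean = log(8e5), baseLogSd = 0.4,
                        featureLogSd = 1.2,
                        missingParams = list(mid = log(1.5e5), width = 0.6,
                                             maxRate = 0.4),
                        qcDriftAmplitude = 0.05, qcNoiseSd = 0.02,
                        seed = 1L) {
  new("StudyDesign",
      nLame = as.integer(nLame), nControl = as.integer(nControl),
      extractionDays = as.numeric(extractionDays),
      nQcPerDay = as.integer(nQcPerDay),
      nFeaturesPerPolarity = as.integer(nFeaturesPerPolarity),
      mzRange = as.numeric(mzRange),
      dayAttenuation = dayAttenuation, dayEffectSd = dayEffectSd,
      ppmJitterSd = ppmJitterSd,
      baseLogMean = baseLogMean, baseLogSd = baseLogSd,
      featureLogSd = featureLogSd, missingParams = missingParams,
      qcDriftAmplitude = qcDriftAmplitude, qcNoiseSd = qcNoiseSd,
      seed = as.integer(seed))
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nLame, "lame +", object@nControl, "control cows,",
      length(object@extractionDays), "extraction days,",
      object@nQcPerDay, "QC/day\n")
  cat(" ", object@nFeaturesPerPolarity, "features/polarity, m/z",
      paste(object@mzRange, collapse = "-"),
      sprintf("; day attenuation %.2f, jitter %.2g ppm, seed %d\n",
              object@dayAttenuation, object@ppmJitterSd, object@seed))
})

#' OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary outcome: one (or more) predictive component correlated with class
#' plus orthogonal components capturing class-uncorrelated structured
#' variation. Carries scores, loadings, weights, fit statistics, VIP scores
#' and S-plot statistics.
#'
#' @slot nPredictive,nOrthogonal component counts.
#' @slot scores,loadings,weights predictive t, p, w (columns = components).
#' @slot orthoScores,orthoLoadings,orthoWeights orthogonal t_o, p_o, w_o.
#' @slot yCoef regression coefficient(s) c of y on the predictive score(s).
#' @slot xMeans,yMean centring statistics.
#' @slot R2X,R2Y fractions of X / y sum of squares explained.
#' @slot vip per-feature variable importance in projection (predictive
#'   components only; mean squared VIP = 1).
#' @slot splotCov,splotCorr S-plot covariance/correlation of each centred
#'   feature with the predictive score.
#' @slot levels class labels; first level is coded 0 (control side).
#' @slot fitted fitted numeric y-hat on the training data.
#' @exportClass OplsModel
setClass("OplsModel",
  representation(
    nPredictive = "integer", nOrthogonal = "integer",
    scores = "matrix", loadings = "matrix", weights = "matrix",
    orthoScores = "matrix", orthoLoadings = "matrix", orthoWeights = "matrix",
    yCoef = "numeric", xMeans = "numeric", yMean = "numeric",
    R2X = "numeric", R2Y = "numeric",
    vip = "numeric", splotCov = "numeric", splotCorr = "numeric",
    levels = "character", fitted = "numeric"
  )
)

setMethod("show", "OplsModel", function(object) {
  cat(sprintf("OPLS-DA model (A = %d predictive + %d orthogonal)\n",
              object@nPredictive, object@nOrthogonal))
  cat(sprintf("  N = %d, features = %d\n",
              nrow(object@scores), length(object@vip)))
  cat(sprintf("  R2X %.3f  R2Y %.3f\n", object@R2X, object@R2Y))
  cat("  classes:", paste(object@levels, collapse = " vs "),
      "(first level coded 0)\n")
})

#' Bootstrap stability-selection result
#'
#' Per-feature selection frequencies across bootstrap refits of a penalised
#' binary-outcome model, the signed coefficient record underlying the
#' sign-based bootstrap p-values, and (once computed) the permutation-derived
#' stability threshold.
#'
#' @slot penalty `"elastic_net"`, `"lasso"` or `"mcp"`.
#' @slot featureNames feature identifiers (columns of X).
#' @slot coefRecord nBootstraps x features matrix of fitted coefficients
#'   (0 = not selected in that resample).
#' @slot selectionCount per-feature number of resamples with non-zero
#'   coefficient.
#' @slot stabilityScore per-feature selection percentage in \[0, 100\].
#' @slot bootstrapP per-feature minority-side-of-zero proportion (NA when a
#'   feature was never selected).
#' @slot threshold permutation-derived stability threshold (%; NA until
#'   [permutationThreshold()] has been run and attached).
#' @slot nBootstraps,nPermutations,nPermutationBootstraps resampling counts.
#' @exportClass StabilityResult
setClass("StabilityResult",
  representation(
    penalty = "character", featureNames = "character",
    coefRecord = "matrix", selectionCount = "integer",
    stabilityScore = "numeric", bootstrapP = "numeric",
    threshold = "numeric",
    nBootstraps = "integer", nPermutations = "integer",
    nPermutationBootstraps = "integer"
  )
)

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult (%s): %d features, %d bootstraps\n",
              object@penalty, length(object@featureNames),
              object@nBootstraps))
  cat(sprintf("  threshold: %s%%\n",
              ifelse(is.na(object@threshold), "not computed",
                     format(object@threshold, digits = 3))))
  n <- sum(object@stabilityScore > 0)
  cat(" ", n, "features selected at least once; top score",
      sprintf("%.1f%%\n", max(object@stabilityScore, 0)))
})

#' Recursive feature-elimination curve
#'
#' LOOCV accuracy as a function of retained feature-subset size, with the
#' best (smallest maximising) size and the corresponding subset from a
#' full-data elimination pass.
#'
#' @slot modelKind one of the four classifier kinds.
#' @slot sizes descending subset sizes.
#' @slot accuracy LOOCV accuracy per size.
#' @slot bestSize smallest size attaining the maximum accuracy.
#' @slot bestSubset feature names retained at `bestSize`.
#' @exportClass RfeCurve
setClass("RfeCurve",
  representation(modelKind = "character", sizes = "integer",
                 accuracy = "numeric", bestSize = "integer",
                 bestSubset = "character")
)

setValidity("RfeCurve", function(object) {
  msg <- character()
  if (length(object@sizes) != length(object@accuracy))
    msg <- c(msg, "sizes and accuracy lengths differ")
  if (any(diff(object@sizes) >= 0)) msg <- c(msg, "sizes must be strictly decreasing")
  if (any(object@accuracy < 0 | object@accuracy > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RfeCurve", function(object) {
  cat(sprintf("RFE curve (%s): %d subset sizes from %d to %d\n",
              object@modelKind, length(object@sizes), max(object@sizes),
              min(object@sizes)))
  cat(sprintf("  best: %.1f%% LOOCV accuracy with %d features\n",
              100 * max(object@accuracy), object@bestSize))
})
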