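#' Specify a planted discriminative effect
#'
#' Describes one feature whose intensity differs between lame and control
#' cows in the synthetic generator. Feature indices are global: positive-mode
#' features come first (1..n), negative-mode features follow (n+1..2n).
#'
#' @param featureIndex global feature index.
#' @param direction `"up"` (elevated in lame cows) or `"down"`.
#' @param log2FoldChange magnitude of the class shift on the log2 scale;
#'   must be finite and non-zero.
#' @return A one-row `data.frame`; rows from several calls can be `rbind`ed.
#' @export
effectSpec <- function(featureIndex, direction = c("up", "down"),
                       log2FoldChange = 1.5) {
  direction <- match.arg(direction)
  if (!is.finite(log2FoldChange) || log2FoldChange == 0)
    stop("log2FoldChange must be finite and non-zero")
  data.frame(featureIndex = as.integer(featureIndex), direction = direction,
             log2FoldChange = abs(log2FoldChange))
}

#' QC intensity drift profile
#'
#' Deterministic per-QC scaling factors (one per QC acquisition within a
#' day), a slow sinusoidal drift of amplitude `qcDriftAmplitude` around 1.
#' With amplitude 0 all factors are exactly 1, so pooled QCs sit at the
#' centre of the sample cloud.
#'
#' @param design a [StudyDesign-class].
#' @return Numeric vector of length `nQcPerDay`, each within
#'   `1 +/- qcDriftAmplitude`.
#' @export
qcDriftProfile <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  n <- design@nQcPerDay
  if (n < 1L) stop("nQcPerDay must be >= 1")
  1 + design@qcDriftAmplitude * sin(2 * pi * seq_len(n) / (n + 1))
}

# draw n true m/z values uniformly on `range` with a guaranteed minimum
# relative gap, so that jitter-free alignment is unambiguous
drawFeatureMz <- function(n, range, minGapPpm = 30) {
  cand <- sort(runif(3 * n + 50, range[1], range[2]))
  keep <- numeric(0)
  last <- -Inf
  for (x in cand) {
    if ((x - last) / last * 1e6 > minGapPpm || !is.finite(last)) {
      keep <- c(keep, x)
      last <- x
      if (length(keep) == n) break
    }
  }
  if (length(keep) < n)
    stop("could not place ", n, " features with ", minGapPpm,
         " ppm minimum spacing in the m/z range")
  keep
}

#' Generate a synthetic dried-milk-spot study
#'
#' Simulates per-sample peak lists with the statistical structure the
#' downstream analysis assumes: log-normal intensities with per-feature
#' means, an additive class effect (on the log scale) for planted
#' discriminative features, a global multiplicative attenuation of all
#' intensities on extraction days after the first, Normal ppm-scale m/z
#' jitter per observed peak, logistic intensity-dependent (MNAR) dropout,
#' and pooled QC samples built as the day's mean biological profile times a
#' small drift and multiplicative noise. Fully reproducible under the
#' design's seed.
#'
#' @param design a [StudyDesign-class].
#' @param effects `data.frame` of planted effects from [effectSpec()]
#'   (or NULL for a null dataset).
#' @return A list with elements:
#'   \describe{
#'     \item{peakLists}{named list of [PeakList-class], one per sample per
#'       polarity per day.}
#'     \item{samples}{metadata `data.frame` (sample_id, cow_id, class, day,
#'       role, polarity) with one row per peak list.}
#'     \item{truth}{ground-truth list: `effects` (with true m/z attached),
#'       `seed`, and `classMeans` (realised first-day mean log2 intensity per
#'       class for each planted feature).}
#'   }
#' @export
generateStudy <- function(design, effects = NULL) {
  stopifnot(is(design, "StudyDesign"))
  nf <- design@nFeaturesPerPolarity
  if (!is.null(effects) && nrow(effects)) {
    if (anyDuplicated(effects$featureIndex))
      stop("effect feature indices must be unique")
    if (any(effects$featureIndex < 1 | effects$featureIndex > 2 * nf))
      stop("effect feature indices must lie in 1..", 2 * nf)
    if (any(!is.finite(effects$log2FoldChange) | effects$log2FoldChange == 0))
      stop("effect log2 fold changes must be finite and non-zero")
  }

  set.seed(design@seed)
  mzPos <- drawFeatureMz(nf, design@mzRange)
  mzNeg <- drawFeatureMz(nf, design@mzRange)
  trueMz <- c(mzPos, mzNeg)
  polOf <- rep(c("positive", "negative"), each = nf)

  mu <- rnorm(2 * nf, design@baseLogMean, design@featureLogSd)

  cowIds <- c(sprintf("L%02d", seq_len(design@nLame)),
              sprintf("C%02d", seq_len(design@nControl)))
  cowClass <- rep(c("lame", "control"), c(design@nLame, design@nControl))
  nCows <- length(cowIds)

  delta <- numeric(2 * nf)                # additive class shift, log scale
  if (!is.null(effects) && nrow(effects)) {
    sgn <- ifelse(effects$direction == "up", 1, -1)
    delta[effects$featureIndex] <- sgn * effects$log2FoldChange * log(2)
  }

  # per-feature day effect: centred on log(dayAttenuation) with spread
  # dayEffectSd, drawn once per feature (storage loss is compound-dependent;
  # a purely global factor would vanish under TIC normalisation)
  dayDev <- rnorm(2 * nf, 0, design@dayEffectSd)

  mp <- design@missingParams
  dropProb <- function(logI)
    mp$maxRate * plogis(-(logI - mp$mid) / mp$width)

  days <- design@extractionDays
  drift <- if (design@nQcPerDay > 0L) qcDriftProfile(design) else numeric(0)

  peakLists <- list()
  meta <- list()
  # true (pre-dropout) intensities per day for QC pooling and the truth table
  trueInt <- array(NA_real_, dim = c(nCows, 2 * nf, length(days)))

  emit <- function(label, role, cls, dayIdx, logI) {
    intensity <- exp(logI)
    for (pol in c("positive", "negative")) {
      idx <- which(polOf == pol)
      keep <- runif(nf) >= dropProb(logI[idx])
      mzObs <- trueMz[idx] * (1 + rnorm(nf, 0, design@ppmJitterSd) * 1e-6)
      id <- sprintf("d%02d_%s", days[dayIdx], label)
      pl <- PeakList(mzObs[keep], intensity[idx][keep], sampleId = id,
                     polarity = pol, day = days[dayIdx])
      peakLists[[paste(id, pol, sep = "_")]] <<- pl
      meta[[length(meta) + 1L]] <<- data.frame(
        sample_id = id, cow_id = label, class = cls,
        day = days[dayIdx], role = role, polarity = pol)
    }
  }

  for (d in seq_along(days)) {
    att <- if (d > 1L)
      (log(design@dayAttenuation) + dayDev) * (d - 1L) else 0
    for (ci in seq_len(nCows)) {
      shift <- if (cowClass[ci] == "lame") delta else 0
      logI <- mu + shift + att + rnorm(2 * nf, 0, design@baseLogSd)
      trueInt[ci, , d] <- exp(logI)
      emit(cowIds[ci], "study", cowClass[ci], d, logI)
    }
    if (design@nQcPerDay > 0L) {
      pool <- colMeans(trueInt[, , d, drop = TRUE])
      for (q in seq_len(design@nQcPerDay)) {
        logI <- log(pool * drift[q]) + rnorm(2 * nf, 0, design@qcNoiseSd)
        emit(sprintf("QC%d", q), "qc", "qc", d, logI)
      }
    }
  }

  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL

  truth <- list(effects = NULL, seed = design@seed, classMeans = NULL)
  if (!is.null(effects) && nrow(effects)) {
    eff <- effects
    eff$trueMz <- trueMz[eff$featureIndex]
    eff$polarity <- polOf[eff$featureIndex]
    lame <- cowClass == "lame"
    cm <- data.frame(
      featureIndex = eff$featureIndex,
      meanLog2Lame = as.numeric(colMeans(log2(
        trueInt[lame, eff$featureIndex, 1, drop = FALSE]))),
      meanLog2Control = as.numeric(colMeans(log2(
        trueInt[!lame, eff$featureIndex, 1, drop = FALSE]))))
    truth$effects <- eff
    truth$classMeans <- cm
  }
  truth$featureMz <- trueMz
  truth$featurePolarity <- polOf

  list(peakLists = peakLists, samples = samples, truth = truth)
}

#' Write a generated study to disk
#'
#' Per-sample peak lists as two-column CSV (mz, intensity), the sample
#' metadata table (with a `file` column pointing at each peak list) and the
#' planted-effect truth table.
#'
#' @param study result of [generateStudy()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the metadata `data.frame` with the `file` column.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(nrow(study$samples))
  for (i in seq_len(nrow(study$samples))) {
    key <- paste(study$samples$sample_id[i], study$samples$polarity[i],
                 sep = "_")
    pl <- study$peakLists[[key]]
    f <- file.path(dir, paste0(key, ".csv"))
    write.csv(data.frame(mz = pl@mz, intensity = pl@intensity), f,
              row.names = FALSE)
    files[i] <- f
  }
  md <- study$samples
  md$file <- files
  write.csv(md, file.path(dir, "metadata.csv"), row.names = FALSE)
  if (!is.null(study$truth$effects))
    write.csv(study$truth$effects, file.path(dir, "truth.csv"),
              row.names = FALSE)
  invisible(md)
}
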