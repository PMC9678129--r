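#' Preprocessing specification
#'
#' The chemometric preprocessing chain: total-ion-count (TIC) normalisation
#' (each sample divided by its row sum), natural-log transform of
#' `value * ticScale + offset`, and Pareto scaling (centre each feature,
#' divide by the square root of its standard deviation). `ticScale` rescales
#' TIC-normalised fractions back to a count-like magnitude so that the
#' offset of 1 behaves as a conventional pseudo-count.
#'
#' @param ticNormalize,logTransform,paretoScale stage flags.
#' @param offset positive pseudo-count added before the log.
#' @param ticScale multiplier applied to TIC-normalised values inside the
#'   log step (default 1e6, i.e. parts-per-million of the ion count).
#' @return A list of class `PreprocessSpec`.
#' @export
preprocessSpec <- function(ticNormalize = TRUE, logTransform = TRUE,
                           paretoScale = TRUE, offset = 1, ticScale = 1e6) {
  if (logTransform && offset <= 0)
    stop("offset must be > 0 when log-transforming")
  structure(list(ticNormalize = ticNormalize, logTransform = logTransform,
                 paretoScale = paretoScale, offset = offset,
                 ticScale = ticScale),
            class = "PreprocessSpec")
}

# row-wise stages (no cross-sample statistics, safe inside CV)
preprocessRows <- function(X, spec) {
  if (spec$ticNormalize) {
    rs <- rowSums(X)
    if (any(rs == 0))
      stop("zero total ion count for sample(s): ",
           paste(rownames(X)[rs == 0] %||% which(rs == 0), collapse = ", "))
    X <- X / rs
  }
  if (spec$logTransform) {
    s <- if (spec$ticNormalize) spec$ticScale else 1
    X <- log(X * s + spec$offset)
  }
  X
}

# fit column statistics (Pareto) on training data
preprocessFit <- function(X, spec) {
  X <- preprocessRows(X, spec)
  center <- scale <- NULL
  if (spec$paretoScale) {
    center <- colMeans(X)
    sds <- apply(X, 2, sd)
    scale <- sqrt(sds)
    scale[scale == 0] <- 1              # constant columns -> zeros
    X <- sweep(sweep(X, 2, center), 2, scale, "/")
  }
  list(X = X, center = center, scale = scale, spec = spec)
}

preprocessApply <- function(fit, X) {
  X <- preprocessRows(X, fit$spec)
  if (!is.null(fit$center))
    X <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  X
}

#' Apply chemometric preprocessing
#'
#' TIC normalisation, log transform and Pareto scaling per
#' [preprocessSpec()]. The matrix must already be imputed (no NA).
#'
#' @param x a [FeatureSet-class] or samples x features matrix.
#' @param spec a [preprocessSpec()].
#' @return The preprocessed samples x features matrix.
#' @export
preprocessMatrix <- function(x, spec = preprocessSpec()) {
  X <- asSampleMatrix(x)
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  preprocessFit(X, spec)$X
}

#' @rdname standardizeMatrix
#' @export
standardizeFit <- function(X, ticNormalize = TRUE) {
  if (ticNormalize) {
    rs <- rowSums(X)
    if (any(rs == 0)) stop("zero total ion count in standardizeFit")
    X <- X / rs
  }
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  zero <- scale == 0
  if (any(zero)) {
    warning(sum(zero), " constant column(s) scaled to zero")
    scale[zero] <- 1
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  Xs[, zero] <- 0
  list(X = Xs, center = center, scale = scale, zero = zero,
       ticNormalize = ticNormalize)
}

#' @rdname standardizeMatrix
#' @param fit result of `standardizeFit()` (returned invisibly by
#'   [standardizeMatrix()] via attribute `fit`).
#' @param X samples x features matrix to transform with training statistics.
#' @export
standardizeApply <- function(fit, X) {
  if (fit$ticNormalize) X <- X / rowSums(X)
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  Xs[, fit$zero] <- 0
  Xs
}

#' Standardise a feature matrix for machine learning
#'
#' TIC normalisation followed by per-feature zero-mean unit-variance
#' scaling. Constant features are set to zero with a warning. When used
#' inside cross-validation the statistics must be refit on each training
#' fold: `standardizeFit()`/`standardizeApply()` (the former is stored in
#' the `fit` attribute of the result) provide that split.
#'
#' @param x a [FeatureSet-class] or samples x features matrix.
#' @param ticNormalize divide rows by their total ion count first.
#' @return Standardised matrix with attribute `fit`.
#' @export
standardizeMatrix <- function(x, ticNormalize = TRUE) {
  X <- asSampleMatrix(x)
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  f <- standardizeFit(X, ticNormalize)
  structure(f$X, fit = f[c("center", "scale", "zero", "ticNormalize")])
}

#' Principal component analysis
#'
#' Column-centred PCA (no scaling; the Pareto step is expected upstream) via
#' the singular value decomposition. Loadings are orthonormal, scores are
#' the centred data projected onto them, and explained-variance fractions
#' are relative to the total variance.
#'
#' @param x a [FeatureSet-class] or samples x features matrix (preprocessed).
#' @param nComponents number of components (capped at the matrix rank).
#' @return List with `scores`, `loadings`, `explainedVar` and `center`.
#' @export
pcaModel <- function(x, nComponents = 6) {
  X <- asSampleMatrix(x)
  if (anyNA(X)) stop("matrix contains missing values; impute first")
  maxRank <- min(nrow(X) - 1L, ncol(X))
  n <- min(nComponents, maxRank)
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n), drop = FALSE],
       loadings = pc$rotation[, seq_len(n), drop = FALSE],
       explainedVar = ev[seq_len(n)],
       center = pc$center)
}
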