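#' NIPALS partial least squares (single response)
#'
#' Standard PLS1: components are extracted by the NIPALS sequence
#' (weight from the X-y covariance, score, loading, rank-one deflation of X
#' and y). Used both as a classifier (PLS-DA, 0/1-coded outcome) and as the
#' numerical cross-check for the OPLS-DA regression path.
#'
#' @param x samples x features matrix (will be column-centred internally).
#' @param y binary labels (factor or 0/1) or a numeric response.
#' @param nComponents number of latent components.
#' @return List of class `plsModel` with weights `W`, loadings `P`,
#'   y-loadings `q`, `scores`, regression coefficients `B`, centring stats
#'   and (for binary input) the class levels.
#' @export
nipalsPls <- function(x, y, nComponents = 2) {
  X <- asSampleMatrix(x)
  lv <- NULL
  if (!is.numeric(y) || all(y %in% c(0, 1))) {
    cl <- codeLabels(y)
    yNum <- cl$y01
    lv <- cl$levels
  } else yNum <- y
  xMeans <- colMeans(X)
  Xc <- sweep(X, 2, xMeans)
  yMean <- mean(yNum)
  yc <- yNum - yMean
  p <- ncol(Xc)
  A <- nComponents
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  Tm <- matrix(0, nrow(Xc), A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("no covariance left for component ", a)
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    pv <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- pv; q[a] <- qa; Tm[, a] <- t
  }
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(W = W, P = P, q = q, scores = Tm, B = drop(B),
                 xMeans = xMeans, yMean = yMean, levels = lv,
                 nComponents = A),
            class = "plsModel")
}

#' Predict from a NIPALS PLS model
#'
#' @param object a `plsModel` from [nipalsPls()].
#' @param newdata samples x features matrix.
#' @param type `"response"` for numeric predictions, `"class"` for labels
#'   (0.5 cut; ties go to the first level).
#' @param ... unused.
#' @export
predict.plsModel <- function(object, newdata, type = c("response", "class"),
                             ...) {
  type <- match.arg(type)
  X <- sweep(asSampleMatrix(newdata), 2, object$xMeans)
  yhat <- drop(X %*% object$B) + object$yMean
  if (type == "response") return(yhat)
  if (is.null(object$levels)) stop("model was fit on a numeric response")
  object$levels[ifelse(yhat > 0.5, 2L, 1L)]
}

# PLS weights-based importance (VIP over the model's components)
plsVip <- function(model) {
  ssy <- model$q^2 * colSums(model$scores^2)
  p <- nrow(model$W)
  sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures for a binary class outcome
#' (labels coded 0/1; the first factor level is the control side, 0).
#' NIPALS-style sequence: the predictive weight vector is taken from the
#' X-y covariance; for each orthogonal component the part of the X-loading
#' orthogonal to that weight is extracted and deflated from X; the single
#' predictive component is then fit on the filtered X. VIP scores are
#' computed from the predictive component (optionally including orthogonal
#' variation), and S-plot statistics are the covariance and Pearson
#' correlation of each centred input feature with the predictive score.
#'
#' @param x samples x features matrix (preprocessed; centred internally) or
#'   [FeatureSet-class].
#' @param y binary labels (two-level factor, or 0/1).
#' @param nOrthogonal number of orthogonal components (default 1).
#' @param vipOrthogonal include orthogonal components in VIP (total-VIP
#'   variant); default FALSE, the predictive-variation convention used for
#'   "VIP > 1" selection.
#' @return An [OplsModel-class].
#' @export
fitOplsDa <- function(x, y, nOrthogonal = 1, vipOrthogonal = FALSE) {
  X <- asSampleMatrix(x)
  cl <- codeLabels(y)
  if (min(table(cl$y01)) < 1L) stop("both classes must be present")
  if (nOrthogonal < 0) stop("nOrthogonal must be >= 0")
  xMeans <- colMeans(X)
  Xc <- sweep(X, 2, xMeans)
  X0 <- Xc
  yMean <- mean(cl$y01)
  yc <- cl$y01 - yMean
  ssX <- sum(X0^2)
  ssY <- sum(yc^2)

  w <- drop(crossprod(Xc, yc)) / ssY
  w <- w / sqrt(sum(w^2))
  p <- ncol(Xc)
  To <- matrix(0, nrow(Xc), max(nOrthogonal, 0))
  Po <- Wo <- matrix(0, p, max(nOrthogonal, 0))
  ssOrth <- numeric(nOrthogonal)
  for (a in seq_len(nOrthogonal)) {
    t <- drop(Xc %*% w)
    pv <- drop(crossprod(Xc, t)) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10)
      stop("rank too low for ", nOrthogonal, " orthogonal component(s)")
    wo <- wo / nwo
    to <- drop(Xc %*% wo)
    po <- drop(crossprod(Xc, to)) / sum(to^2)
    Xc <- Xc - tcrossprod(to, po)
    To[, a] <- to; Po[, a] <- po; Wo[, a] <- wo
    ssOrth[a] <- sum(to^2) * sum(po^2)
  }
  t <- drop(Xc %*% w)
  pv <- drop(crossprod(Xc, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  fitted <- t * cc + yMean

  ssPred <- sum(t^2) * sum(pv^2)
  R2X <- (ssPred + sum(ssOrth)) / ssX
  R2Y <- 1 - sum((cl$y01 - fitted)^2) / ssY

  if (vipOrthogonal && nOrthogonal > 0) {
    ssyPred <- cc^2 * sum(t^2)
    num <- ssyPred * w^2 + drop(Wo^2 %*% ssOrth)
    vip <- sqrt(p * num / (ssyPred + sum(ssOrth)))
  } else {
    vip <- sqrt(p) * abs(w)
  }

  sdT <- sd(t)
  sdX <- apply(X0, 2, sd)
  splotCov <- drop(crossprod(X0, t - mean(t))) / (nrow(X0) - 1)
  splotCorr <- splotCov / (sdT * sdX)
  splotCorr[sdX == 0] <- 0

  new("OplsModel",
      nPredictive = 1L, nOrthogonal = as.integer(nOrthogonal),
      scores = matrix(t, ncol = 1), loadings = matrix(pv, ncol = 1),
      weights = matrix(w, ncol = 1),
      orthoScores = To, orthoLoadings = Po, orthoWeights = Wo,
      yCoef = cc, xMeans = xMeans, yMean = yMean,
      R2X = R2X, R2Y = R2Y, vip = vip,
      splotCov = splotCov, splotCorr = splotCorr,
      levels = cl$levels, fitted = fitted)
}

#' Predict from an OPLS-DA model
#'
#' New samples are centred, stripped of the orthogonal components, projected
#' onto the predictive weight and regressed through the standard O-PLS path.
#' Class calls cut predicted y at 0.5 (ties go to the control/first level).
#'
#' @param object an [OplsModel-class].
#' @param newdata samples x features matrix on the same feature set.
#' @param type `"response"` or `"class"`.
#' @export
setMethod("predict", "OplsModel",
  function(object, newdata, type = c("response", "class")) {
    type <- match.arg(type)
    X <- sweep(asSampleMatrix(newdata), 2, object@xMeans)
    for (a in seq_len(object@nOrthogonal)) {
      to <- drop(X %*% object@orthoWeights[, a])
      X <- X - tcrossprod(to, object@orthoLoadings[, a])
    }
    t <- drop(X %*% object@weights[, 1])
    yhat <- t * object@yCoef + object@yMean
    if (type == "response") return(yhat)
    object@levels[ifelse(yhat > 0.5, 2L, 1L)]
  })

#' VIP scores of an OPLS-DA model
#' @param object an [OplsModel-class].
#' @return Named numeric vector (mean of squared values = 1 for the
#'   predictive-only convention).
#' @export
vipScores <- function(object) {
  stopifnot(is(object, "OplsModel"))
  object@vip
}

#' S-plot statistics of an OPLS-DA model
#' @param object an [OplsModel-class].
#' @return `data.frame` with per-feature `covariance` and `correlation`
#'   against the predictive score.
#' @export
splotStats <- function(object) {
  stopifnot(is(object, "OplsModel"))
  data.frame(covariance = object@splotCov, correlation = object@splotCorr)
}

#' Leave-one-out cross-validated Q2
#'
#' Q2 = 1 - PRESS/SS, where PRESS accumulates the squared error of each
#' left-out sample predicted from a model fit without it, and SS is the
#' total sum of squares of the 0/1-coded outcome about its mean. When a
#' preprocessing spec is supplied, the raw matrix is preprocessed inside
#' each fold (Pareto centring/scaling statistics refit on the training
#' fold only).
#'
#' @param x samples x features matrix or [FeatureSet-class]; raw if `spec`
#'   is given, otherwise already preprocessed.
#' @param y binary labels.
#' @param nOrthogonal orthogonal components.
#' @param spec optional [preprocessSpec()] applied per fold.
#' @return Q2 (a fraction, at most 1; can be negative).
#' @export
loocvQ2 <- function(x, y, nOrthogonal = 1, spec = NULL) {
  X <- asSampleMatrix(x)
  cl <- codeLabels(y)
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (!is.null(spec)) {
      f <- preprocessFit(Xtr, spec)
      Xtr <- f$X
      Xte <- preprocessApply(f, Xte)
    }
    m <- fitOplsDa(Xtr, cl$factor[-i], nOrthogonal)
    press <- press + (cl$y01[i] - predict(m, Xte))^2
  }
  1 - press / sum((cl$y01 - mean(cl$y01))^2)
}

#' Permutation test for an OPLS-DA model
#'
#' Class labels are permuted `nPerm` times; the model (and its LOOCV Q2) is
#' refit for each permutation, giving null distributions for R2Y and Q2 and
#' empirical p-values `(1 + #{null >= observed}) / (nPerm + 1)`.
#'
#' @inheritParams loocvQ2
#' @param nPerm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return List with observed statistics, null distributions and p-values.
#' @export
oplsPermutationTest <- function(x, y, nOrthogonal = 1, nPerm = 100,
                                seed = 1, spec = NULL) {
  stopifnot(nPerm >= 1)
  X <- asSampleMatrix(x)
  cl <- codeLabels(y)
  Xm <- if (is.null(spec)) X else preprocessMatrix(X, spec)
  obsR2Y <- fitOplsDa(Xm, cl$factor, nOrthogonal)@R2Y
  obsQ2 <- loocvQ2(X, cl$factor, nOrthogonal, spec)
  nullR2Y <- nullQ2 <- numeric(nPerm)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      yp <- sample(cl$factor)
      nullR2Y[b] <- fitOplsDa(Xm, yp, nOrthogonal)@R2Y
      nullQ2[b] <- loocvQ2(X, yp, nOrthogonal, spec)
    }
  })
  list(observedR2Y = obsR2Y, observedQ2 = obsQ2,
       nullR2Y = nullR2Y, nullQ2 = nullQ2,
       pR2Y = (1 + sum(nullR2Y >= obsR2Y)) / (nPerm + 1),
       pQ2 = (1 + sum(nullQ2 >= obsQ2)) / (nPerm + 1))
}
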