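#' Penalised-model specification for stability selection
#'
#' Three penalised binary-outcome regressions are supported: elastic net
#' and Lasso (glmnet) and the minimax concave penalty (MCP; in-repo
#' coordinate-descent solver). The penalty strength is chosen per fit by
#' inner cross-validation with the 1-SE rule by default; a fixed lambda is
#' available. The outcome model is penalised logistic regression (a linear
#' mode is available for numeric responses).
#'
#' @param penalty `"elastic_net"`, `"lasso"` or `"mcp"`.
#' @param alpha elastic-net mixing parameter in (0, 1\] (default 0.5;
#'   ignored for lasso/mcp).
#' @param mcpGamma MCP concavity parameter, > 1 (default 3).
#' @param lambdaRule `"cv1se"` (inner CV, 1-SE rule), `"cvmin"` or
#'   `"fixed"`.
#' @param lambda fixed penalty strength (required when
#'   `lambdaRule = "fixed"`).
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param nfolds inner-CV folds (default 10, the glmnet convention).
#' @param seed base RNG seed (inner-CV fold assignment).
#' @return List of class `PenalisedSpec`.
#' @export
penalisedSpec <- function(penalty = c("elastic_net", "lasso", "mcp"),
                          alpha = 0.5, mcpGamma = 3,
                          lambdaRule = c("cv1se", "cvmin", "fixed"),
                          lambda = NULL,
                          family = c("binomial", "gaussian"),
                          nfolds = 10, seed = 1) {
  penalty <- match.arg(penalty)
  lambdaRule <- match.arg(lambdaRule)
  family <- match.arg(family)
  if (penalty == "elastic_net" && (alpha <= 0 || alpha > 1))
    stop("alpha must be in (0, 1]")
  if (mcpGamma <= 1) stop("mcpGamma must be > 1")
  if (lambdaRule == "fixed" && is.null(lambda))
    stop("lambdaRule = 'fixed' requires lambda")
  structure(list(penalty = penalty, alpha = alpha, mcpGamma = mcpGamma,
                 lambdaRule = lambdaRule, lambda = lambda, family = family,
                 nfolds = as.integer(nfolds), seed = as.integer(seed)),
            class = "PenalisedSpec")
}

# lambda path for the MCP solver (glmnet-style geometric path)
mcpLambdaPath <- function(X, y, family, nLambda = 30, minRatio = 0.1) {
  n <- nrow(X)
  Xs <- scale(X, center = TRUE,
              scale = apply(X, 2, function(v) {
                s <- sqrt(mean((v - mean(v))^2)); if (s > 1e-12) s else 1
              }))
  yc <- if (family == "binomial") y - mean(y) else y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc))) / n
  if (family == "binomial") lmax <- lmax     # working-response scale ~ y - pi
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
}

#' Fit a single MCP-penalised regression path
#'
#' Coordinate descent with the firm (MCP) thresholding rule; binomial fits
#' use IRLS working responses with adaptive rescaling so `gamma` keeps its
#' linear-model interpretation. Columns are standardised internally and
#' coefficients returned on the input scale.
#'
#' @param X samples x features matrix.
#' @param y 0/1 (binomial) or numeric (gaussian) response.
#' @param lambda numeric vector of penalty strengths (decreasing).
#' @param gamma MCP concavity parameter (> 1).
#' @param family `"binomial"` or `"gaussian"`.
#' @param maxit,tol solver controls; non-convergence is an error.
#' @return Matrix (1 + p) x length(lambda) of intercept and coefficients.
#' @export
mcpPath <- function(X, y, lambda, gamma = 3, family = "binomial",
                    maxit = 10000, tol = 1e-7) {
  fam <- if (family == "binomial") 1L else 0L
  res <- .mcpSolve(as.matrix(X), as.numeric(y), as.numeric(lambda),
                   gamma, fam, as.integer(maxit), tol)
  if (!all(res$converged))
    stop("mcp solver failed to converge within ", maxit,
         " coordinate sweeps per reweighting at lambda = ",
         paste(signif(lambda[!res$converged], 3), collapse = ", "),
         " (gamma = ", gamma, ", n = ", nrow(X), ", p = ", ncol(X), ")")
  rownames(res$beta) <- c("(Intercept)",
                          colnames(X) %||% paste0("V", seq_len(ncol(X))))
  res$beta
}

# fold assignment for inner CV. When rows are bootstrap copies of source
# observations (foldGroups = source index per row), all copies of one
# observation share a fold: otherwise duplicates straddle the split and
# the CV curve rewards overfitting noise
makeFoldid <- function(y, nfolds, seed, foldGroups = NULL) {
  n <- length(y)
  if (is.null(foldGroups)) foldGroups <- seq_len(n)
  ug <- unique(foldGroups)
  gy <- y[match(ug, foldGroups)]
  gf <- integer(length(ug))
  withSeed(seed, {
    for (cls in unique(gy)) {
      idx <- which(gy == cls)
      gf[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  gf[match(foldGroups, ug)]
}

# K-fold CV over an MCP lambda path; returns lambda.min and lambda.1se
mcpCv <- function(X, y, lambda, gamma, family, nfolds, seed,
                  foldGroups = NULL) {
  n <- nrow(X)
  folds <- makeFoldid(y, nfolds, seed, foldGroups)
  err <- matrix(NA_real_, nfolds, length(lambda))
  for (k in seq_len(nfolds)) {
    te <- folds == k
    if (family == "binomial" && length(unique(y[!te])) < 2L) next
    beta <- mcpPath(X[!te, , drop = FALSE], y[!te], lambda, gamma, family)
    eta <- cbind(1, X[te, , drop = FALSE]) %*% beta
    if (family == "binomial") {
      pr <- 1 / (1 + exp(-eta))
      pr <- pmin(pmax(pr, 1e-10), 1 - 1e-10)
      err[k, ] <- -2 * colMeans(y[te] * log(pr) + (1 - y[te]) * log(1 - pr))
    } else {
      err[k, ] <- colMeans((y[te] - eta)^2)
    }
  }
  cvm <- colMeans(err, na.rm = TRUE)
  cvse <- apply(err, 2, function(e) sd(e, na.rm = TRUE)) /
    sqrt(colSums(!is.na(err)))
  iMin <- which.min(cvm)
  ok <- which(cvm <= cvm[iMin] + cvse[iMin])
  i1se <- min(ok)                        # largest lambda within 1 SE
  list(lambdaMin = lambda[iMin], lambda1se = lambda[i1se])
}

#' Fit one penalised model and return its coefficients
#'
#' Elastic net and Lasso go through glmnet; MCP through the in-repo
#' coordinate-descent solver. The penalty strength follows the spec's
#' lambda rule (inner CV 1-SE by default). A feature is "selected" iff its
#' returned coefficient is non-zero.
#'
#' @param X samples x features matrix (standardised upstream; the solvers
#'   also standardise internally).
#' @param y binary labels (or numeric response for the gaussian family).
#' @param spec a [penalisedSpec()].
#' @param seed RNG seed for inner-CV fold assignment (defaults to the
#'   spec's).
#' @param foldGroups optional source-observation index per row: rows that
#'   are bootstrap copies of the same observation are kept in one CV fold,
#'   so the inner CV is not leaked by duplicates.
#' @return Named numeric vector of feature coefficients (intercept
#'   excluded).
#' @export
fitPenalised <- function(X, y, spec = penalisedSpec(), seed = spec$seed,
                         foldGroups = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  yNum <- if (spec$family == "binomial") codeLabels(y)$y01 else as.numeric(y)

  if (spec$penalty %in% c("elastic_net", "lasso")) {
    alpha <- if (spec$penalty == "lasso") 1 else spec$alpha
    fam <- spec$family
    if (spec$lambdaRule == "fixed") {
      fit <- glmnet::glmnet(X, yNum, family = fam, alpha = alpha,
                            lambda = spec$lambda)
      return(drop(coef(fit, s = spec$lambda))[-1])
    }
    foldid <- makeFoldid(yNum, spec$nfolds, seed, foldGroups)
    cv <- quietGlmnet(glmnet::cv.glmnet(X, yNum, family = fam,
                                        alpha = alpha, foldid = foldid))
    s <- if (spec$lambdaRule == "cv1se") cv$lambda.1se else cv$lambda.min
    return(drop(coef(cv, s = s))[-1])
  }

  # MCP
  path <- mcpLambdaPath(X, yNum, spec$family)
  if (spec$lambdaRule == "fixed") {
    beta <- mcpPath(X, yNum, sort(c(path[path > spec$lambda],
                                    spec$lambda), decreasing = TRUE),
                    spec$mcpGamma, spec$family)
    return(beta[-1, ncol(beta)])
  }
  cv <- mcpCv(X, yNum, path, spec$mcpGamma, spec$family, spec$nfolds, seed,
              foldGroups)
  s <- if (spec$lambdaRule == "cv1se") cv$lambda1se else cv$lambdaMin
  beta <- mcpPath(X, yNum, path, spec$mcpGamma, spec$family)
  beta[-1, which.min(abs(path - s))]
}

#' Bootstrap stability scores
#'
#' Refits the penalised model on `nBoot` stratified bootstrap resamples
#' (rows drawn with replacement within each class, preserving class
#' counts) and records the fitted coefficient of every feature in every
#' resample. The stability score of a feature is the percentage of
#' resamples in which its coefficient was non-zero; sign-based bootstrap
#' p-values are computed from the same record.
#'
#' @param X samples x features matrix (standardised).
#' @param y binary labels.
#' @param spec a [penalisedSpec()].
#' @param nBoot number of bootstrap resamples (study default 500).
#' @param seed RNG seed.
#' @param stratified stratify the bootstrap by class (default TRUE);
#'   unstratified resamples that land in a single class are redrawn
#'   (bounded retries).
#' @param groupedCv keep all bootstrap copies of one observation in a
#'   single inner-CV fold. The default (FALSE) is the plain per-resample
#'   CV of the reference procedure: duplicate rows do leak across folds
#'   and flatter the fit, but the permutation threshold is computed under
#'   exactly the same mechanism, so the null calibration absorbs it.
#'   Grouped CV is the stricter variant; it yields sparser fits and much
#'   lower thresholds.
#' @return A [StabilityResult-class] (threshold slot NA until
#'   [permutationThreshold()] is attached via [selectStable()] or manually).
#' @export
stabilityScores <- function(X, y, spec = penalisedSpec(), nBoot = 500,
                            seed = 1, stratified = TRUE,
                            groupedCv = FALSE) {
  stopifnot(nBoot >= 1)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  cl <- codeLabels(y)
  n <- nrow(X)
  coefRec <- matrix(0, nBoot, ncol(X),
                    dimnames = list(NULL, colnames(X)))
  withSeed(seed, {
    byClass <- split(seq_len(n), cl$y01)
    for (b in seq_len(nBoot)) {
      if (stratified) {
        idx <- unlist(lapply(byClass, function(ix)
          sample(ix, length(ix), replace = TRUE)), use.names = FALSE)
      } else {
        for (try in 1:25) {
          idx <- sample(n, n, replace = TRUE)
          if (length(unique(cl$y01[idx])) == 2L) break
          if (try == 25) stop("could not draw a two-class bootstrap sample")
        }
      }
      coefRec[b, ] <- fitPenalised(X[idx, , drop = FALSE],
                                   cl$factor[idx], spec,
                                   seed = deriveSeed(seed, b),
                                   foldGroups = if (groupedCv) idx)
    }
  })
  counts <- colSums(coefRec != 0)
  new("StabilityResult",
      penalty = spec$penalty, featureNames = colnames(X),
      coefRecord = coefRec, selectionCount = as.integer(counts),
      stabilityScore = 100 * counts / nBoot,
      bootstrapP = bootstrapP(coefRec),
      threshold = NA_real_,
      nBootstraps = as.integer(nBoot), nPermutations = 0L,
      nPermutationBootstraps = 0L)
}

#' Permutation-derived stability threshold
#'
#' The class labels are permuted `nPerm` times; for each permuted dataset
#' the bootstrap stability scores are recomputed with `nPermBoot`
#' resamples. The threshold is the highest stability score achieved by any
#' feature in any permuted dataset (a family-wise null bound; a quantile
#' alternative is available).
#'
#' @inheritParams stabilityScores
#' @param nPerm number of label permutations (study default 20).
#' @param nPermBoot bootstraps per permuted dataset (study default 50).
#' @param quantile if < 1, use this quantile of the per-permutation maxima
#'   instead of the overall maximum.
#' @return Threshold in percent.
#' @export
permutationThreshold <- function(X, y, spec = penalisedSpec(), nPerm = 20,
                                 nPermBoot = 50, seed = 1, quantile = 1) {
  stopifnot(nPerm >= 1, nPermBoot >= 1)
  cl <- codeLabels(y)
  maxima <- numeric(nPerm)
  perms <- withSeed(deriveSeed(seed, 555),
                    replicate(nPerm, sample(cl$factor), simplify = FALSE))
  for (i in seq_len(nPerm)) {
    sc <- stabilityScores(X, perms[[i]], spec, nBoot = nPermBoot,
                          seed = deriveSeed(seed, 7000 + i))
    maxima[i] <- max(sc@stabilityScore, 0)
  }
  if (quantile >= 1) max(maxima) else
    as.numeric(stats::quantile(maxima, quantile))
}

#' Sign-based bootstrap p-values
#'
#' The bootstrap p-value of a feature is the proportion of its non-zero
#' bootstrap coefficients lying on the minority side of zero: selected 100
#' times with 95 positive coefficients gives (100 - 95)/100 = 0.05. By
#' construction p <= 0.5; features never selected get NA.
#'
#' @param x a signed-coefficient record: numeric vector (one feature's
#'   non-zero coefficients; zeros are ignored), a bootstraps x features
#'   matrix, or a [StabilityResult-class].
#' @return Numeric p-value(s) in \[0, 0.5\], NA where undefined.
#' @export
bootstrapP <- function(x) {
  if (is(x, "StabilityResult")) return(bootstrapP(x@coefRecord))
  if (is.matrix(x)) return(apply(x, 2, bootstrapP))
  pos <- sum(x > 0)
  neg <- sum(x < 0)
  if (pos + neg == 0L) return(NA_real_)
  min(pos, neg) / (pos + neg)
}

#' Select stable features
#'
#' Features with a stability score strictly above the permutation threshold
#' and a bootstrap p-value below `pCut`.
#'
#' @param result a [StabilityResult-class].
#' @param threshold permutation threshold in percent (from
#'   [permutationThreshold()]); taken from the result's slot when already
#'   attached.
#' @param pCut bootstrap p-value cut (default 0.05).
#' @return Character vector of selected feature names.
#' @export
selectStable <- function(result, threshold = result@threshold, pCut = 0.05) {
  stopifnot(is(result, "StabilityResult"))
  if (is.na(threshold)) stop("no threshold computed; run permutationThreshold()")
  p <- result@bootstrapP
  sel <- result@stabilityScore > threshold & !is.na(p) & p < pCut
  result@featureNames[sel]
}

#' Tabulate a stability-selection result
#'
#' @param result a [StabilityResult-class].
#' @param threshold optional threshold to evaluate the `selected` flag
#'   (default: the slot value, possibly NA).
#' @param pCut bootstrap p-value cut for the flag.
#' @return `data.frame` with feature, stability score (%), selection count,
#'   bootstrap p and selected flag, sorted by decreasing score.
#' @export
stabilityTable <- function(result, threshold = result@threshold,
                           pCut = 0.05) {
  stopifnot(is(result, "StabilityResult"))
  sel <- if (is.na(threshold)) NA else
    result@stabilityScore > threshold & !is.na(result@bootstrapP) &
      result@bootstrapP < pCut
  out <- data.frame(feature = result@featureNames,
                    stabilityScore = result@stabilityScore,
                    selectionCount = result@selectionCount,
                    bootstrapP = result@bootstrapP,
                    selected = sel)
  out[order(-out$stabilityScore), ]
}
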