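#' Machine-learning model specification
#'
#' One of the four classifiers triangulated against the chemometric
#' selection. Defaults: random forest with 500 trees (impurity importance),
#' elastic net with mixing 0.5 and penalty from inner CV, 2-component
#' PLS-DA (weights-based VIP importance), linear SVM with cost 1
#' (weight-vector importance).
#'
#' @param modelKind `"random_forest"`, `"elastic_net"`, `"pls_da"` or
#'   `"svm"`.
#' @param hyper named list of hyperparameters (`ntree`, `alpha`, `nComp`,
#'   `cost`, `kernel`, `nfolds`).
#' @param nRepeats repeats for stochastic learners (averaged); >= 1.
#' @param seed base RNG seed.
#' @return List of class `MlSpec`.
#' @export
mlSpec <- function(modelKind = c("random_forest", "elastic_net", "pls_da",
                                 "svm"),
                   hyper = list(), nRepeats = 1, seed = 1) {
  modelKind <- match.arg(modelKind)
  stopifnot(nRepeats >= 1)
  defaults <- switch(modelKind,
    random_forest = list(ntree = 500),
    elastic_net = list(alpha = 0.5, nfolds = 5),
    pls_da = list(nComp = 2),
    svm = list(cost = 1, kernel = "linear"))
  defaults[names(hyper)] <- hyper
  structure(list(modelKind = modelKind, hyper = defaults,
                 nRepeats = as.integer(nRepeats), seed = as.integer(seed)),
            class = "MlSpec")
}

isStochastic <- function(spec) spec$modelKind %in% c("random_forest",
                                                     "elastic_net")

# fit one classifier; X standardized, y factor with 2 levels
fitMl <- function(spec, X, y, seed) {
  y <- droplevels(factor(y))
  h <- spec$hyper
  switch(spec$modelKind,
    random_forest = withSeed(seed,
      randomForest::randomForest(x = X, y = y, ntree = h$ntree,
                                 importance = FALSE)),
    elastic_net = withSeed(seed, {
      if (ncol(X) == 1L) {
        # glmnet needs >= 2 columns; a single retained feature gets an
        # unpenalised logistic fit
        df <- data.frame(y = y, x = X[, 1])
        structure(list(fit = suppressWarnings(glm(y ~ x, df, family = binomial())),
                       levels = levels(y)), class = "mdGlm1")
      } else {
        nf <- min(h$nfolds, min(table(y)))
        cv <- quietGlmnet(glmnet::cv.glmnet(X, y, family = "binomial",
                                            alpha = h$alpha,
                                            nfolds = max(nf, 3),
                                            standardize = FALSE))
        structure(list(cv = cv, lambda = cv$lambda.min), class = "mdEnet")
      }
    }),
    pls_da = nipalsPls(X, y, nComponents = min(h$nComp, nrow(X) - 1L,
                                               ncol(X))),
    svm = {
      if (!identical(h$kernel, "linear"))
        stop("linear kernel required for weight-based SVM ranking")
      e1071::svm(x = X, y = y, kernel = "linear", cost = h$cost,
                 scale = FALSE)
    })
}

predictMl <- function(spec, model, X) {
  if (inherits(model, "mdGlm1")) {
    pr <- predict(model$fit, data.frame(x = X[, 1]), type = "response")
    return(factor(model$levels[ifelse(pr > 0.5, 2L, 1L)],
                  levels = model$levels))
  }
  lv <- switch(spec$modelKind,
    random_forest = levels(model$y),
    elastic_net = model$cv$glmnet.fit$classnames,
    pls_da = model$levels,
    svm = levels(model$fitted))
  out <- switch(spec$modelKind,
    random_forest = as.character(predict(model, X)),
    elastic_net = as.character(predict(model$cv, X, s = model$lambda,
                                       type = "class")),
    pls_da = predict(model, X, type = "class"),
    svm = as.character(predict(model, X)))
  factor(out, levels = lv)
}

importanceMl <- function(spec, model) {
  if (inherits(model, "mdGlm1")) return(abs(coef(model$fit)[2]))
  switch(spec$modelKind,
    random_forest = model$importance[, "MeanDecreaseGini"],
    elastic_net = abs(drop(coef(model$cv, s = model$lambda))[-1]),
    pls_da = plsVip(model),
    svm = {
      w <- drop(crossprod(model$coefs, model$SV))
      abs(w)
    })
}

# RF importance needs importance slot; refit with importance when ranking
fitMlForImportance <- function(spec, X, y, seed) {
  if (spec$modelKind == "random_forest") {
    withSeed(seed, randomForest::randomForest(
      x = X, y = droplevels(factor(y)), ntree = spec$hyper$ntree,
      importance = FALSE))       # MeanDecreaseGini is always computed
  } else fitMl(spec, X, y, seed)
}

#' Leave-one-out cross-validated accuracy
#'
#' One fold per sample (cow): standardisation statistics are refit on each
#' training fold and applied to the held-out sample, the classifier is fit
#' on the (optionally subset) training matrix, and accuracy is the fraction
#' of correctly classified held-out samples. Stochastic learners are
#' averaged over `nRepeats` seeded runs.
#'
#' @param x raw (imputed, unstandardised) samples x features matrix or
#'   [FeatureSet-class].
#' @param y binary labels.
#' @param spec an [mlSpec()].
#' @param featureSubset optional column names/indices to restrict to
#'   (applied after fold-internal standardisation).
#' @param standardize refit TIC + z-score inside each fold (default TRUE).
#' @return Accuracy fraction in \[0, 1\].
#' @export
loocvAccuracy <- function(x, y, spec, featureSubset = NULL,
                          standardize = TRUE) {
  X <- asSampleMatrix(x)
  yf <- droplevels(factor(y))
  n <- nrow(X)
  reps <- if (isStochastic(spec)) spec$nRepeats else 1L
  acc <- numeric(reps)
  for (r in seq_len(reps)) {
    correct <- 0L
    for (i in seq_len(n)) {
      ytr <- yf[-i]
      if (nlevels(droplevels(ytr)) < 2L)
        stop("degenerate training fold: single class after holding out ", i)
      if (standardize) {
        f <- standardizeFit(X[-i, , drop = FALSE])
        Xtr <- f$X
        Xte <- standardizeApply(f, X[i, , drop = FALSE])
      } else {
        Xtr <- X[-i, , drop = FALSE]
        Xte <- X[i, , drop = FALSE]
      }
      if (!is.null(featureSubset)) {
        Xtr <- Xtr[, featureSubset, drop = FALSE]
        Xte <- Xte[, featureSubset, drop = FALSE]
      }
      m <- fitMl(spec, Xtr, ytr, seed = deriveSeed(spec$seed, 1000 * r + i))
      correct <- correct + (as.character(predictMl(spec, m, Xte)) ==
                              as.character(yf[i]))
    }
    acc[r] <- correct / n
  }
  mean(acc)
}

# subset-size ladder: halve down to (at most) 20 features, then step by 1
rfeSizes <- function(p) {
  sizes <- integer(0)
  s <- p
  while (s > 20L) {
    sizes <- c(sizes, s)
    s <- as.integer(ceiling(s / 2))
  }
  c(sizes, seq(s, 1L))
}

# one elimination pass: returns list of retained-feature index vectors per
# size, ranking recomputed (model refit) at every size
rfePass <- function(spec, X, y, sizes, seed) {
  current <- seq_len(ncol(X))
  subsets <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    if (length(current) > s) {
      m <- fitMlForImportance(spec, X[, current, drop = FALSE], y,
                              deriveSeed(seed, si))
      imp <- importanceMl(spec, m)
      keep <- order(imp, decreasing = TRUE)[seq_len(s)]
      current <- sort(current[keep])
    }
    subsets[[si]] <- current
  }
  subsets
}

#' Recursive feature elimination under LOOCV
#'
#' Features are eliminated by model-specific importance (impurity for RF,
#' |coefficient| for elastic net, PLS weights-based VIP, |weight| for the
#' linear SVM), halving the set down to 20 features and then stepping by
#' one. To avoid selection bias the ranking and elimination are recomputed
#' inside every training fold; the per-size accuracies are averages over
#' the held-out samples. Alternatively (`nested = FALSE`) a literal
#' rank-once-on-all-data pass is available for comparison. The reported
#' best subset comes from a full-data elimination pass at the best
#' (smallest maximising) size.
#'
#' @inheritParams loocvAccuracy
#' @param nested recompute elimination within training folds (default TRUE).
#' @return An [RfeCurve-class].
#' @export
rfe <- function(x, y, spec, standardize = TRUE, nested = TRUE) {
  X <- asSampleMatrix(x)
  if (ncol(X) < 2L) stop("need >= 2 features for elimination")
  if (spec$modelKind == "svm" && !identical(spec$hyper$kernel, "linear"))
    stop("linear kernel required for weight-based SVM ranking")
  yf <- droplevels(factor(y))
  n <- nrow(X)
  sizes <- rfeSizes(ncol(X))
  hits <- matrix(0, n, length(sizes))

  fullStd <- if (standardize) standardizeFit(X)$X else X
  fullSubsets <- rfePass(spec, fullStd, yf, sizes,
                         deriveSeed(spec$seed, 777))

  for (i in seq_len(n)) {
    if (standardize) {
      f <- standardizeFit(X[-i, , drop = FALSE])
      Xtr <- f$X
      Xte <- standardizeApply(f, X[i, , drop = FALSE])
    } else {
      Xtr <- X[-i, , drop = FALSE]
      Xte <- X[i, , drop = FALSE]
    }
    subsets <- if (nested) rfePass(spec, Xtr, yf[-i], sizes,
                                   deriveSeed(spec$seed, i))
               else fullSubsets
    for (si in seq_along(sizes)) {
      cols <- subsets[[si]]
      m <- fitMl(spec, Xtr[, cols, drop = FALSE], yf[-i],
                 deriveSeed(spec$seed, 5000 + 100 * i + si))
      hits[i, si] <- as.character(predictMl(
        spec, m, Xte[, cols, drop = FALSE])) == as.character(yf[i])
    }
  }
  acc <- colMeans(hits)
  bestSize <- sizes[max(which(acc == max(acc)))]   # smallest among ties
  bestCols <- fullSubsets[[which(sizes == bestSize)]]
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  new("RfeCurve", modelKind = spec$modelKind, sizes = as.integer(sizes),
      accuracy = acc, bestSize = as.integer(bestSize),
      bestSubset = nm[bestCols])
}

#' Top-k features by model importance
#'
#' Refits the classifier on the full (standardised) data and returns the
#' k highest-importance features, deterministically under the spec's seed.
#'
#' @inheritParams loocvAccuracy
#' @param k number of features (default 10; capped at the feature count).
#' @return Character vector of feature names, ranked.
#' @export
importanceTopk <- function(x, y, spec, k = 10, standardize = TRUE) {
  stopifnot(k >= 1)
  X <- asSampleMatrix(x)
  Xs <- if (standardize) standardizeFit(X)$X else X
  m <- fitMlForImportance(spec, Xs, factor(y), deriveSeed(spec$seed, 99))
  imp <- importanceMl(spec, m)
  nm <- colnames(X) %||% as.character(seq_len(ncol(X)))
  nm[order(imp, decreasing = TRUE)][seq_len(min(k, ncol(X)))]
}

#' Triangulate chemometric and machine-learning selections
#'
#' For each feature in the conventional (OPLS-DA + t-test) selection, counts
#' the ML models whose top-k contains it and flags it model-dependent when
#' its only supporters are PLS-family methods (the PLS-DA top-k and/or the
#' OPLS-based conventional selection itself).
#'
#' @param conventional character vector of conventionally selected feature
#'   names.
#' @param topkPerModel named list (one element per model kind) of ranked
#'   top-k feature-name vectors.
#' @return `data.frame` with per-feature membership flags, per-model rank,
#'   consensus count and the `modelDependent` flag.
#' @export
triangulate <- function(conventional, topkPerModel) {
  if (!length(conventional))
    return(data.frame(feature = character(0), consensusCount = integer(0),
                      modelDependent = logical(0)))
  models <- names(topkPerModel)
  out <- data.frame(feature = conventional, inConventional = TRUE)
  for (m in models) {
    out[[paste0("in_", m)]] <- conventional %in% topkPerModel[[m]]
    out[[paste0("rank_", m)]] <- match(conventional, topkPerModel[[m]])
  }
  inCols <- as.matrix(out[paste0("in_", models)])
  out$consensusCount <- rowSums(inCols)
  nonPls <- setdiff(models, "pls_da")
  out$modelDependent <- rowSums(inCols[, paste0("in_", nonPls),
                                       drop = FALSE]) == 0
  out
}
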