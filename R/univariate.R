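#' Per-feature two-sample t-tests with BH false-discovery control
#'
#' Student's pooled-variance t-test per feature (Welch's optional), with
#' Benjamini-Hochberg step-up q-values. Features that are constant and
#' identical in both groups get p = 1.
#'
#' @param x samples x features matrix (preprocessed) or [FeatureSet-class].
#' @param y binary labels.
#' @param varEqual pooled-variance Student's test (default) or Welch.
#' @return `data.frame` with per-feature `t`, `p` and `q`.
#' @export
tTestFdr <- function(x, y, varEqual = TRUE) {
  X <- asSampleMatrix(x)
  cl <- codeLabels(y)
  if (min(table(cl$y01)) < 2L) stop("need >= 2 samples per class")
  g1 <- cl$y01 == 0
  tt <- apply(X, 2, function(v) {
    res <- tryCatch(t.test(v[g1], v[!g1], var.equal = varEqual),
                    error = function(e) NULL)
    if (is.null(res)) c(t = 0, p = 1) else c(t = unname(res$statistic),
                                             p = res$p.value)
  })
  out <- data.frame(t = tt["t", ], p = tt["p", ],
                    q = p.adjust(tt["p", ], method = "BH"))
  rownames(out) <- colnames(X)
  out
}

#' Select discriminative features
#'
#' The conventional chemometric rule: VIP > `vipCut` in the OPLS-DA model
#' AND t-test p < `pCut` AND BH q < `qCut`.
#'
#' @param model an [OplsModel-class].
#' @param uni result of [tTestFdr()] on the same feature ordering.
#' @param vipCut,pCut,qCut thresholds (defaults 1, 0.05, 0.05).
#' @return Integer vector of selected feature indices (named when the
#'   univariate table carries feature names).
#' @export
selectDiscriminative <- function(model, uni, vipCut = 1, pCut = 0.05,
                                 qCut = 0.05) {
  stopifnot(is(model, "OplsModel"), length(model@vip) == nrow(uni))
  idx <- which(model@vip > vipCut & uni$p < pCut & uni$q < qCut)
  names(idx) <- rownames(uni)[idx]
  idx
}

#' Single-feature ROC analysis
#'
#' Threshold sweep over midpoints between consecutive distinct values,
#' trapezoidal AUC (equal to the Mann-Whitney concordance statistic), and
#' the Youden-optimal operating point. The direction is fixed (cases are
#' called above the threshold), so permuted labels give AUC ~ 0.5 on
#' average and an anti-discriminating feature gives AUC < 0.5.
#'
#' @param x numeric feature values.
#' @param y binary labels (first level = control).
#' @return List with `thresholds`, `sensitivity`, `specificity`, `auc` and
#'   `youden` (threshold, sensitivity, specificity at the optimum).
#' @export
univariateRoc <- function(x, y) {
  cl <- codeLabels(y)
  if (length(unique(x)) < 2L) {
    warning("constant feature; AUC set to 0.5")
    return(list(thresholds = numeric(0), sensitivity = numeric(0),
                specificity = numeric(0), auc = 0.5,
                youden = c(threshold = NA, sensitivity = NA,
                           specificity = NA)))
  }
  r <- pROC::roc(response = cl$y01, predictor = x, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  best <- pROC::coords(r, "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, ]                      # first optimum on ties
  list(thresholds = r$thresholds,
       sensitivity = r$sensitivities,
       specificity = r$specificities,
       auc = as.numeric(r$auc),
       youden = c(threshold = best$threshold,
                  sensitivity = best$sensitivity,
                  specificity = best$specificity))
}
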