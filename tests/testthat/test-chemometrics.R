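test_that("preprocessing implements TIC, log and Pareto as specified", {
  X <- rbind(c(2, 2, 4), c(1, 1, 2))
  tic <- preprocessMatrix(X, preprocessSpec(TRUE, FALSE, FALSE))
  expect_equal(tic[1, ], c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(tic)), c(1, 1))

  # Pareto turns a column of variance 16 into variance 4
  withr::with_seed(1, {
    Xp <- matrix(rnorm(200, sd = 4), 50, 4)
    Xp <- sweep(Xp, 2, apply(Xp, 2, sd) / 4, "/")   # force sd exactly 4
  })
  par <- preprocessMatrix(Xp, preprocessSpec(FALSE, FALSE, TRUE))
  expect_equal(unname(apply(par, 2, var)), rep(4, 4), tolerance = 1e-10)

  # constant column scales to zeros; zero row sum errors with the sample name
  Xc <- cbind(c(1, 1, 1), c(1, 2, 3))
  expect_equal(preprocessMatrix(Xc, preprocessSpec(FALSE, FALSE, TRUE))[, 1],
               c(0, 0, 0))
  Xz <- rbind(a = c(0, 0), b = c(1, 2))
  expect_error(preprocessMatrix(Xz, preprocessSpec(TRUE, FALSE, FALSE)), "a")
})

test_that("post-TIC statistics are invariant to per-sample rescaling", {
  withr::with_seed(7, X <- matrix(rexp(60, 1e-6), 6, 10))
  X2 <- X
  X2[3, ] <- X2[3, ] * 17.5
  expect_equal(preprocessMatrix(X, preprocessSpec()),
               preprocessMatrix(X2, preprocessSpec()), tolerance = 1e-12)
})

test_that("PCA handles rank deficiency and returns the requested components", {
  r1 <- tcrossprod(1:6, c(2, 1, 3))
  pc <- pcaModel(r1, 3)
  expect_gt(pc$explainedVar[1], 1 - 1e-10)

  withr::with_seed(3, Xbig <- matrix(rnorm(48 * 300), 48, 300))
  pc6 <- pcaModel(Xbig, 6)
  expect_equal(ncol(pc6$scores), 6)
  expect_equal(crossprod(pc6$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc6$explainedVar) <= 1e-12))
})

test_that("PCA separates extraction days on attenuated synthetic data", {
  d <- studyDesign(nFeaturesPerPolarity = 80, dayAttenuation = 0.7, seed = 17)
  st <- generateStudy(d, NULL)
  X <- extractStudyMatrix(st)
  Xp <- preprocessMatrix(X, preprocessSpec())
  pc <- pcaModel(Xp, 2)
  day <- ifelse(grepl("^d08", rownames(X)), 8, 16)
  # day groups separate along PC1: projections do not overlap
  s1 <- pc$scores[, 1]
  expect_true(max(s1[day == 16]) < min(s1[day == 8]) ||
                max(s1[day == 8]) < min(s1[day == 16]))
})

test_that("OPLS-DA recovers a dominant predictor and valid fit statistics", {
  withr::with_seed(5, {
    y <- rep(c(0, 1), each = 10)
    X <- cbind(y * 40 + rnorm(20, sd = 1e-4), matrix(rnorm(20 * 9), 20, 9))
  })
  m <- fitOplsDa(X, factor(y, labels = c("control", "lame")), nOrthogonal = 0)
  expect_gt(abs(m@weights[1, 1]), 0.999)
  expect_gt(m@R2Y, 0.999)
  expect_equal(mean(vipScores(m)^2), 1, tolerance = 1e-6)

  expect_error(fitOplsDa(X, rep("lame", 20)), "two classes")
})

test_that("OPLS-DA (1+1) predictions equal 2-component PLS predictions", {
  dat <- toyClassData(n0 = 9, n1 = 12, p = 30, nSignal = 3, shift = 1.5,
                      seed = 8)
  Xp <- preprocessMatrix(abs(dat$X) + 1, preprocessSpec())
  opls <- fitOplsDa(Xp, dat$y, nOrthogonal = 1)
  pls <- nipalsPls(Xp, dat$y, nComponents = 2)
  expect_equal(predict(opls, Xp), predict(pls, Xp), tolerance = 1e-8)
  # and on held-out-style data
  expect_equal(predict(opls, Xp[1:5, ] * 1), predict(pls, Xp[1:5, ]),
               tolerance = 1e-8)
})

test_that("OPLS-DA separates planted classes along the predictive score", {
  d <- studyDesign(nFeaturesPerPolarity = 60, seed = 23)
  eff <- do.call(rbind, lapply(c(5, 18, 33), function(i)
    effectSpec(i, "up", 2)))
  st <- generateStudy(d, eff)
  X <- extractStudyMatrix(st)
  keep <- grepl("^d08_[LC]", rownames(X))
  y <- factor(ifelse(grepl("_L", rownames(X)[keep]), "lame", "control"),
              levels = c("control", "lame"))
  Xp <- preprocessMatrix(X[keep, ], preprocessSpec())
  m <- fitOplsDa(Xp, y, 1)
  t1 <- m@scores[, 1]
  expect_gt(abs(mean(t1[y == "lame"]) - mean(t1[y == "control"])),
            sd(t1))
  # predictive and orthogonal scores are orthogonal
  expect_lt(abs(crossprod(m@scores[, 1], m@orthoScores[, 1])), 1e-6)
  # S-plot: covariance sign tracks the class mean difference for strong ions
  sp <- splotStats(m)
  expect_true(all(sp$correlation >= -1 - 1e-9 & sp$correlation <= 1 + 1e-9))
  dMean <- colMeans(Xp[y == "lame", ]) - colMeans(Xp[y == "control", ])
  big <- abs(dMean) > quantile(abs(dMean), 0.9)
  sgn <- sign(m@yCoef)   # orient the score toward the lame class
  expect_true(all(sign(sp$covariance[big] * sgn) == sign(dMean[big])))
})

test_that("LOOCV Q2 rewards signal and collapses under permuted labels", {
  d <- studyDesign(nFeaturesPerPolarity = 50, seed = 29)
  eff <- do.call(rbind, lapply(c(4, 21, 37), function(i)
    effectSpec(i, "up", 2)))
  st <- generateStudy(d, eff)
  X <- extractStudyMatrix(st)
  keep <- grepl("^d08_[LC]", rownames(X))
  y <- factor(ifelse(grepl("_L", rownames(X)[keep]), "lame", "control"),
              levels = c("control", "lame"))
  q2 <- loocvQ2(X[keep, ], y, 1, preprocessSpec())
  expect_gt(q2, 0.5)
  expect_lte(q2, 1)
  q2perm <- withr::with_seed(1, vapply(1:3, function(i)
    loocvQ2(X[keep, ], sample(y), 1, preprocessSpec()), numeric(1)))
  expect_true(all(q2perm < q2))
  expect_lte(median(q2perm), 0.1)
})

test_that("the permutation test reports valid empirical p-values", {
  dat <- toyClassData(n0 = 8, n1 = 8, p = 15, nSignal = 3, shift = 3,
                      seed = 12)
  pt <- oplsPermutationTest(abs(dat$X) + 1, dat$y, 1, nPerm = 50, seed = 3,
                            spec = preprocessSpec())
  expect_equal(pt$pQ2,
               (1 + sum(pt$nullQ2 >= pt$observedQ2)) / 51)
  expect_lte(pt$pQ2, 0.05)     # planted signal is detected
  expect_equal(pt$pR2Y,
               (1 + sum(pt$nullR2Y >= pt$observedR2Y)) / 51)
})

test_that("t-tests match the closed form and BH adjustment is correct", {
  X <- cbind(a = c(1, 2, 3, 7, 8, 9))
  y <- factor(c("control", "control", "control", "lame", "lame", "lame"),
              levels = c("control", "lame"))
  res <- tTestFdr(X, y)
  # pooled-variance Student t for {1,2,3} vs {7,8,9}: t = -6/sqrt(2/3)
  expect_equal(res$t, -7.348469, tolerance = 1e-6)
  expect_equal(res$p, 2 * pt(-7.348469, df = 4), tolerance = 1e-6)

  withr::with_seed(2, Xn <- matrix(rnorm(6 * 4), 6, 4))
  resn <- tTestFdr(Xn, y)
  expect_true(all(resn$q >= resn$p))
  expect_equal(resn$q, oracleBH(resn$p))

  # identical groups: p ~ 1; constant equal columns: p = 1 exactly
  Xs <- cbind(rep(c(1, 2, 3), 2), rep(5, 6))
  ress <- tTestFdr(Xs, y)
  expect_gt(ress$p[1], 0.99)
  expect_equal(ress$p[2], 1)
})

test_that("discriminative-ion selection applies the VIP/p/q gates", {
  m <- new("OplsModel", nPredictive = 1L, nOrthogonal = 0L,
           scores = matrix(0, 2, 1), loadings = matrix(0, 3, 1),
           weights = matrix(0, 3, 1), orthoScores = matrix(0, 2, 0),
           orthoLoadings = matrix(0, 3, 0), orthoWeights = matrix(0, 3, 0),
           yCoef = 1, xMeans = rep(0, 3), yMean = 0.5, R2X = 0.5, R2Y = 0.5,
           vip = c(1.2, 0.9, 1.5), splotCov = rep(0, 3),
           splotCorr = rep(0, 3), levels = c("control", "lame"),
           fitted = c(0, 1))
  uni <- data.frame(t = c(3, 4, 1), p = c(0.01, 0.001, 0.2),
                    q = c(0.03, 0.001, 0.4),
                    row.names = c("f1", "f2", "f3"))
  sel <- selectDiscriminative(m, uni)
  expect_equal(names(sel), "f1")        # f2 fails VIP, f3 fails p/q
  expect_length(selectDiscriminative(m, transform(uni, p = 1)), 0)
})

test_that("single-feature ROC matches the exhaustive pair-count oracle", {
  r <- univariateRoc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(unname(r$youden["sensitivity"]), 1)
  expect_equal(unname(r$youden["specificity"]), 1)

  withr::with_seed(10, {
    for (i in 1:20) {
      n <- sample(6:15, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      x <- sample(1:6, n, replace = TRUE)   # ties included
      expect_equal(univariateRoc(x, y)$auc, oracleAuc(x, y))
    }
  })

  # permuted labels average to chance
  withr::with_seed(4, {
    aucs <- vapply(1:40, function(i) {
      x <- rnorm(20)
      univariateRoc(x, sample(rep(0:1, 10)))$auc
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.07)

  expect_warning(rc <- univariateRoc(rep(1, 6), rep(0:1, 3)), "constant")
  expect_equal(rc$auc, 0.5)
})
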