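test_that("standardisation is exact and leaks nothing across folds", {
  withr::with_seed(1, X <- matrix(rexp(80, 1e-5), 8, 10))
  Xs <- standardizeMatrix(X)
  expect_equal(unname(colMeans(Xs)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(Xs, 2, var)), rep(1, 10), tolerance = 1e-10)

  Xc <- cbind(X, const = 5)
  expect_warning(Xsc <- standardizeMatrix(Xc, ticNormalize = FALSE),
                 "constant")
  expect_equal(unname(Xsc[, 11]), rep(0, 8))

  # fold statistics must come from the training rows only
  fit <- standardizeFit(X[-1, , drop = FALSE])
  held <- standardizeApply(fit, X[1, , drop = FALSE])
  whole <- standardizeMatrix(X)[1, ]
  expect_false(isTRUE(all.equal(drop(held), whole)))
  expect_false(isTRUE(all.equal(fit$center,
                                attr(standardizeMatrix(X), "fit")$center)))
})

test_that("LOOCV accuracy is perfect on separable data for all four models", {
  dat <- toyClassData(n0 = 10, n1 = 11, p = 8, nSignal = 2, shift = 8,
                      seed = 2)
  X <- abs(dat$X) + 1
  for (kind in c("random_forest", "elastic_net", "pls_da", "svm")) {
    acc <- loocvAccuracy(X, dat$y, mlSpec(kind, seed = 5))
    expect_equal(acc, 1, info = kind)
  }
})

test_that("LOOCV runs one fold per cow and collapses under shuffled labels", {
  dat <- toyClassData(n0 = 10, n1 = 11, p = 6, nSignal = 1, shift = 2,
                      seed = 3)
  X <- abs(dat$X) + 1
  acc <- loocvAccuracy(X, dat$y, mlSpec("pls_da"))
  # 21 folds: accuracy has granularity 1/21
  expect_equal(acc * 21, round(acc * 21), tolerance = 1e-9)

  accs <- withr::with_seed(9, vapply(1:15, function(i)
    loocvAccuracy(X, sample(dat$y), mlSpec("pls_da")), numeric(1)))
  expect_lt(abs(mean(accs) - 0.5), 0.12)

  expect_error(loocvAccuracy(X[c(1, 11, 12), ], dat$y[c(1, 11, 12)],
                             mlSpec("pls_da")), "degenerate")
})

test_that("the RFE ladder halves to 20 then steps by one", {
  expect_equal(milkDIMS:::rfeSizes(100L), c(100L, 50L, 25L, 13:1))
  expect_equal(milkDIMS:::rfeSizes(21L), c(21L, 11:1))
  expect_equal(milkDIMS:::rfeSizes(5L), 5:1)
  s <- milkDIMS:::rfeSizes(300L)
  expect_true(all(diff(s) < 0))
  expect_equal(tail(s, 1), 1L)
})

test_that("RFE finds a single separating feature and reports a valid curve", {
  withr::with_seed(6, {
    y <- factor(rep(c("control", "lame"), c(8, 8)))
    X <- cbind(sep = rep(c(0, 10), c(8, 8)) + rnorm(16, sd = 0.1),
               matrix(rnorm(16 * 11), 16, 11))
    colnames(X)[-1] <- paste0("n", 1:11)
  })
  curve <- rfe(abs(X) + 1, y, mlSpec("svm"), standardize = TRUE)
  expect_s4_class(curve, "RfeCurve")
  expect_true(all(diff(curve@sizes) < 0))
  expect_equal(min(curve@sizes), 1L)
  expect_equal(curve@accuracy[curve@sizes == 1], 1)
  expect_equal(curve@bestSize, 1L)          # smallest size among ties
  expect_equal(curve@bestSubset, "sep")

  expect_error(rfe(X, y, mlSpec("svm", hyper = list(kernel = "radial"))),
               "linear")
})

test_that("RFE recovers planted informative features among noise", {
  # individually weak, jointly strong signals: no single feature should tie
  # the maximum accuracy, so the best subset must keep all three
  dat <- toyClassData(n0 = 14, n1 = 14, p = 40, nSignal = 3, shift = 2,
                      seed = 19)
  curve <- rfe(abs(dat$X) + 1, dat$y, mlSpec("svm", seed = 7))
  expect_gte(curve@bestSize, 3)
  expect_true(all(c("f1", "f2", "f3") %in% curve@bestSubset))
  expect_gte(max(curve@accuracy), 0.85)
})

test_that("importance rankings put a lone signal first for every model", {
  dat <- toyClassData(n0 = 9, n1 = 9, p = 10, nSignal = 1, shift = 8,
                      seed = 4)
  X <- abs(dat$X) + 1
  for (kind in c("random_forest", "elastic_net", "pls_da", "svm")) {
    topk <- importanceTopk(X, dat$y, mlSpec(kind, seed = 2), k = 3)
    expect_equal(topk[1], "f1", info = kind)
  }
  all10 <- importanceTopk(X, dat$y, mlSpec("svm"), k = 50)
  expect_setequal(all10, colnames(X))

  # RF rank-1 stability across seeds for a strong effect
  rank1 <- vapply(1:5, function(s)
    importanceTopk(X, dat$y, mlSpec("random_forest", seed = s), k = 1),
    character(1))
  expect_true(all(rank1 == "f1"))
})

test_that("triangulation flags PLS-only features as model-dependent", {
  topk <- list(random_forest = c("a", "b"), elastic_net = c("a", "c"),
               pls_da = c("a", "d"), svm = c("a", "b"))
  rep <- triangulate(c("a", "d", "e"), topk)
  expect_equal(rep$consensusCount[rep$feature == "a"], 4)
  expect_false(rep$modelDependent[rep$feature == "a"])
  # "d" is only in the PLS top-k (the glucosamine/alpha-lactose pattern)
  expect_true(rep$modelDependent[rep$feature == "d"])
  # "e" is supported by nothing beyond the conventional OPLS selection
  expect_true(rep$modelDependent[rep$feature == "e"])
  expect_equal(nrow(triangulate(character(0), topk)), 0)
})
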