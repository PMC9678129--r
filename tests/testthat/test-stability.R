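test_that("penalised fits shrink fully under a huge penalty and approach the
           unpenalised fit under a vanishing one", {
  withr::with_seed(1, {
    X <- matrix(rnorm(40 * 6), 40, 6)
    yg <- drop(X %*% c(2, -1, 0, 0, 0.5, 0)) + rnorm(40, sd = 0.3)
    yb <- factor(ifelse(drop(X %*% c(2, -1, 0, 0, 0, 0)) > 0, "b", "a"))
  })
  for (pen in c("elastic_net", "lasso", "mcp")) {
    big <- fitPenalised(X, yb, penalisedSpec(pen, lambdaRule = "fixed",
                                             lambda = 1e4))
    expect_true(all(big == 0), info = pen)
  }
  ols <- coef(lm(yg ~ X))[-1]
  near0 <- fitPenalised(X, yg, penalisedSpec("mcp", lambdaRule = "fixed",
                                             lambda = 1e-8,
                                             family = "gaussian"))
  expect_equal(unname(near0), unname(ols), tolerance = 1e-4)
})

test_that("the MCP solution matches the firm-threshold closed form on an
           orthonormal design", {
  withr::with_seed(2, {
    n <- 48
    Q <- qr.Q(qr(matrix(rnorm(n * 6), n)))
    Xo <- sweep(Q * sqrt(n), 2, colMeans(Q * sqrt(n)))   # mean 0, ||x||^2/n ~ 1
    # re-orthonormalise after centring
    Xo <- qr.Q(qr(Xo)) * sqrt(n)
    y <- drop(Xo %*% c(1.8, -0.9, 0.45, 0.1, 0, 0)) + rnorm(n, sd = 0.2)
  })
  firm <- function(z, l, g)
    ifelse(abs(z) <= g * l, pmax(abs(z) - l, 0) * sign(z) / (1 - 1 / g), z)
  bOls <- drop(crossprod(Xo, y - mean(y))) / n
  for (lam in c(0.1, 0.4, 0.8)) {
    beta <- mcpPath(Xo, y, lam, gamma = 3, family = "gaussian",
                    tol = 1e-12)[-1, 1]
    expect_equal(unname(beta), unname(firm(bOls, lam, 3)), tolerance = 1e-6,
                 info = paste("lambda", lam))
  }
})

test_that("MCP converges to the Lasso as gamma grows", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    y <- drop(X %*% c(1.5, -1, rep(0, 8))) + rnorm(30, sd = 0.5)
  })
  b <- mcpPath(X, y, 0.2, gamma = 1e8, family = "gaussian", tol = 1e-10)[-1, 1]
  gl <- as.numeric(coef(glmnet::glmnet(X, y, alpha = 1, lambda = 0.2,
                                       thresh = 1e-14)))[-1]
  expect_lt(max(abs(b - gl)), 1e-4)
})

test_that("stability scores have bootstrap granularity and find a perfect
           predictor", {
  withr::with_seed(3, {
    y <- factor(rep(c("control", "lame"), c(10, 11)),
                levels = c("control", "lame"))
    X <- cbind(sig = as.numeric(y) - 1 + rnorm(21, sd = 0.05),
               matrix(rnorm(21 * 9), 21, 9))
    colnames(X)[-1] <- paste0("n", 1:9)
  })
  one <- stabilityScores(X, y, penalisedSpec("lasso"), nBoot = 1, seed = 2)
  expect_true(all(one@stabilityScore %in% c(0, 100)))

  sc <- stabilityScores(X, y, penalisedSpec("elastic_net"), nBoot = 40,
                        seed = 2)
  expect_gte(sc@stabilityScore[1], 95)
  expect_identical(sc@coefRecord,
                   stabilityScores(X, y, penalisedSpec("elastic_net"),
                                   nBoot = 40, seed = 2)@coefRecord)
})

test_that("the permutation threshold is deterministic and bounded", {
  withr::with_seed(6, {
    y <- factor(rep(c("control", "lame"), c(10, 11)))
    X <- matrix(rnorm(21 * 10), 21, 10)
  })
  th1 <- permutationThreshold(X, y, penalisedSpec("lasso"), nPerm = 3,
                              nPermBoot = 10, seed = 7)
  th2 <- permutationThreshold(X, y, penalisedSpec("lasso"), nPerm = 3,
                              nPermBoot = 10, seed = 7)
  expect_identical(th1, th2)
  expect_gte(th1, 0)
  expect_lte(th1, 100)
})

test_that("bootstrap p-values implement the minority-side definition", {
  expect_equal(bootstrapP(c(rep(1, 95), rep(-1, 5))), 0.05)
  expect_equal(bootstrapP(rep(2.3, 17)), 0)
  expect_equal(bootstrapP(c(rep(1, 5), rep(-1, 5))), 0.5)
  # zeros are excluded from both counts; never-selected is undefined
  expect_equal(bootstrapP(c(0, 0, 1, 1, -1)), 1 / 3)
  expect_true(is.na(bootstrapP(numeric(0))))
  expect_true(is.na(bootstrapP(c(0, 0))))

  m <- cbind(a = c(1, 1, -1), b = c(0, 0, 0))
  expect_equal(unname(bootstrapP(m)), c(1 / 3, NA))
})

test_that("stable-set selection is strict at the threshold", {
  res <- new("StabilityResult", penalty = "elastic_net",
             featureNames = c("a", "b", "c"),
             coefRecord = rbind(c(1, 1, 1), c(1, -1, 0)),
             selectionCount = c(2L, 2L, 1L),
             stabilityScore = c(80, 40, 50), bootstrapP = c(0, 0.5, 0),
             threshold = 40, nBootstraps = 2L, nPermutations = 0L,
             nPermutationBootstraps = 0L)
  expect_equal(selectStable(res), c("a", "c"))         # b: p too high
  expect_equal(selectStable(res, threshold = 50), "a") # c: score == threshold
  expect_equal(selectStable(res, threshold = 90), character(0))
  tab <- stabilityTable(res)
  expect_equal(tab$feature[1], "a")
  expect_true(tab$selected[tab$feature == "a"])
})

test_that("null data rarely produce scores above the permutation threshold", {
  hits <- withr::with_seed(31, vapply(1:8, function(r) {
    y <- factor(rep(c("control", "lame"), c(10, 11)))
    X <- matrix(rnorm(21 * 15), 21, 15)
    spec <- penalisedSpec("elastic_net")
    th <- permutationThreshold(X, y, spec, nPerm = 5, nPermBoot = 15,
                               seed = 100 + r)
    sc <- stabilityScores(X, y, spec, nBoot = 30, seed = 200 + r)
    any(sc@stabilityScore > th)
  }, logical(1)))
  expect_lte(mean(hits), 0.25)
})

test_that("stability scores rise monotonically with planted effect size", {
  med <- vapply(c(0.5, 1.5, 2.5), function(effect) {
    d <- studyDesign(nFeaturesPerPolarity = 20, seed = 77)
    st <- generateStudy(d, effectSpec(5, "up", effect))
    X <- extractStudyMatrix(st)
    keep <- grepl("^d08_[LC]", rownames(X))
    y <- factor(ifelse(grepl("_L", rownames(X)[keep]), "lame", "control"),
                levels = c("control", "lame"))
    Xs <- suppressWarnings(standardizeMatrix(X[keep, ]))
    colMz <- as.numeric(sub("^pos_", "", colnames(X)))
    target <- which.min(abs(colMz - st$truth$effects$trueMz[1]))
    sc <- stabilityScores(Xs, y, penalisedSpec("elastic_net"), nBoot = 30,
                          seed = 5)
    sc@stabilityScore[target]
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})
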