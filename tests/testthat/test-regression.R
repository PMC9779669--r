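test_that("z-score standardization is exact, idempotent and reusable", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 2, 1))
  expect_warning(std <- standardizeFeatures(X), "constant")
  expect_equal(unname(std$X[, "a"]), c(-1, 0, 1))
  expect_identical(std$dropped, "b")
  again <- standardizeFeatures(std$X)
  expect_equal(again$X, std$X, tolerance = 1e-12)
  ## the stored transform reapplies training statistics to new data
  newX <- cbind(a = c(4, 0), c = c(3, 3))
  expect_equal(unname(applyStandardization(std, newX)[, "a"]), c(2, -2))
})

test_that("a noiseless response gives unit fraction explained and R2", {
  X <- cbind(f = rnorm(100))
  rep <- suppressWarnings(
    singleFeatureModel(X, 3 * X[, "f"], "f", nRepeats = 20, seed = 1))
  expect_equal(rep$fractionExplained, 1, tolerance = 1e-12)
  expect_equal(rep$predictedR2, 1, tolerance = 1e-12)
})

test_that("null features have predicted R2 near zero and below training R2", {
  set.seed(2)
  X <- cbind(f = rnorm(500))
  y <- rnorm(500)
  rep <- singleFeatureModel(X, y, "f", nRepeats = 200, seed = 3)
  expect_lt(abs(rep$predictedR2), 0.05)
  expect_gt(rep$fractionExplained, rep$predictedR2)
})

test_that("two orthogonal features with planted 0.2 each combine to 0.4", {
  n <- 4000
  set.seed(4)
  X <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)
  colnames(X) <- c("u", "v")
  ## each feature explains 0.2 of the response variance
  y <- X[, 1] * sqrt(0.2) + X[, 2] * sqrt(0.2) + rnorm(n, sd = sqrt(0.6))
  rep <- multiFeatureModel(X, y, c("u", "v"), nRepeats = 50, seed = 5)
  expect_equal(rep$fractionExplained, 0.4, tolerance = 0.05)
  r1 <- singleFeatureModel(X, y, "u", nRepeats = 50, seed = 5)
  expect_equal(r1$fractionExplained, 0.2, tolerance = 0.05)
})

test_that("the sparse 1se lasso recovers a planted orthogonal support", {
  ft <- simFeatureTable(nGenes = 2000, nFeatures = 100, populationR2 = 0.4,
                        seed = 6)
  Xo <- qr.Q(qr(ft$X)) * sqrt(nrow(ft$X))
  colnames(Xo) <- colnames(ft$X)
  set.seed(6)
  yo <- drop(Xo %*% ft$trueCoefficients) + rnorm(nrow(Xo), sd = ft$noiseSd)
  sel <- selectFeatures(Xo, yo, "lasso", lambdaRule = "1se", seed = 6)
  truth <- colnames(Xo)[ft$trueCoefficients != 0]
  expect_setequal(sel, truth)
})

test_that("lasso shares the weight of a perfectly collinear pair", {
  ft <- simFeatureTable(nGenes = 500, nFeatures = 10, populationR2 = 0.5,
                        seed = 7)
  X <- cbind(ft$X, dup001 = ft$X[, 1])
  sel <- selectFeatures(X, ft$response, "lasso", seed = 7)
  ## the duplicated signal is selected (in one or both copies), and the
  ## selection changes nothing downstream: a refit on the de-duplicated
  ## selected set has the same R2 as on the original features
  expect_true(any(c("feat001", "dup001") %in% sel))
  dedup <- unique(sub("dup001", "feat001", sel))
  r2dup <- summary(lm(ft$response ~ X[, sel]))$r.squared
  r2 <- summary(lm(ft$response ~ ft$X[, dedup]))$r.squared
  expect_equal(r2, r2dup, tolerance = 1e-8)
})

test_that("ridge significance selection finds strong effects", {
  ft <- simFeatureTable(nGenes = 1000, nFeatures = 20, populationR2 = 0.5,
                        seed = 8)
  sel <- selectFeatures(ft$X, ft$response, "ridge", seed = 8)
  truth <- colnames(ft$X)[ft$trueCoefficients != 0]
  expect_true(all(truth %in% sel))
})

test_that("stepwise AIC never exceeds the full model and matches exhaustive", {
  set.seed(9)
  for (case in 1:2) {
    X <- matrix(rnorm(250 * 7), 250, 7,
                dimnames = list(NULL, paste0("f", 1:7)))
    beta <- numeric(7); beta[sample(7, 2)] <- c(0.7, -0.5)
    y <- drop(X %*% beta) + rnorm(250)
    sel <- stepwiseAIC(X, y)
    expect_identical(sort(as.character(sel)), oracleBestSubsetAIC(X, y))
    full <- AIC(lm(y ~ ., data = data.frame(y = y, X)))
    expect_lte(attr(sel, "AIC"), full)
  }
})

test_that("feature filters keep impactful features and drop null ones", {
  set.seed(10)
  n <- 3000
  x1 <- rnorm(n); x0 <- rnorm(n)
  ## planted single-feature R2 of 0.06 for x1
  y <- x1 * sqrt(0.06) + rnorm(n, sd = sqrt(0.94))
  X <- cbind(sig = x1, nul = x0)
  kept <- filterFeatures(X, y, "impact", nRepeats = 50, seed = 10)
  expect_true("sig" %in% kept)
  expect_false("nul" %in% kept)
  keptC <- filterFeatures(X, y, "correlation")
  expect_true("sig" %in% keptC)
  expect_false("nul" %in% keptC)
})

test_that("feature rankings are reproducible and correlate for shared truth", {
  ft <- simFeatureTable(nGenes = 400, nFeatures = 8,
                        trueCoefficients = c(2, 1, 0.5, 0, 0, 0, 0, 0),
                        noiseSd = 1, seed = 11)
  ## identical responses: rank correlation exactly 1
  rk <- rankFeatures(ft$X, ft$response, ft$response, nRepeats = 20,
                     seed = 11)
  expect_equal(unname(rk$rankCorrelation["fractionExplained"]), 1)
  expect_equal(unname(rk$rankCorrelation["predictedR2"]), 1)
  ## two noisy realizations of the same generative model: positive
  y2 <- drop(ft$X %*% ft$trueCoefficients) + rnorm(400, sd = ft$noiseSd)
  rk2 <- rankFeatures(ft$X, ft$response, y2, nRepeats = 20, seed = 11)
  expect_gt(rk2$rankCorrelation["fractionExplained"], 0.5)
})

test_that("model reports are bit-reproducible under a master seed", {
  ft <- simFeatureTable(nGenes = 300, nFeatures = 5, seed = 12)
  a <- multiFeatureModel(ft$X, ft$response, colnames(ft$X)[1:3],
                         nRepeats = 25, seed = 99)
  b <- multiFeatureModel(ft$X, ft$response, colnames(ft$X)[1:3],
                         nRepeats = 25, seed = 99)
  expect_identical(a, b)
})
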