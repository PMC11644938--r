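test_that("overall accuracy and kappa reproduce hand-computed values", {
  cm <- matrix(c(25, 10, 5, 60), 2)  # rows truth, cols prediction
  expect_equal(overallAccuracy(cm), 0.85)
  ## p_o = 0.85, p_e = 0.56 -> kappa = 0.29 / 0.44
  expect_equal(cohensKappa(cm), 0.29 / 0.44, tolerance = 1e-10)

  d <- diag(c(3, 7, 9))
  expect_equal(overallAccuracy(d), 1)
  expect_equal(cohensKappa(d), 1)
  expect_equal(overallAccuracy(matrix(1, 2, 2)), 0.5)

  ## independence with matching marginals gives kappa exactly 0
  expect_equal(cohensKappa(matrix(c(9, 21, 21, 49), 2)), 0)

  expect_error(overallAccuracy(matrix(numeric(0), 0, 0)),
               class = "bsdr_data_error")
  expect_error(cohensKappa(matrix(c(5, 0, 0, 0), 2)),
               class = "bsdr_data_error")
})

test_that("kappa never exceeds overall accuracy on fuzzed confusion matrices", {
  set.seed(99)
  for (i in 1:300) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, lambda = sample(1:20, 1)), K)
    if (sum(cm) == 0) next
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (pe >= 1) next
    expect_lte(cohensKappa(cm), overallAccuracy(cm) + 1e-12)
  }
})

test_that("accuracy is invariant under simultaneous label permutation", {
  set.seed(12)
  cm <- matrix(rpois(16, 6), 4)
  pm <- sample(4)
  expect_equal(overallAccuracy(cm[pm, pm]), overallAccuracy(cm))
  expect_equal(cohensKappa(cm[pm, pm]), cohensKappa(cm))
})

test_that("regression metrics match their definitions", {
  y <- c(1.2, 0.4, 2.5, 1.9)
  perfect <- regressionMetrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  null <- regressionMetrics(y, rep(mean(y), 4))
  expect_equal(null$r2, 0)
  expect_equal(null$rmse, sd(y) * sqrt(3 / 4))  # population sd

  m <- regressionMetrics(c(0, 2), c(1, 1))
  expect_equal(m$r2, 0)
  expect_equal(m$rmse, 1)

  const <- regressionMetrics(c(1, 1, 1), c(1, 0.5, 1))
  expect_true(is.na(const$r2))
  expect_gt(const$rmse, 0)
  expect_error(regressionMetrics(1:3, 1:2), class = "bsdr_data_error")
})

test_that("an SVM on a target that is a function of one selected band fits regression almost perfectly", {
  set.seed(8)
  g <- generateSpectra(syntheticSpec(800, 60, 30, task = "regression",
                                     noiseSd = 0, seed = 14))
  plan <- makeSplitPlan(800, 1, seed = 5)
  res <- evaluateBandsSVM(g$dataset, 30L, plan)
  expect_gte(res$r2, 0.99)
  expect_identical(res$t_prime, 1L)
})

test_that("SVM evaluation flags a class missing from its training split", {
  set.seed(4)
  X <- matrix(runif(80 * 10), 80, 10)
  y <- rep(0:1, each = 40)
  ds <- spectralSet(X, y, "classification")
  ## plan engineered so class 1 is absent from svmTrain (indices 1:4
  ## are all class 0)
  plan <- new("SplitPlan", bsTrain = 11:50, bsValidation = 5:10,
              svmTrain = 1:4, svmTest = 61:80,
              foldId = 1L, nFolds = 10L, seed = 1L)
  expect_error(evaluateBandsSVM(ds, c(1, 2), plan),
               class = "bsdr_data_error")
})

test_that("cross-validation has the promised shape and its summary matches a hand aggregation", {
  g <- smallRegression(n = 200, L = 40, planted = c(12, 30))
  trivial <- function(x, plan, targetSize, seed)
    new("SelectedBandSet", bands = seq_len(bandCount(x)),
        targetSize = bandCount(x))
  res <- crossValidate(g$dataset, trivial, targetSizes = 40, seed = 3,
                       folds = 1:3, selectorName = "trivial")

  expect_identical(nrow(res), 6L)  # (baseline + one size) x 3 folds
  ## the identity selector reproduces the all-bands baseline per fold
  for (k in 1:3) {
    a <- res[res$selector == "all_bands" & res$fold == k, ]
    b <- res[res$selector == "trivial" & res$fold == k, ]
    expect_equal(a$r2, b$r2)
    expect_equal(a$rmse, b$rmse)
  }

  summ <- summarizeCrossValidation(res)
  expect_identical(nrow(summ), 2L)
  byHand <- res[res$selector == "trivial", "rmse"]
  row <- summ[summ$selector == "trivial", ]
  expect_equal(row$rmse_mean, mean(byHand))
  expect_equal(row$rmse_sd, sd(byHand))
  expect_identical(row$n_folds, 3L)

  ## reproducibility of the whole harness
  res2 <- crossValidate(g$dataset, trivial, targetSizes = 40, seed = 3,
                        folds = 1:3, selectorName = "trivial")
  expect_equal(res, res2)
})

test_that("the exhaustive oracle enumerates C(L, t) subsets and finds planted bands", {
  g <- generateSpectra(syntheticSpec(300, 10, c(3, 8), task = "regression",
                                     smoothness = 1, noiseSd = 0.01,
                                     seed = 21))
  plan <- makeSplitPlan(300, 1, seed = 9)
  bf <- bruteForceSubsetSearch(g$dataset, 2, plan)
  expect_identical(bf$nEvaluated, 45L)
  expect_true(all(c(3L, 8L) %in% bands(bf$bands)))

  ## t = L degenerates to the all-bands baseline
  bfAll <- bruteForceSubsetSearch(g$dataset, 10, plan)
  base <- evaluateBandsSVM(g$dataset, 1:10, plan)
  expect_equal(bfAll$metric, base$rmse)

  expect_error(bruteForceSubsetSearch(g$dataset, 5, plan, maxSubsets = 10),
               class = "bsdr_config_error")
})
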