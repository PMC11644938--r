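test_that("band parameters initialize linearly spaced, strictly interior", {
  expect_equal(initBandParams(1, 10)$normalized, 0.5)
  expect_equal(initBandParams(3, 100)$normalized, c(0.25, 0.5, 0.75))
  ## raw params are the inverse-sigmoid images
  ip <- initBandParams(3, 100)
  expect_equal(plogis(ip$raw), ip$normalized)
  ## initial integer preview for t = 4 on a 131-band spectrum
  r4 <- initBandParams(4, 131)$normalized
  expect_identical(bands(extractBands(r4, 131)), c(27L, 53L, 79L, 105L))
  expect_error(initBandParams(0, 10), class = "bsdr_config_error")
  expect_error(initBandParams(10, 10), class = "bsdr_config_error")
})

test_that("closed-form parameter count matches the instantiated model for many (t, K)", {
  for (t in c(1, 5, 12)) {
    for (K in c(1, 5, 16)) {
      bp <- initBandParams(t, 300)
      inf <- initInferenceParams(t, K, seed = 3)
      expect_identical(countModelScalars(bp$raw, inf), countParameters(t, K))
    }
  }
  ## each unit increase in target size adds exactly 129 parameters
  d <- diff(vapply(1:10, countParameters, 1L, K = 7))
  expect_true(all(d == 129L))
})

test_that("forward pass is linear in the weights, batch-consistent and deterministic", {
  set.seed(21)
  X <- matrix(runif(8 * 40), 8, 40)
  raw <- initBandParams(3, 40)$raw
  inf <- initInferenceParams(3, 4, seed = 2)

  ## zero weights and biases produce all-zero scores
  zero <- lapply(inf, function(p) p * 0)
  expect_true(all(bsdrForward(X, raw, zero) == 0))

  ## a single row equals the batched row applied singly
  full <- bsdrForward(X, raw, inf)
  one <- bsdrForward(X[3, , drop = FALSE], raw, inf)
  expect_equal(one[1, ], full[3, ])

  ## repeated evaluation is bit-identical
  expect_identical(full, bsdrForward(X, raw, inf))
})

test_that("losses reproduce closed-form values", {
  expect_equal(bsdrLoss(matrix(c(1, 1)), c(0, 2), "regression"), 1.0)
  expect_equal(bsdrLoss(matrix(c(1, 2), ncol = 1), c(1, 2), "regression"), 0)
  ## uniform class scores give cross-entropy ln K
  for (K in c(2, 5, 16)) {
    sc <- matrix(0, 7, K)
    y <- sample(0:(K - 1), 7, replace = TRUE)
    expect_equal(bsdrLoss(sc, y, "classification"), log(K))
  }
  expect_error(bsdrLoss(matrix(0, 2, 3), c(0, 3), "classification"),
               class = "bsdr_data_error")
})

test_that("model gradients match finite differences on a tiny instance", {
  set.seed(31)
  X <- matrix(runif(6 * 12), 6, 12)
  y <- runif(6)
  raw <- initBandParams(2, 12)$raw
  inf <- initInferenceParams(2, 1, hiddenSizes = c(4L, 3L), seed = 7)
  gradFn <- bsdr:::bsdrGradients
  g <- gradFn(X, y, raw, inf, "regression", 0.01)
  h <- 1e-6
  for (p in 1:2) {
    rp <- raw; rp[p] <- rp[p] + h
    rm_ <- raw; rm_[p] <- rm_[p] - h
    fd <- (gradFn(X, y, rp, inf, "regression", 0.01)$loss -
             gradFn(X, y, rm_, inf, "regression", 0.01)$loss) / (2 * h)
    expect_equal(g$gRaw[p], fd, tolerance = 1e-4)
  }
  ## spot-check one weight matrix too
  ij <- cbind(c(1, 2), c(1, 3))
  for (k in 1:2) {
    up <- inf; up$W1[ij[k, 1], ij[k, 2]] <- up$W1[ij[k, 1], ij[k, 2]] + h
    dn <- inf; dn$W1[ij[k, 1], ij[k, 2]] <- dn$W1[ij[k, 1], ij[k, 2]] - h
    fd <- (gradFn(X, y, raw, up, "regression", 0.01)$loss -
             gradFn(X, y, raw, dn, "regression", 0.01)$loss) / (2 * h)
    expect_equal(g$grads$W1[ij[k, 1], ij[k, 2]], fd, tolerance = 1e-4)
  }
})

test_that("extraction rounds, deduplicates, sorts and is idempotent", {
  s <- extractBands(c(0, 0.5, 1), 131)
  expect_identical(bands(s), c(1L, 66L, 131L))
  expect_identical(tPrime(s), 3L)

  ## two relaxed indices converged to the same band: t' = t - 1
  dup <- extractBands(c(0.6920, 0.6925, 0.30), 131)
  expect_identical(bands(dup), c(40L, 91L))
  expect_identical(tPrime(dup), 2L)
  expect_identical(dup@targetSize, 3L)

  ## all-distinct mapping keeps t' = t
  dis <- extractBands(c(0.1, 0.5, 0.9), 131)
  expect_identical(tPrime(dis), 3L)

  ## re-embedding the extracted bands at their centers is a fixed point
  L <- 131
  centers <- (bands(dis) - 1) / (L - 1)
  expect_identical(bands(extractBands(centers, L)), bands(dis))
})

test_that("training is reproducible, tracks every epoch, and fits a constant target", {
  set.seed(2)
  X <- matrix(runif(120 * 20), 120, 20)
  ds <- spectralSet(X, rep(0.3, 120), "regression")
  plan <- makeSplitPlan(120, 1, seed = 4)
  cfg <- bsdrConfig(2, epochs = 60, seed = 8)

  f1 <- bsdrTrain(ds, plan, cfg)
  f2 <- bsdrTrain(ds, plan, cfg)
  expect_identical(f1@rawParams, f2@rawParams)
  expect_identical(trainingTrace(f1), trainingTrace(f2))
  expect_identical(bands(selectedBands(f1)), bands(selectedBands(f2)))

  tr <- trainingTrace(f1)
  expect_identical(nrow(tr), 60L)
  expect_true(all(tr$band_1 >= 1 & tr$band_2 <= 20))
  ## a constant target is learnable: the loss falls well below the
  ## trivial zero-prediction loss of 0.09 and keeps falling
  expect_lt(tail(tr$train_loss, 1), 0.01)
  expect_lt(tail(tr$train_loss, 1), tr$train_loss[1])
  ## normalized indices stayed strictly interior throughout
  expect_true(all(plogis(f1@rawParams) > 0 & plogis(f1@rawParams) < 1))
})

test_that("a single planted band is recovered by joint training", {
  ## one informative band at normalized position 0.6 of a 100-band axis
  L <- 100
  planted <- round(0.6 * (L - 1)) + 1
  g <- generateSpectra(syntheticSpec(500, L, planted, task = "regression",
                                     noiseSd = 0.02, seed = 17))
  plan <- makeSplitPlan(500, 1, seed = 6)
  fit <- bsdrTrain(g$dataset, plan, bsdrConfig(1, seed = 3))
  got <- bands(selectedBands(fit))
  expect_length(got, 1)
  expect_lte(abs(got - planted), 0.02 * L)
})

test_that("model predictions and task guards behave", {
  g <- smallRegression(n = 120, L = 30, planted = c(10, 22))
  plan <- makeSplitPlan(120, 1, seed = 2)
  fit <- bsdrTrain(g$dataset, plan, bsdrConfig(2, epochs = 30, seed = 1))
  pr <- predictModel(fit, g$dataset)
  expect_length(pr, 120)
  expect_true(is.numeric(pr))
  ## t >= L is refused
  expect_error(bsdrTrain(g$dataset, plan, bsdrConfig(30, epochs = 5)),
               class = "bsdr_config_error")
})
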