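# Training stack: loss arithmetic, metrics, EMA, gradient liveness, the
# loop's convergence/determinism/resume guarantees, and checkpoints.

test_that("weighted MSE loss matches its closed form", {
  pred <- list(y = c(1, 2), negDy = matrix(0, 4, 3))
  targ <- list(y = c(1, 2), negDy = matrix(0, 4, 3))
  expect_equal(lossFunction(pred, targ, lossWeights(1, 1)), 0)
  expect_equal(lossFunction(list(y = 2, negDy = NULL), list(y = 0),
                            lossWeights(1, 0)), 4)
  predF <- list(y = c(0, 0), negDy = matrix(1, 2, 3))
  targF <- list(y = c(1, 3), negDy = matrix(0, 2, 3))
  le <- lossFunction(predF, targF, lossWeights(1, 0))
  lf <- lossFunction(predF, targF, lossWeights(0, 1))
  expect_equal(lossFunction(predF, targF, lossWeights(0.5, 0.5)),
               0.5 * (le + lf))
  expect_error(lossFunction(list(y = 1, negDy = NULL), list(y = 1),
                            lossWeights(1, 1)), "forces are missing")
  expect_error(lossWeights(0, 0))
})

test_that("validation metrics report L1/MSE pairs and ignore sample order", {
  y <- rnorm(5); f <- matrix(rnorm(15), 5, 3)
  m0 <- validationMetrics(list(y = y, negDy = f), list(y = y, negDy = f))
  expect_equal(unlist(m0), c(l1Energy = 0, mseEnergy = 0, l1Force = 0, mseForce = 0))
  delta <- 0.7
  m1 <- validationMetrics(list(y = y + delta, negDy = NULL), list(y = y))
  expect_equal(m1$l1Energy, delta)
  expect_equal(m1$mseEnergy, delta^2)
  expect_true(is.na(m1$l1Force))
  perm <- c(3, 1, 5, 2, 4)
  m2 <- validationMetrics(list(y = (y + delta)[perm], negDy = NULL), list(y = y[perm]))
  expect_equal(m2$l1Energy, m1$l1Energy)
})

test_that("EMA smoothing: tracking, midpoint and fixed-point behaviour", {
  raw <- emaState(alpha = 1)
  for (v in c(3, -1, 7)) { raw <- emaUpdate(raw, v); expect_equal(raw$value, v) }
  half <- emaUpdate(emaState(0.5), 2)
  half <- emaUpdate(half, 4)
  expect_equal(half$value, 3)
  const <- emaState(0.3)
  for (k in 1:10) const <- emaUpdate(const, 5)
  expect_equal(const$value, 5)
})

test_that("loss gradients are finite and nonzero for a random model (no dead graph)", {
  ds <- makeDimerDataset(8, seed = 70)
  model <- assembleModel(smallRepConfig("tensornet", numLayers = 1L,
                                        cutoff = 4.5), seed = 71)
  bd <- collateRecords(ds, 1:8)
  paramNodes <- lapply(model@params, adLeaf)
  lossNode <- NNPkit:::.batchLossNode(model, bd, paramNodes, lossWeights(1, 0.5))
  grads <- lapply(adGrad(lossNode, paramNodes), adValue)
  allG <- unlist(grads)
  expect_true(all(is.finite(allG)))
  expect_gt(max(abs(allG)), 0)
})

test_that("training converges on the dimer dataset and is exactly reproducible", {
  ds <- makeDimerDataset(60, noiseSd = 0, seed = 72)
  splits <- makeSplits(60, 48, 6, 6, seed = 1)
  model <- assembleModel(smallRepConfig("tensornet", numLayers = 1L, cutoff = 4.5),
                         seed = 73)
  cfg <- trainConfig(epochs = 8, batchSize = 30, learningRate = 0.01,
                     lambdaEnergy = 1, lambdaForce = 0.2, seed = 5)
  init <- NNPkit:::.evalSplit(model, ds, splits$val, 30, cfg$weights)
  r1 <- trainLoop(model, ds, splits, cfg)
  expect_lt(min(r1$history$valLoss), init$loss)
  # bit-identical rerun under the same seed
  r2 <- trainLoop(model, ds, splits, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@params, r2$model@params)
  # lambdaForce > 0 on a force-free dataset is a configuration error
  noF <- conformerDataset(lapply(ds@records[1:10], function(r) { r$negDy <- NULL; r }))
  expect_error(trainLoop(model, noF, makeSplits(10, 8, 1, 1, seed = 1), cfg),
               "no forces")
})

test_that("resuming from a checkpoint reproduces the uninterrupted run", {
  ds <- makeDimerDataset(40, seed = 74)
  splits <- makeSplits(40, 32, 4, 4, seed = 2)
  model <- assembleModel(smallRepConfig("graph_network", numLayers = 1L,
                                        cutoff = 4.5), seed = 75)
  dirA <- tempfile(); dirB <- tempfile()
  full <- trainLoop(model, ds, splits,
                    trainConfig(epochs = 6, batchSize = 20, learningRate = 0.01,
                                seed = 3, checkpointDir = dirA))
  part <- trainLoop(model, ds, splits,
                    trainConfig(epochs = 3, batchSize = 20, learningRate = 0.01,
                                seed = 3, checkpointDir = dirB))
  resumed <- trainLoop(model, ds, splits,
                       trainConfig(epochs = 6, batchSize = 20, learningRate = 0.01,
                                   seed = 3, checkpointDir = dirB),
                       resumeFrom = file.path(dirB, "last.ckpt"))
  expect_equal(resumed$history, full$history, tolerance = 1e-12)
  expect_identical(resumed$model@params, full$model@params)
})

test_that("checkpoints round-trip bit-identically and honor the derivative override", {
  sys <- clusterSystem(5, seed = 76)
  model <- assembleModel(smallRepConfig("equivariant_transformer"), seed = 77,
                         priors = list(atomrefPrior(rep(-1, 16), trainable = TRUE)),
                         derivative = FALSE)
  path <- tempfile(fileext = ".ckpt")
  saveCheckpoint(model, path, epoch = 12L)
  back <- loadModel(path)
  expect_identical(back@params, model@params)
  p0 <- predict(model, sys); p1 <- predict(back, sys)
  expect_identical(p0@y, p1@y)
  expect_null(p1@negDy)
  withF <- loadModel(path, derivative = TRUE)
  expect_false(is.null(predict(withF, sys)@negDy))
  # corrupt file: clean error, no partial model
  bad <- tempfile()
  writeLines("not a checkpoint", bad)
  expect_error(loadModel(bad), "corrupt|not an NNPkit checkpoint")
})
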