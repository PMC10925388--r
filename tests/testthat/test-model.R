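# Assembled model: the y/neg_dy contract, energy conservation, batch
# consistency, determinism, the static-shape mode and parameter counting.

test_that("derivative flag controls neg_dy presence and shape", {
  sys <- clusterSystem(4, seed = 41)
  on <- assembleModel(smallRepConfig("graph_network"), seed = 1, derivative = TRUE)
  off <- assembleModel(smallRepConfig("graph_network"), seed = 1, derivative = FALSE)
  pOn <- predict(on, sys); pOff <- predict(off, sys)
  expect_null(pOff@negDy)
  expect_equal(dim(pOn@negDy), c(4L, 3L))
  expect_equal(pOn@y, pOff@y)
})

test_that("forces are the exact negative gradient (finite-difference audit, priors active)", {
  sys <- clusterSystem(5, seed = 42, charged = TRUE)
  model <- assembleModel(smallRepConfig("tensornet"), seed = 2,
                         priors = list(atomrefPrior(rep(0.1, 16)), zblPrior(),
                                       coulombPrior(1.2), d2Prior()))
  p <- predict(model, sys)
  h <- 1e-4
  set.seed(43)
  for (k in 1:4) {               # directional derivatives along random directions
    v <- matrix(rnorm(15), 5, 3); v <- v / sqrt(sum(v^2))
    yp <- predict(model, particleSystem(sys@positions + h * v, sys@atomicNumbers,
                                        charges = sys@charges))@y
    ym <- predict(model, particleSystem(sys@positions - h * v, sys@atomicNumbers,
                                        charges = sys@charges))@y
    num <- -(yp - ym) / (2 * h)
    expect_equal(sum(p@negDy * v), num, tolerance = 1e-6)
  }
  # translation invariance: net force vanishes per batch
  expect_lt(max(abs(colSums(p@negDy))), 1e-10)
})

test_that("rotating the input rotates the forces and leaves y fixed", {
  sys <- clusterSystem(6, seed = 44)
  model <- assembleModel(smallRepConfig("tensornet"), seed = 3)
  p0 <- predict(model, sys)
  set.seed(45)
  Q <- randomO3(improper = TRUE)
  p1 <- predict(model, particleSystem(sys@positions %*% t(Q), sys@atomicNumbers))
  expect_equal(p1@y, p0@y, tolerance = 1e-9)
  expect_equal(p1@negDy, p0@negDy %*% t(Q), tolerance = 1e-8)
})

test_that("joint batched prediction equals independent per-sample prediction", {
  s1 <- clusterSystem(4, seed = 46)
  s2 <- clusterSystem(6, seed = 47)
  model <- assembleModel(smallRepConfig("equivariant_transformer"), seed = 4)
  joint <- particleSystem(rbind(s1@positions, s2@positions),
                          c(s1@atomicNumbers, s2@atomicNumbers),
                          batch = c(rep(0L, 4), rep(1L, 6)))
  pj <- predict(model, joint)
  p1 <- predict(model, s1); p2 <- predict(model, s2)
  expect_equal(pj@y, c(p1@y, p2@y), tolerance = 1e-12)
  expect_equal(pj@negDy, rbind(p1@negDy, p2@negDy), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical models and predictions", {
  sys <- clusterSystem(5, seed = 48)
  m1 <- assembleModel(smallRepConfig("tensornet"), seed = 123)
  m2 <- assembleModel(smallRepConfig("tensornet"), seed = 123)
  expect_identical(m1@params, m2@params)
  p1 <- predict(m1, sys); p2 <- predict(m2, sys)
  expect_identical(p1@y, p2@y)
  expect_identical(p1@negDy, p2@negDy)
})

test_that("static-shape mode: empty systems, capacity sweeps and overflow", {
  model <- assembleModel(smallRepConfig("graph_network"), seed = 5)
  empty <- particleSystem(matrix(0, 0, 3), integer(0))
  pe <- predict(model, empty)
  expect_length(pe@y, 0)
  sys <- clusterSystem(6, seed = 49)
  p0 <- predict(model, sys)
  need <- nFound(buildNeighbors(sys, 3.0))
  pBig <- predictStatic(model, sys, capacity = 4L * need)
  expect_identical(p0@y, pBig@y)
  expect_identical(p0@negDy, pBig@negDy)
  err <- tryCatch(predictStatic(model, sys, capacity = need - 1L),
                  error = function(e) e)
  expect_s3_class(err, "neighborOverflowError")
  expect_equal(err$required, need)
})

test_that("parameter counting is monotone in depth and tracks trainable priors", {
  c0 <- countParameters(assembleModel(smallRepConfig("tensornet", 0L), seed = 6))
  c2 <- countParameters(assembleModel(smallRepConfig("tensornet", 2L), seed = 6))
  expect_lt(c0, c2)
  frozen <- assembleModel(smallRepConfig("graph_network"), seed = 6,
                          priors = list(atomrefPrior(rep(0, 16))))
  learn <- assembleModel(smallRepConfig("graph_network"), seed = 6,
                         priors = list(atomrefPrior(rep(0, 16), trainable = TRUE)))
  expect_equal(as.numeric(countParameters(learn)) - as.numeric(countParameters(frozen)),
               17)  # table + ghost row
  bk <- attr(countParameters(learn), "breakdown")
  expect_equal(sum(bk), as.numeric(countParameters(learn)))
})

test_that("output head reduction: sums partition exactly across batch splits", {
  model <- assembleModel(smallRepConfig("graph_network"), seed = 7, derivative = FALSE)
  s1 <- clusterSystem(4, seed = 50)
  s2 <- clusterSystem(4, seed = 51)
  # one batch holding both far-separated clusters vs two batches
  farPos <- rbind(s1@positions, s2@positions + 100)
  z <- c(s1@atomicNumbers, s2@atomicNumbers)
  oneBatch <- particleSystem(farPos, z)
  twoBatch <- particleSystem(farPos, z, batch = rep(0:1, each = 4))
  expect_equal(predict(model, oneBatch)@y, sum(predict(model, twoBatch)@y),
               tolerance = 1e-10)
  # mean reduction divides by per-sample atom counts
  mMean <- assembleModel(smallRepConfig("graph_network"),
                         outConfig = outputConfig(reduceOp = "mean"),
                         seed = 7, derivative = FALSE)
  expect_equal(predict(mMean, s1)@y, predict(model, s1)@y / 4, tolerance = 1e-12)
})
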