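# Representation models: tensor decomposition, O(3) behaviour,
# permutation equivariance, locality, padding/ghost bit-identity, and the
# equivariant transformer's cutoff continuity switch.

test_that("rank-2 tensor decomposition is exact and conjugation-equivariant", {
  expect_equal(decomposeTensor(diag(3)),
               list(I = diag(3), A = matrix(0, 3, 3), S = matrix(0, 3, 3)))
  Anti <- matrix(c(0, 2, -1, -2, 0, 3, 1, -3, 0), 3, 3)
  dA <- decomposeTensor(Anti)
  expect_equal(dA$A, Anti)
  expect_equal(dA$I, matrix(0, 3, 3))
  expect_equal(dA$S, matrix(0, 3, 3))
  set.seed(5)
  for (k in 1:5) {
    X <- matrix(rnorm(9), 3, 3)
    p <- decomposeTensor(X)
    expect_equal(p$I + p$A + p$S, X, tolerance = 1e-12)
    expect_equal(sum(diag(p$S)), 0, tolerance = 1e-12)
    expect_equal(t(p$A), -p$A)
    R <- randomO3()
    pr <- decomposeTensor(R %*% X %*% t(R))
    expect_equal(pr$I, R %*% p$I %*% t(R), tolerance = 1e-10)
    expect_equal(pr$A, R %*% p$A %*% t(R), tolerance = 1e-10)
    expect_equal(pr$S, R %*% p$S %*% t(R), tolerance = 1e-10)
  }
})

predEnergy <- function(model, sys) predict(model, sys)@y

test_that("all models are invariant under O(3) transformations and atom permutations", {
  set.seed(6)
  sys <- clusterSystem(7, seed = 61)
  for (mdl in c("tensornet", "equivariant_transformer", "graph_network")) {
    for (layers in 0:2) {
      model <- assembleModel(smallRepConfig(mdl, layers), seed = 7, derivative = FALSE)
      y0 <- predEnergy(model, sys)
      for (k in 1:3) {
        Q <- randomO3(improper = k %% 2 == 0)
        t0 <- rnorm(3, sd = 3)
        sys2 <- particleSystem(sweep(sys@positions %*% t(Q), 2, -t0),
                               sys@atomicNumbers)
        expect_equal(predEnergy(model, sys2), y0, tolerance = 1e-9)
      }
      perm <- sample(nAtoms(sys))
      sysP <- particleSystem(sys@positions[perm, ], sys@atomicNumbers[perm])
      expect_equal(predEnergy(model, sysP), y0, tolerance = 1e-9)
    }
  }
})

test_that("isolated and exploded geometries reduce to per-atom embeddings", {
  for (mdl in c("tensornet", "equivariant_transformer", "graph_network")) {
    model <- assembleModel(smallRepConfig(mdl), seed = 8, derivative = FALSE)
    lone <- function(z) predEnergy(model, particleSystem(matrix(rnorm(3), 1, 3), z))
    expect_equal(lone(6L), lone(6L))
    expect_false(isTRUE(all.equal(lone(6L), lone(8L))))  # species matters
    # atoms far beyond the cutoff behave as isolated atoms
    far <- particleSystem(rbind(c(0, 0, 0), c(50, 0, 0), c(0, 70, 0)),
                          c(6L, 8L, 6L))
    yFar <- predEnergy(model, far)
    expect_equal(yFar, lone(6L) + lone(8L) + lone(6L), tolerance = 1e-10)
  }
})

test_that("locality: perturbing an atom outside the receptive field changes nothing", {
  model <- assembleModel(smallRepConfig("tensornet", numLayers = 1L), seed = 9,
                         derivative = FALSE)
  # chain 0 -- 2.5 -- 5.0 -- 40: the far atom is outside every receptive field
  base <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(5, 0, 0), c(40, 0, 0))
  z <- c(6L, 6L, 6L, 8L)
  mkBatch <- function(pos4) particleSystem(pos4[1:3, , drop = FALSE], z[1:3])
  y1 <- predEnergy(model, particleSystem(base, z))
  moved <- base; moved[4, ] <- c(60, 5, -3)
  y2 <- predEnergy(model, particleSystem(moved, z))
  lonely8 <- predEnergy(model, particleSystem(matrix(0, 1, 3), 8L))
  expect_equal(y1, y2, tolerance = 1e-12)
  expect_equal(y1, predEnergy(model, mkBatch(base)) + lonely8, tolerance = 1e-10)
})

test_that("neighbor capacity and the ghost atom never leak into real outputs", {
  sys <- clusterSystem(8, seed = 71, charged = TRUE)
  for (mdl in c("tensornet", "equivariant_transformer", "graph_network")) {
    model <- assembleModel(smallRepConfig(mdl), seed = 10,
                           priors = list(zblPrior(), coulombPrior(1.5)))
    p0 <- predict(model, sys)
    need <- nFound(buildNeighbors(sys, 3.0))
    for (cap in c(need, need + 13L, need * 3L)) {
      p1 <- predictStatic(model, sys, capacity = cap)
      expect_identical(p0@y, p1@y)
      expect_identical(p0@negDy, p1@negDy)
    }
  }
})

test_that("equivariant transformer is continuous at the cutoff only with the vector-cutoff fix", {
  mkModel <- function(fix) {
    assembleModel(smallRepConfig("equivariant_transformer", numLayers = 2L,
                                 vectorCutoff = fix),
                  seed = 12, derivative = FALSE)
  }
  eAt <- function(model, r) {
    predEnergy(model, particleSystem(cbind(c(0, r), 0, 0), c(6L, 8L)))
  }
  fixOn <- mkModel(TRUE); fixOff <- mkModel(FALSE)
  jumps <- function(model) {
    vapply(c(1e-2, 1e-3, 1e-4),
           function(eps) abs(eAt(model, 3 - eps) - eAt(model, 3 + eps)), 0)
  }
  jOn <- jumps(fixOn); jOff <- jumps(fixOff)
  # with the fix: the jump is bounded by O(eps) and converges to zero
  expect_true(all(jOn <= 10 * c(1e-2, 1e-3, 1e-4)))
  expect_lt(jOn[3], 1e-10)
  # without it: a finite jump persists as eps -> 0 (legacy behaviour)
  expect_gt(min(jOff), 1e-9)
  expect_lt(abs(jOff[2] - jOff[3]) / jOff[3], 0.05)

  # with the fix, forces stay bounded approaching the cutoff
  fixOnD <- assembleModel(smallRepConfig("equivariant_transformer",
                                         numLayers = 2L, vectorCutoff = TRUE),
                          seed = 12)
  fNear <- predict(fixOnD, particleSystem(cbind(c(0, 3 - 1e-5), 0, 0), c(6L, 8L)))@negDy
  expect_lt(max(abs(fNear)), 10)
})

test_that("vector features rotate with the frame while scalars stay put", {
  sys <- clusterSystem(5, seed = 81)
  model <- assembleModel(smallRepConfig("equivariant_transformer"), seed = 13)
  p0 <- predict(model, sys)
  Q <- randomO3()
  sysR <- particleSystem(sys@positions %*% t(Q), sys@atomicNumbers)
  pR <- predict(model, sysR)
  expect_equal(pR@y, p0@y, tolerance = 1e-9)
  expect_equal(pR@negDy, p0@negDy %*% t(Q), tolerance = 1e-8)
})
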