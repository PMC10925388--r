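# Physical priors: closed-form anchors, pairwise oracles, symmetry,
# force audits, and the custom-prior extension contract.

# evaluate the summed prior energy of a system through a model whose
# network head is zeroed, isolating the prior terms
priorOnlyModel <- function(priors, cutoff = 5.0) {
  model <- assembleModel(representationConfig("graph_network",
                                              embeddingDimension = 4,
                                              numLayers = 0,
                                              radial = radialConfig(cutoff, 4),
                                              maxZ = 20),
                         priors = priors, seed = 20)
  for (nm in c("head1.W", "head1.b", "head2.W", "head2.b")) model@params[[nm]][] <- 0
  model
}

test_that("ZBL screening function anchors: f(0) = 1, monotone decay, cutoff zero", {
  zbl <- zblPrior()
  expect_equal(zblScreening(0, zbl), 1, tolerance = 1e-3)   # published coefficients sum to 1
  expect_equal(sum(zbl@coefficients), 1, tolerance = 1e-3)
  grid <- seq(0.01, 4, by = 0.01)
  expect_true(all(diff(zblScreening(grid, zbl)) < 0))

  model <- priorOnlyModel(list(zbl), cutoff = 4.0)
  eAt <- function(r, z = c(1L, 1L)) {
    predict(model, particleSystem(cbind(c(0, r), 0, 0), z))@y
  }
  # pairwise energy strictly decreasing in r on (0, r_c)
  rs <- seq(0.2, 3.9, by = 0.1)
  es <- vapply(rs, eAt, 0)
  expect_true(all(diff(es) < 0))
  expect_true(all(es > 0))
  expect_equal(eAt(4.5), 0)   # beyond cutoff: exactly zero
  # closed-form check at one separation
  r <- 1.3; zi <- 6; zj <- 8
  a <- zbl@lengthScale / (zi^0.23 + zj^0.23)
  expected <- cosineCutoff(r, 4.0) * 14.3996 * zi * zj / r * zblScreening(r / a, zbl)
  expect_equal(eAt(r, c(6L, 8L)), expected, tolerance = 1e-10)
})

test_that("D2 anchors: geometric C6 combination, damping midpoint, asymptotic form", {
  expect_equal(sqrt(4 * 9), 6)  # the combination rule the implementation uses
  expect_equal(d2Damping(2.5, 2.5), 0.5)
  tab <- d2Parameters()
  expect_true(all(c(1, 6, 7, 8, 16) %in% tab$z))
  d2 <- d2Prior(s6 = 1)
  model <- priorOnlyModel(list(d2), cutoff = 9.0)
  eAt <- function(r, z = c(6L, 6L)) predict(model, particleSystem(cbind(c(0, r), 0, 0), z))@y
  r <- 8.0  # far beyond the vdW radius sum: damping ~ 1
  c6 <- tab$c6[tab$z == 6] * 10.36436
  expect_equal(eAt(r), -c6 / r^6, tolerance = 1e-4)
  # mixed pair uses sqrt(C6_i C6_j)
  c6mix <- sqrt(tab$c6[tab$z == 6] * tab$c6[tab$z == 8]) * 10.36436
  expect_equal(eAt(r, c(6L, 8L)), -c6mix / r^6, tolerance = 1e-4)
  light <- d2Prior(table = tab[tab$z <= 10, ])   # truncated coverage
  mLight <- priorOnlyModel(list(light))
  err <- tryCatch(predict(mLight, particleSystem(cbind(c(0, 1), 0, 0), c(6L, 16L))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "Z=16")
})

test_that("Coulomb prior: switched short range, exact long range, pairwise additivity", {
  model <- priorOnlyModel(list(coulombPrior(2.0, coulombConstant = 1)), cutoff = 6.0)
  eAt <- function(r, q) {
    predict(model, particleSystem(cbind(c(0, r), 0, 0), c(1L, 1L), charges = q))@y
  }
  expect_equal(eAt(5, c(1, -1)), -0.2, tolerance = 1e-12)  # k q1 q2 / r beyond switch
  expect_lt(abs(eAt(1e-4, c(1, -1))), 1e-3)                # sw(0) = 0 kills the singularity
  expect_lt(abs(eAt(1e-6, c(1, -1))), 1e-5)                # and the limit is 0, linearly in r
  # midpoint of the switch
  expect_equal(eAt(1.0, c(1, -1)), 0.5 * (1 - cos(pi / 2)) * -1, tolerance = 1e-12)

  # three charges: sum of the three pair terms (direct oracle)
  pos <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  q <- c(0.5, -0.3, 0.2)
  sys3 <- particleSystem(pos, c(1L, 1L, 1L), charges = q)
  sw <- function(r) ifelse(r < 2, 0.5 * (1 - cos(pi * r / 2)), 1)
  oracle <- sw(3) * q[1] * q[2] / 3 + sw(4) * q[1] * q[3] / 4 + sw(5) * q[2] * q[3] / 5
  expect_equal(predict(model, sys3)@y, oracle, tolerance = 1e-12)

  noQ <- particleSystem(pos, c(1L, 1L, 1L))
  expect_error(predict(model, noQ), "coulomb prior requires")
})

test_that("atomref adds table entries per atom and rejects uncovered elements", {
  tab <- rep(0, 16); tab[6] <- -1000
  model <- priorOnlyModel(list(atomrefPrior(tab)))
  yC <- predict(model, particleSystem(matrix(0, 1, 3), 6L))@y
  expect_equal(yC, -1000)
  y2 <- predict(model, particleSystem(rbind(c(0, 0, 0), c(1.2, 0, 0)), c(6L, 6L)))@y
  expect_equal(y2, -2000)
  zero <- priorOnlyModel(list(atomrefPrior(rep(0, 16))))
  expect_equal(predict(zero, particleSystem(matrix(0, 1, 3), 8L))@y, 0)
  expect_error(predict(model, particleSystem(matrix(0, 1, 3), 17L)), "Z=17")
})

test_that("priors compose additively and stay O(3) invariant", {
  sys <- clusterSystem(6, seed = 91, charged = TRUE, cutoff = 5.0)
  mZbl <- priorOnlyModel(list(zblPrior()))
  mCol <- priorOnlyModel(list(coulombPrior(1.5)))
  mBoth <- priorOnlyModel(list(zblPrior(), coulombPrior(1.5)))
  expect_equal(predict(mBoth, sys)@y, predict(mZbl, sys)@y + predict(mCol, sys)@y,
               tolerance = 1e-12)
  mAll <- priorOnlyModel(list(atomrefPrior(rep(1, 16)), zblPrior(),
                              coulombPrior(1.5), d2Prior()))
  y0 <- predict(mAll, sys)@y
  set.seed(92)
  for (k in 1:5) {
    Q <- randomO3(improper = k %% 2 == 0)
    sys2 <- particleSystem(sys@positions %*% t(Q) + 1.7, sys@atomicNumbers,
                           charges = sys@charges)
    expect_equal(predict(mAll, sys2)@y, y0, tolerance = 1e-9)
  }
})

test_that("prior forces match central finite differences", {
  sys <- clusterSystem(5, seed = 93, charged = TRUE, cutoff = 5.0)
  model <- priorOnlyModel(list(zblPrior(), coulombPrior(1.5), d2Prior(),
                               atomrefPrior(rep(0.5, 16))))
  f <- predict(model, sys)@negDy
  h <- 1e-5
  num <- matrix(0, 5, 3)
  for (i in 1:5) for (k in 1:3) {
    pp <- sys@positions; pp[i, k] <- pp[i, k] + h
    pm <- sys@positions; pm[i, k] <- pm[i, k] - h
    num[i, k] <- -(predict(model, particleSystem(pp, sys@atomicNumbers, charges = sys@charges))@y -
                   predict(model, particleSystem(pm, sys@atomicNumbers, charges = sys@charges))@y) / (2 * h)
  }
  expect_lt(max(abs(f - num)) / max(abs(num)), 1e-5)
})

test_that("a user-defined prior composes exactly like the built-ins", {
  setClass("testHarmonicPrior", contains = "Prior",
           representation(k = "numeric"), where = globalenv())
  setMethod("priorLevel", "testHarmonicPrior", function(prior) "molecule",
            where = globalenv())
  setMethod("priorEnergyNode", "testHarmonicPrior",
            function(prior, ctx, params, prefix) {
              term <- adMul(adMul(ctx$d, ctx$d), prior@k)
              adScatter(adMul(term, ctx$halfMask), ctx$edgeBatch, ctx$nbatchTot)
            }, where = globalenv())
  custom <- new("testHarmonicPrior", k = 0.25)
  model <- priorOnlyModel(list(custom))
  r <- 1.7
  y <- predict(model, particleSystem(cbind(c(0, r), 0, 0), c(1L, 1L)))@y
  expect_equal(y, 0.25 * r^2, tolerance = 1e-12)
  # force = -dE/dr along the bond
  f <- predict(model, particleSystem(cbind(c(0, r), 0, 0), c(1L, 1L)))@negDy
  expect_equal(f[2, 1], -2 * 0.25 * r, tolerance = 1e-10)
})

test_that("truncation discontinuity of D2/Coulomb at the neighbor cutoff is bounded", {
  cutoff <- 6.0
  tab <- d2Parameters()
  c6 <- tab$c6[tab$z == 6] * 10.36436
  # the D2 term dropped at r_c is C6/r_c^6 (damping ~ 1 there): (3/6)^6 =
  # 1/64 of the term at typical contact distance
  expect_lt(c6 / cutoff^6, 0.02 * c6 / 3.0^6)
  model <- priorOnlyModel(list(d2Prior()), cutoff = cutoff)
  eAt <- function(r) predict(model, particleSystem(cbind(c(0, r), 0, 0), c(6L, 6L)))@y
  expect_lt(abs(eAt(cutoff - 1e-6) - eAt(cutoff + 1e-6)), c6 / cutoff^6 * 1.01)
})
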