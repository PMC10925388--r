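# Neighbor engine: minimum image against the exhaustive 27-image oracle,
# brute force against direct pair enumeration, cell list against brute
# force, and the padding/backward contracts.

test_that("minimum image matches the exhaustive 27-image oracle", {
  boxR <- simulationBox(c(10, 10, 10))
  expect_equal(minimumImage(c(0, 0, 0), boxR), c(0, 0, 0))
  expect_equal(minimumImage(c(9.4, 0, 0), boxR), c(-0.6, 0, 0))
  latT <- matrix(c(10, 0, 0, 5, 9, 0, 0, 0, 10), 3, 3, byrow = TRUE)
  boxT <- simulationBox(latT)
  expect_equal(minimumImage(c(6, 6, 0), boxT), oracleMinImage(c(6, 6, 0), latT))
  set.seed(4)
  checked <- 0L
  for (k in 1:120) {
    delta <- runif(3, -8, 8)
    # the sequential reduction is guaranteed only inside the single-image
    # regime (reduced displacement below half the smallest diagonal), which
    # is exactly where the neighbor engine is allowed to operate
    if (sqrt(sum(oracleMinImage(delta, latT)^2)) <= 4.5) {
      expect_equal(minimumImage(delta, boxT), oracleMinImage(delta, latT),
                   tolerance = 1e-12)
      checked <- checked + 1L
    }
    expect_equal(minimumImage(delta, boxR), oracleMinImage(delta, diag(c(10, 10, 10))),
                 tolerance = 1e-12)
  }
  expect_gte(checked, 30L)
  expect_error(simulationBox(matrix(c(10, 1, 0, 0, 9, 0, 0, 0, 8), 3, 3, byrow = TRUE)),
               "reduced")
})

test_that("brute-force search finds exactly the in-range same-batch pairs", {
  sys <- particleSystem(cbind(c(0, 1, 2.5), 0, 0), c(1L, 1L, 1L))
  half <- bruteForceNeighbors(sys, 1.5, includeTranspose = FALSE)
  expect_equal(nFound(half), 2L)
  expect_identical(pairKey(half), c("1-2", "2-3"))
  expect_equal(nFound(bruteForceNeighbors(sys, 3.0, includeTranspose = FALSE)), 3L)

  # coincident geometries in two batches: only within-batch pairs survive
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  two <- particleSystem(pos, rep(1L, 4), batch = c(0L, 0L, 1L, 1L))
  nl <- bruteForceNeighbors(two, 100, includeTranspose = FALSE)
  expect_equal(nFound(nl), 2L)
  expect_identical(pairKey(nl), c("1-2", "3-4"))

  single <- particleSystem(matrix(0, 1, 3), 1L)
  nl1 <- bruteForceNeighbors(single, 2, capacity = 4L)
  expect_equal(nFound(nl1), 0L)
  expect_true(all(nl1@pairs == -1L))
})

test_that("cell list reproduces the brute-force pair set across sizes, batches and box kinds", {
  cases <- expand.grid(n = c(2, 17, 120, 500), b = c(1, 2, 8),
                       kind = c("open", "rectangular", "triclinic"),
                       stringsAsFactors = FALSE)
  seed <- 100L
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    if (cs$n < cs$b) next
    sys <- makeCloud(cs$n, meanNeighbors = min(12, cs$n / cs$b), cutoff = 3.0,
                     nBatches = cs$b, boxKind = cs$kind, seed = seed + r,
                     checkDensity = FALSE)
    a <- bruteForceNeighbors(sys, 3.0, includeTranspose = FALSE)
    b <- cellListNeighbors(sys, 3.0, includeTranspose = FALSE)
    expect_identical(pairKey(a), pairKey(b))
  }
})

test_that("reduced-scale dense cloud keeps cell list and brute force in exact agreement", {
  sys <- makeCloud(1000, meanNeighbors = 64, cutoff = 3.0, seed = 42)
  a <- bruteForceNeighbors(sys, 3.0, includeTranspose = FALSE)
  b <- cellListNeighbors(sys, 3.0, includeTranspose = FALSE)
  expect_identical(pairKey(a), pairKey(b))
  expect_equal(nFound(cellListNeighbors(particleSystem(matrix(0, 0, 3), integer(0)), 3.0)), 0L)
})

test_that("lattice translations leave pair set and edge geometry unchanged", {
  sys <- makeCloud(60, meanNeighbors = 10, cutoff = 3.0, boxKind = "triclinic",
                   seed = 9)
  nl <- bruteForceNeighbors(sys, 3.0)
  pos2 <- sys@positions
  set.seed(10)
  shift <- sample(-2:2, nAtoms(sys) * 3, replace = TRUE)
  pos2 <- pos2 + matrix(shift, ncol = 3) %*% sys@box@lattice
  sys2 <- particleSystem(pos2, sys@atomicNumbers, batch = sys@batch, box = sys@box)
  nl2 <- bruteForceNeighbors(sys2, 3.0)
  expect_identical(pairKey(nl), pairKey(nl2))
  expect_equal(sort(edgeDistances(nl)), sort(edgeDistances(nl2)), tolerance = 1e-10)
})

test_that("padding is inert and transposed pairs mirror with negated vectors", {
  sys <- makeCloud(40, meanNeighbors = 8, cutoff = 3.0, seed = 11)
  nl <- bruteForceNeighbors(sys, 3.0)
  nlPad <- bruteForceNeighbors(sys, 3.0, capacity = nFound(nl) + 25L)
  m <- nFound(nl)
  expect_identical(nl@pairs[, 1:m], nlPad@pairs[, 1:m])
  expect_identical(nl@edgeVectors[1:m, ], nlPad@edgeVectors[1:m, ])
  expect_true(all(nlPad@pairs[, (m + 1):(m + 25)] == -1L))

  p <- neighborPairs(nl)
  key <- paste(p[1, ], p[2, ])
  keyT <- paste(p[2, ], p[1, ])
  expect_setequal(key, keyT)
  for (k in seq_len(min(20, m))) {
    mirror <- which(p[1, ] == p[2, k] & p[2, ] == p[1, k])
    expect_equal(nl@edgeVectors[mirror, ], -nl@edgeVectors[k, ])
  }
  expect_equal(edgeDistances(nl), sqrt(rowSums(edgeVectors(nl)^2)))
  expect_true(all(edgeDistances(nl) <= 3.0))
})

test_that("batch concatenation yields the re-indexed union of individual pair sets", {
  s1 <- clusterSystem(6, seed = 21)
  s2 <- clusterSystem(5, seed = 22)
  joint <- particleSystem(rbind(s1@positions, s2@positions),
                          c(s1@atomicNumbers, s2@atomicNumbers),
                          batch = c(rep(0L, 6), rep(1L, 5)))
  a <- pairKey(bruteForceNeighbors(s1, 3.0, includeTranspose = FALSE))
  b <- pairKey(bruteForceNeighbors(s2, 3.0, includeTranspose = FALSE))
  bShift <- vapply(strsplit(b, "-"), function(x) {
    paste(as.integer(x[1]) + 6L, as.integer(x[2]) + 6L, sep = "-")
  }, "")
  expect_identical(pairKey(bruteForceNeighbors(joint, 3.0, includeTranspose = FALSE)),
                   sort(c(a, bShift)))
})

test_that("overflow reports the required capacity instead of truncating", {
  sys <- makeCloud(50, meanNeighbors = 10, cutoff = 3.0, seed = 12)
  need <- nFound(bruteForceNeighbors(sys, 3.0))
  err <- tryCatch(bruteForceNeighbors(sys, 3.0, capacity = need - 1L),
                  error = function(e) e)
  expect_s3_class(err, "neighborOverflowError")
  expect_equal(err$required, need)
})

test_that("strategy selection switches to the cell list at the threshold", {
  expect_identical(selectStrategy(100), "brute")
  expect_identical(selectStrategy(50000), "cell")
  expect_identical(selectStrategy(10000), "cell")  # boundary goes to cell
  expect_identical(selectStrategy(9999), "brute")
})

test_that("edge-geometry backward matches finite differences of edge quantities", {
  sys <- clusterSystem(5, seed = 31)
  nl <- bruteForceNeighbors(sys, 3.0)
  m <- nFound(nl)
  expect_identical(edgeGeometryBackward(matrix(0, m, 3), rep(0, m), nl, 5), matrix(0, 5, 3))

  set.seed(32)
  gv <- matrix(rnorm(m * 3), m, 3)
  gd <- rnorm(m)
  got <- edgeGeometryBackward(gv, gd, nl, 5)
  lossAt <- function(pos) {
    nl2 <- bruteForceNeighbors(particleSystem(pos, sys@atomicNumbers), 3.0)
    stopifnot(identical(nl2@pairs, nl@pairs))
    sum(gv * nl2@edgeVectors[1:m, ]) + sum(gd * nl2@distances[1:m])
  }
  num <- matrix(0, 5, 3)
  h <- 1e-6
  for (i in 1:5) for (k in 1:3) {
    pp <- sys@positions; pp[i, k] <- pp[i, k] + h
    pm <- sys@positions; pm[i, k] <- pm[i, k] - h
    num[i, k] <- (lossAt(pp) - lossAt(pm)) / (2 * h)
  }
  expect_lt(max(abs(got - num)) / max(abs(num)), 1e-6)

  # single pair along x with unit distance gradient: opposite unit forces
  dimer <- particleSystem(cbind(c(0, 1.2), 0, 0), c(1L, 1L))
  nld <- bruteForceNeighbors(dimer, 3.0, includeTranspose = FALSE)
  g <- edgeGeometryBackward(matrix(0, 1, 3), 1, nld, 2)
  expect_equal(g, rbind(c(-1, 0, 0), c(1, 0, 0)))
})
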