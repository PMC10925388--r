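# Seeded synthetic generators for every test input: random particle clouds
# with controlled neighbor density, toy dimer datasets from an analytic
# pair potential, and composition datasets for reference-energy recovery.
# All generators are pure functions of (spec, seed): they run on a private
# RNG stream and leave the caller's RNG untouched.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }, add = TRUE)
  force(expr)
}

#' Random particle cloud with controlled neighbor density
#'
#' Atoms are placed uniformly in a box sized so that the expected
#' within-batch neighbor count matches `meanNeighbors` through the density
#' relation `density = meanNeighbors / ((4/3) pi r_c^3)` (each batch fills
#' the same box). Atomic numbers are drawn from a small organic-chemistry
#' element set. For periodic kinds the realized mean neighbor count is
#' checked to lie within 20% of the target; open boundaries skip the check
#' (edge effects deplete the neighborhood of surface atoms).
#'
#' @param nAtoms total atom count across batches.
#' @param meanNeighbors target mean neighbors per particle (within batch).
#' @param cutoff neighbor cutoff in Angstrom.
#' @param nBatches number of samples sharing the box.
#' @param boxKind `"rectangular"`, `"triclinic"` or `"open"`.
#' @param seed RNG seed.
#' @param charged attach random (zero-sum per batch) partial charges.
#' @param elements element set to draw atomic numbers from.
#' @param checkDensity verify the realized neighbor count (default: only
#'   for periodic kinds).
#' @return a [ParticleSystem-class].
#' @examples
#' sys <- makeCloud(100, meanNeighbors = 10, cutoff = 3, seed = 1)
#' nAtoms(sys)
#' @export
makeCloud <- function(nAtoms, meanNeighbors = 16, cutoff = 4.5, nBatches = 1L,
                      boxKind = c("rectangular", "triclinic", "open"),
                      seed = 0L, charged = FALSE,
                      elements = c(1L, 6L, 7L, 8L, 16L),
                      checkDensity = NULL) {
  boxKind <- match.arg(boxKind)
  stopifnot(nAtoms >= 1, nBatches >= 1, nAtoms >= nBatches)
  if (is.null(checkDensity)) checkDensity <- boxKind != "open" && nAtoms / nBatches >= 50
  perBatch <- nAtoms / nBatches
  if (meanNeighbors > perBatch) {
    stop(sprintf("infeasible density: %d atoms per batch cannot average %.3g neighbors",
                 as.integer(perBatch), meanNeighbors))
  }
  sphere <- 4 / 3 * pi * cutoff^3
  vol <- perBatch * sphere / meanNeighbors
  s <- vol^(1 / 3)
  if (s < 2 * cutoff && boxKind != "open") {
    if (isTRUE(checkDensity) || is.null(checkDensity)) {
      stop(sprintf("infeasible density: box edge %.3g A below the single-image limit %.3g A; lower meanNeighbors or raise nAtoms",
                   s, 2 * cutoff))
    }
    s <- 2 * cutoff  # density check waived: grow to the smallest valid box
  }
  .withSeed(seed, {
    lattice <- switch(boxKind,
                      rectangular = diag(rep(s, 3)),
                      triclinic = matrix(c(s, 0, 0, 0.2 * s, s, 0, 0.1 * s, 0.15 * s, s),
                                         3, 3, byrow = TRUE),
                      open = diag(rep(s, 3)))
    frac <- matrix(runif(nAtoms * 3L), ncol = 3L)
    pos <- frac %*% lattice
    counts <- diff(round(seq(0, nAtoms, length.out = nBatches + 1L)))
    batch <- rep(seq_len(nBatches) - 1L, counts)
    z <- elements[sample.int(length(elements), nAtoms, replace = TRUE)]
    q <- NULL
    if (charged) {
      q <- runif(nAtoms, -0.5, 0.5)
      for (b in unique(batch)) q[batch == b] <- q[batch == b] - mean(q[batch == b])
    }
    box <- if (boxKind == "open") NULL else simulationBox(lattice)
    sys <- particleSystem(pos, z, batch = batch, charges = q, box = box)
    if (checkDensity) {
      nl <- bruteForceNeighbors(sys, cutoff, includeTranspose = TRUE)
      realized <- nFound(nl) / nAtoms
      if (abs(realized - meanNeighbors) > 0.2 * meanNeighbors) {
        stop(sprintf("cloud generator: realized mean neighbor count %.1f outside 20%% of target %.1f",
                     realized, meanNeighbors))
      }
    }
    sys
  })
}

#' Morse pair potential
#'
#' `V(r) = De ((1 - exp(-a (r - r0)))^2 - 1)`: smooth, with an attractive
#' well of depth `De` at `r0` and a steep repulsive wall -- a convenient
#' stand-in for a bond-like interaction in training smoke tests.
#'
#' @param De well depth (energy units).
#' @param a stiffness (1/Angstrom).
#' @param r0 equilibrium separation (Angstrom).
#' @return list with functions `V(r)` and `dV(r)`.
#' @export
morsePotential <- function(De = 1.0, a = 1.7, r0 = 1.5) {
  list(V = function(r) De * ((1 - exp(-a * (r - r0)))^2 - 1),
       dV = function(r) 2 * De * a * exp(-a * (r - r0)) * (1 - exp(-a * (r - r0))))
}

#' Toy dimer dataset from an analytic pair potential
#'
#' Two-atom conformers at separations sampled uniformly from `rRange`,
#' randomly oriented and translated, with `y = V(r) + noise` and exact
#' analytic forces `-dV/dr` along the bond. Used for training convergence
#' and force-matching tests, where ground truth is known in closed form.
#'
#' @param nSamples number of conformers.
#' @param rRange separation range in Angstrom.
#' @param pairPotential list with `V` and `dV` (see [morsePotential]).
#' @param noiseSd standard deviation of energy noise (forces stay exact).
#' @param seed RNG seed.
#' @param z atomic numbers of the two atoms.
#' @return a [ConformerDataset-class].
#' @export
makeDimerDataset <- function(nSamples = 200L, rRange = c(1.0, 3.5),
                             pairPotential = morsePotential(),
                             noiseSd = 0.0, seed = 0L, z = c(6L, 6L)) {
  .withSeed(seed, {
    records <- vector("list", nSamples)
    for (k in seq_len(nSamples)) {
      r <- runif(1, rRange[1], rRange[2])
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      com <- rnorm(3, sd = 0.5)
      pos <- rbind(com - r / 2 * u, com + r / 2 * u)
      f2 <- -pairPotential$dV(r) * u   # force on atom 2 (along +u)
      records[[k]] <- list(z = as.integer(z), pos = unname(pos),
                           y = pairPotential$V(r) + rnorm(1, sd = noiseSd),
                           negDy = unname(rbind(-f2, f2)), q = NULL)
    }
    conformerDataset(records)
  })
}

#' Composition dataset for reference-energy recovery
#'
#' Random compositions over `elementSet` with `y = sum_i mu[z_i] + noise`
#' and zero forces: a dataset whose energies are fully explained by
#' per-element reference energies, so a learnable atomref prior should
#' recover `mu` up to the noise floor.
#'
#' @param nSamples number of records.
#' @param elementSet atomic numbers to draw from.
#' @param muTable numeric vector indexed by atomic number with the true
#'   per-element references.
#' @param noiseSd energy noise standard deviation.
#' @param seed RNG seed.
#' @param atomRange min/max atoms per record.
#' @return a [ConformerDataset-class].
#' @export
makeAtomrefDataset <- function(nSamples = 500L,
                               elementSet = c(1L, 6L, 7L, 8L, 16L),
                               muTable, noiseSd = 0.01, seed = 0L,
                               atomRange = c(3L, 8L)) {
  stopifnot(max(elementSet) <= length(muTable))
  .withSeed(seed, {
    records <- vector("list", nSamples)
    for (k in seq_len(nSamples)) {
      n <- sample(atomRange[1]:atomRange[2], 1L)
      z <- elementSet[sample.int(length(elementSet), n, replace = TRUE)]
      # loose cloud; geometry is irrelevant to the target
      pos <- matrix(runif(n * 3L, 0, 4 * n^(1 / 3)), ncol = 3L)
      records[[k]] <- list(z = as.integer(z), pos = pos,
                           y = sum(muTable[z]) + rnorm(1, sd = noiseSd),
                           negDy = matrix(0, n, 3L), q = NULL)
    }
    conformerDataset(records)
  })
}
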