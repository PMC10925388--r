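# Shared test helpers: small seeded systems, random O(3) transformations,
# and independent brute-force oracles kept deliberately naive.

# random orthogonal matrix; improper = TRUE forces det(Q) == -1
randomO3 <- function(improper = FALSE) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (improper && det(Q) > 0) Q[, 1] <- -Q[, 1]
  if (!improper && det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# exhaustive 27-image minimum-image oracle
oracleMinImage <- function(delta, lattice) {
  best <- delta
  bn <- sum(delta^2)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    cand <- delta - (i * lattice[1, ] + j * lattice[2, ] + k * lattice[3, ])
    if (sum(cand^2) < bn) { best <- cand; bn <- sum(cand^2) }
  }
  best
}

# canonical half-list pair set as a sorted "i-j" character vector
pairKey <- function(nl) {
  if (nFound(nl) == 0L) return(character(0))
  p <- neighborPairs(nl)
  i <- pmin(p[1, ], p[2, ]); j <- pmax(p[1, ], p[2, ])
  sort(unique(paste(i, j, sep = "-")))
}

smallRepConfig <- function(model, numLayers = 2L, cutoff = 3.0,
                           vectorCutoff = TRUE) {
  representationConfig(model, embeddingDimension = 8L, numLayers = numLayers,
                       radial = radialConfig(cutoff, 8L), maxZ = 20L,
                       vectorCutoff = vectorCutoff)
}

# compact cluster guaranteed connected under `cutoff`, away from the cutoff
# sphere boundary (no pair within `margin` of r_c) so finite differences
# never cross a neighbor-list discontinuity
clusterSystem <- function(n, seed, cutoff = 3.0, charged = FALSE,
                          margin = 0.05) {
  set.seed(seed)
  repeat {
    pos <- matrix(rnorm(n * 3, sd = 1.0), n, 3)
    d <- as.matrix(dist(pos))
    off <- d[upper.tri(d)]
    if (min(off) > 0.7 && !any(abs(off - cutoff) < margin)) break
  }
  q <- NULL
  if (charged) { q <- runif(n, -0.3, 0.3); q <- q - mean(q) }
  particleSystem(pos, sample(c(1L, 6L, 7L, 8L, 16L), n, replace = TRUE),
                 charges = q)
}
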