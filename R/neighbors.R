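# Neighbor-search engine: brute force and cell list, batch aware, with
# open/rectangular/triclinic periodic boundaries and a padded static-shape
# output contract (sentinel -1 in unused slots).

# minimum-image displacement plus the lattice translation that was applied,
# operating on an M x 3 matrix of displacements
.minimumImageM <- function(delta, box) {
  if (is.null(box) || box@kind == "open") {
    return(list(delta = delta, shift = matrix(0, nrow(delta), 3L)))
  }
  L <- box@lattice
  d0 <- delta
  if (box@kind == "rectangular") {
    Ld <- diag(L)
    for (k in 3:1) delta[, k] <- delta[, k] - Ld[k] * round(delta[, k] / Ld[k])
  } else {
    # sequential reduction against rows c, then b, then a of the reduced
    # lower-triangular lattice; exact for |delta| < min(diag)/2
    for (k in 3:1) {
      nk <- round(delta[, k] / L[k, k])
      delta <- delta - outer(nk, L[k, ])
    }
  }
  list(delta = delta, shift = delta - d0)
}

#' Minimum-image displacement under periodic boundaries
#'
#' Maps a displacement vector to the displacement towards the nearest
#' periodic image. Open boundaries return the input unchanged; rectangular
#' boxes reduce each axis independently; triclinic (reduced lower-
#' triangular) boxes are reduced sequentially against lattice rows c, b, a,
#' which is exact whenever the reduced displacement is shorter than half the
#' smallest diagonal entry (the same single-image condition enforced for
#' neighbor searches).
#'
#' @param delta length-3 displacement or M x 3 matrix of displacements
#'   (Angstrom).
#' @param box a [SimulationBox-class].
#' @return displacement(s) with the same shape as the input.
#' @examples
#' box <- simulationBox(c(10, 10, 10))
#' minimumImage(c(9.4, 0, 0), box)   # -> (-0.6, 0, 0)
#' @export
minimumImage <- function(delta, box) {
  vec <- is.null(dim(delta))
  m <- if (vec) matrix(as.double(delta), 1L, 3L) else matrix(as.double(delta), ncol = 3L)
  if (!all(is.finite(m))) stop("minimumImage: displacement must be finite")
  validObject(box)
  out <- .minimumImageM(m, box)$delta
  if (vec) as.vector(out) else out
}

.overflowError <- function(required, capacity) {
  stop(errorCondition(
    sprintf("neighbor list overflow: %d pairs found but capacity is %d; rebuild with capacity >= %d",
            required, capacity, required),
    required = required, capacity = capacity,
    class = c("neighborOverflowError", "error", "condition")))
}

# assemble a NeighborList from half-list pair data; sorts edges by
# (source, target) so downstream reductions have a fixed summation order
.finalizeNeighborList <- function(i, j, vec, dist, shift, capacity, cutoff,
                                  includeTranspose) {
  if (includeTranspose && length(i)) {
    i2 <- c(i, j); j2 <- c(j, i)
    vec <- rbind(vec, -vec)
    shift <- rbind(shift, -shift)
    dist <- c(dist, dist)
    i <- i2; j <- j2
  }
  m <- length(i)
  if (m) {
    ord <- order(i, j)
    i <- i[ord]; j <- j[ord]
    vec <- vec[ord, , drop = FALSE]
    shift <- shift[ord, , drop = FALSE]
    dist <- dist[ord]
  }
  if (is.null(capacity)) capacity <- m
  capacity <- as.integer(capacity)
  if (m > capacity) .overflowError(m, capacity)
  pairs <- matrix(-1L, 2L, capacity)
  ev <- matrix(0, capacity, 3L)
  sh <- matrix(0, capacity, 3L)
  dd <- numeric(capacity)
  if (m) {
    pairs[1L, seq_len(m)] <- as.integer(i)
    pairs[2L, seq_len(m)] <- as.integer(j)
    ev[seq_len(m), ] <- vec
    sh[seq_len(m), ] <- shift
    dd[seq_len(m)] <- dist
  }
  new("NeighborList", pairs = pairs, edgeVectors = ev, distances = dd,
      shifts = sh, nFound = as.integer(m), capacity = capacity,
      cutoff = as.double(cutoff), includeTranspose = includeTranspose)
}

#' Brute-force neighbor search
#'
#' Examines every unordered atom pair (O(N^2)); best for small workloads.
#' Pairs are kept when both atoms share a batch value and their
#' minimum-image distance is at most `cutoff`. Output slots beyond the found
#' count carry the sentinel -1.
#'
#' @param system a [ParticleSystem-class].
#' @param cutoff cutoff radius in Angstrom (> 0).
#' @param capacity padded output size; NULL (default) sizes the list to the
#'   exact number of pairs found. If the found count exceeds `capacity`, an
#'   error of class `neighborOverflowError` reports the required size.
#' @param includeTranspose store both edge directions (full list, default)
#'   or each unordered pair once (half list).
#' @return a [NeighborList-class].
#' @examples
#' sys <- particleSystem(cbind(c(0, 1, 2.5), 0, 0), c(1L, 1L, 1L))
#' nFound(bruteForceNeighbors(sys, cutoff = 1.5, includeTranspose = FALSE))
#' @export
bruteForceNeighbors <- function(system, cutoff, capacity = NULL,
                                includeTranspose = TRUE) {
  stopifnot(cutoff > 0)
  if (!is.null(system@box)) validateBoxCutoff(system@box, cutoff)
  n <- nAtoms(system)
  if (n < 2L) {
    return(.finalizeNeighborList(integer(0), integer(0),
                                 matrix(0, 0, 3), numeric(0), matrix(0, 0, 3),
                                 capacity, cutoff, includeTranspose))
  }
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  same <- system@batch[i] == system@batch[j]
  i <- i[same]; j <- j[same]
  delta <- system@positions[j, , drop = FALSE] - system@positions[i, , drop = FALSE]
  mi <- .minimumImageM(delta, system@box)
  dist <- sqrt(rowSums(mi$delta^2))
  keep <- dist <= cutoff
  .finalizeNeighborList(i[keep], j[keep],
                        mi$delta[keep, , drop = FALSE], dist[keep],
                        mi$shift[keep, , drop = FALSE],
                        capacity, cutoff, includeTranspose)
}

# perpendicular widths of the cell along each lattice direction
.boxHeights <- function(L) {
  v <- abs(det(L))
  crossN <- function(a, b) {
    sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
               a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])^2))
  }
  c(v / crossN(L[2, ], L[3, ]),
    v / crossN(L[3, ], L[1, ]),
    v / crossN(L[1, ], L[2, ]))
}

#' Cell-list neighbor search
#'
#' Hash-and-sort spatial binning: atoms are assigned to grid cells of edge
#' at least one cutoff (in perpendicular width), and candidates are drawn
#' only from adjacent cells. One decomposition is built jointly over all
#' batches; cross-batch candidates are rejected at distance-check time.
#' Returns the same pair set as [bruteForceNeighbors] on any input. Open-
#' boundary systems are handled through an enclosing padded box.
#'
#' @inheritParams bruteForceNeighbors
#' @return a [NeighborList-class].
#' @export
cellListNeighbors <- function(system, cutoff, capacity = NULL,
                              includeTranspose = TRUE) {
  stopifnot(cutoff > 0)
  if (!is.null(system@box)) validateBoxCutoff(system@box, cutoff)
  n <- nAtoms(system)
  if (n < 2L) {
    return(.finalizeNeighborList(integer(0), integer(0),
                                 matrix(0, 0, 3), numeric(0), matrix(0, 0, 3),
                                 capacity, cutoff, includeTranspose))
  }
  periodic <- !is.null(system@box) && system@box@kind != "open"
  pos <- system@positions
  if (periodic) {
    L <- system@box@lattice
    origin <- c(0, 0, 0)
  } else {
    lo <- apply(pos, 2L, min) - 0.5 * cutoff
    hi <- apply(pos, 2L, max) + 0.5 * cutoff
    L <- diag(pmax(hi - lo, cutoff))
    origin <- lo
  }
  frac <- sweep(pos, 2L, origin) %*% solve(L)
  if (periodic) frac <- frac - floor(frac)
  heights <- .boxHeights(L)
  ncell <- pmax(1L, as.integer(floor(heights / cutoff)))
  cellOf <- pmax(floor(sweep(frac, 2L, ncell, "*")), 0L)
  cellOf <- sweep(cellOf, 2L, ncell - 1L, pmin)  # per-axis clamp
  mode(cellOf) <- "integer"
  flat <- cellOf[, 1L] + ncell[1L] * (cellOf[, 2L] + ncell[2L] * cellOf[, 3L])
  ord <- order(flat)
  sortedFlat <- flat[ord]
  # cell -> contiguous range in `ord`
  starts <- c(1L, which(diff(sortedFlat) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  cellIds <- sortedFlat[starts]
  lookup <- new.env(parent = emptyenv(), size = length(cellIds))
  for (k in seq_along(cellIds)) {
    assign(as.character(cellIds[k]), c(starts[k], ends[k]), envir = lookup)
  }
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  iAll <- vector("list", n); jAll <- vector("list", n)
  batch <- system@batch
  for (a in seq_len(n)) {
    cc <- cellOf[a, ]
    neigh <- sweep(offs, 2L, cc, "+")
    if (periodic) {
      neigh <- sweep(neigh, 2L, ncell, function(x, m) ((x %% m) + m) %% m)
    } else {
      okr <- neigh[, 1L] >= 0L & neigh[, 1L] < ncell[1L] &
             neigh[, 2L] >= 0L & neigh[, 2L] < ncell[2L] &
             neigh[, 3L] >= 0L & neigh[, 3L] < ncell[3L]
      neigh <- neigh[okr, , drop = FALSE]
    }
    ids <- unique(neigh[, 1L] + ncell[1L] * (neigh[, 2L] + ncell[2L] * neigh[, 3L]))
    cand <- integer(0)
    for (id in ids) {
      rng <- lookup[[as.character(id)]]
      if (!is.null(rng)) cand <- c(cand, ord[rng[1L]:rng[2L]])
    }
    cand <- cand[cand > a & batch[cand] == batch[a]]
    if (length(cand)) {
      iAll[[a]] <- rep.int(a, length(cand))
      jAll[[a]] <- cand
    }
  }
  i <- unlist(iAll); j <- unlist(jAll)
  if (is.null(i)) i <- integer(0)
  if (is.null(j)) j <- integer(0)
  if (length(i)) {
    delta <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    mi <- .minimumImageM(delta, system@box)
    dist <- sqrt(rowSums(mi$delta^2))
    keep <- dist <= cutoff
    i <- i[keep]; j <- j[keep]
    vec <- mi$delta[keep, , drop = FALSE]
    shift <- mi$shift[keep, , drop = FALSE]
    dist <- dist[keep]
  } else {
    vec <- matrix(0, 0, 3); shift <- matrix(0, 0, 3); dist <- numeric(0)
  }
  .finalizeNeighborList(i, j, vec, dist, shift, capacity, cutoff, includeTranspose)
}

#' Choose a neighbor-search strategy by system size
#'
#' Brute force examines all pairs and wins for small systems; the cell list
#' scales near-linearly and takes over at the threshold (workloads of ten
#' thousand atoms and above by default; the boundary itself is assigned to
#' the cell list).
#'
#' @param nAtoms number of atoms.
#' @param threshold switch-over point (default 10000).
#' @return `"brute"` or `"cell"`.
#' @export
selectStrategy <- function(nAtoms, threshold = 10000L) {
  stopifnot(nAtoms >= 0)
  if (nAtoms < threshold) "brute" else "cell"
}

#' Build a neighbor list with automatic strategy selection
#'
#' @inheritParams bruteForceNeighbors
#' @param strategy `"auto"` (size-based via [selectStrategy]), `"brute"` or
#'   `"cell"`.
#' @return a [NeighborList-class].
#' @export
buildNeighbors <- function(system, cutoff, capacity = NULL,
                           includeTranspose = TRUE,
                           strategy = c("auto", "brute", "cell")) {
  strategy <- match.arg(strategy)
  if (strategy == "auto") strategy <- selectStrategy(nAtoms(system))
  if (strategy == "brute") {
    bruteForceNeighbors(system, cutoff, capacity, includeTranspose)
  } else {
    cellListNeighbors(system, cutoff, capacity, includeTranspose)
  }
}

#' Analytic backward pass for edge geometry
#'
#' Accumulates upstream gradients on edge vectors and edge distances back
#' onto atom positions: for a pair (i, j) with edge vector `v = r_j - r_i`
#' (minimum image), atom j receives `g_vec + g_dist * v / |v|` and atom i
#' its negative. Padded slots contribute exactly zero. A zero-distance edge
#' uses the defined-zero direction convention (`v/|v| := 0`).
#'
#' This closed form is what the model's differentiable edge-geometry path
#' computes; it is exposed for callers that assemble custom adjoints, and
#' doubles as an independently testable statement of the backward contract.
#'
#' @param gradEdgeVectors M x 3 upstream gradient on edge vectors (M >=
#'   nFound rows; padded rows are ignored).
#' @param gradDistances length-M upstream gradient on distances.
#' @param neighbors a [NeighborList-class] built from the positions being
#'   differentiated.
#' @param nAtoms number of atoms in the system.
#' @return N x 3 matrix of position gradients.
#' @export
edgeGeometryBackward <- function(gradEdgeVectors, gradDistances, neighbors,
                                 nAtoms) {
  m <- neighbors@nFound
  out <- matrix(0, nAtoms, 3L)
  if (m == 0L) return(out)
  gv <- matrix(as.double(gradEdgeVectors), ncol = 3L)[seq_len(m), , drop = FALSE]
  gd <- as.double(gradDistances)[seq_len(m)]
  v <- neighbors@edgeVectors[seq_len(m), , drop = FALSE]
  d <- neighbors@distances[seq_len(m)]
  u <- v
  nz <- d > 0
  u[nz, ] <- v[nz, , drop = FALSE] / d[nz]
  u[!nz, ] <- 0
  contrib <- gv + u * gd
  i <- neighbors@pairs[1L, seq_len(m)]
  j <- neighbors@pairs[2L, seq_len(m)]
  out <- .scatterRows(contrib, j, nAtoms) - .scatterRows(contrib, i, nAtoms)
  out
}
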