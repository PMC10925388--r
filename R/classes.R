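#' @import methods
#' @importFrom stats rnorm runif predict
#' @importFrom utils head tail unzip modifyList
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' SimulationBox: open, rectangular or triclinic periodic cell
#'
#' Lattice vectors are stored as the rows of a 3x3 matrix in Angstrom.
#' Triclinic boxes must be in reduced (lower-triangular) form
#' `a = (ax,0,0)`, `b = (bx,by,0)`, `c = (cx,cy,cz)` with positive
#' diagonal; reduced-form skew limits (`|bx|,|cx| <= ax/2`, `|cy| <= by/2`)
#' are enforced so that sequential minimum-image reduction is exact for any
#' displacement shorter than half the smallest diagonal entry.
#'
#' @slot lattice 3x3 double matrix of row lattice vectors, or NULL for open
#'   boundaries.
#' @slot kind one of "open", "rectangular", "triclinic".
#' @export
setClass("SimulationBox",
         representation(lattice = "matrixOrNULL", kind = "character"))

setValidity("SimulationBox", function(object) {
  kind <- object@kind
  if (length(kind) != 1L || !kind %in% c("open", "rectangular", "triclinic")) {
    return("kind must be one of 'open', 'rectangular', 'triclinic'")
  }
  L <- object@lattice
  if (kind == "open") {
    if (!is.null(L)) return("open box must have NULL lattice")
    return(TRUE)
  }
  if (is.null(L) || !all(dim(L) == c(3L, 3L)) || !all(is.finite(L))) {
    return("lattice must be a finite 3x3 matrix")
  }
  if (any(diag(L) <= 0)) return("lattice diagonal entries must be > 0")
  off <- L; diag(off) <- 0
  if (kind == "rectangular") {
    if (any(off != 0)) return("rectangular box must have zero off-diagonal entries")
  } else {
    if (L[1, 2] != 0 || L[1, 3] != 0 || L[2, 3] != 0) {
      return("triclinic lattice must be reduced lower-triangular (a=(ax,0,0), b=(bx,by,0), c=(cx,cy,cz))")
    }
    if (abs(L[2, 1]) > L[1, 1] / 2 + 1e-12 || abs(L[3, 1]) > L[1, 1] / 2 + 1e-12 ||
        abs(L[3, 2]) > L[2, 2] / 2 + 1e-12) {
      return("triclinic lattice is not in reduced form (skew exceeds half the box edge)")
    }
  }
  TRUE
})

#' Construct a simulation box
#'
#' @param lattice NULL (open boundaries) or a 3x3 matrix of row lattice
#'   vectors in Angstrom. A length-3 vector is accepted as shorthand for a
#'   rectangular box.
#' @return a [SimulationBox-class] object.
#' @examples
#' simulationBox(c(10, 10, 10))      # rectangular
#' simulationBox(NULL)               # open boundaries
#' @export
simulationBox <- function(lattice = NULL) {
  if (is.null(lattice)) {
    return(new("SimulationBox", lattice = NULL, kind = "open"))
  }
  if (is.numeric(lattice) && is.null(dim(lattice)) && length(lattice) == 3L) {
    lattice <- diag(as.double(lattice))
  }
  lattice <- matrix(as.double(lattice), 3L, 3L)
  off <- lattice; diag(off) <- 0
  kind <- if (all(off == 0)) "rectangular" else "triclinic"
  new("SimulationBox", lattice = lattice, kind = kind)
}

#' Check that a box can serve a cutoff under the single-image convention
#'
#' Periodic kinds require `cutoff <= min(diag(lattice))/2` so that at most
#' one periodic image of any neighbor can lie within the cutoff.
#'
#' @param box a [SimulationBox-class].
#' @param cutoff cutoff radius in Angstrom.
#' @return invisibly TRUE; errors otherwise.
#' @export
validateBoxCutoff <- function(box, cutoff) {
  if (box@kind != "open") {
    lim <- min(diag(box@lattice)) / 2
    if (cutoff > lim + 1e-12) {
      stop(sprintf("cutoff %.4g exceeds half the smallest box extent (%.4g): single-image convention violated",
                   cutoff, lim))
    }
  }
  invisible(TRUE)
}

setClassUnion("SimulationBoxOrNULL", c("SimulationBox", "NULL"))

#' ParticleSystem: one batched collection of atoms
#'
#' The model input: positions R (Angstrom), atomic numbers Z, a batch index
#' assigning each atom to a sample, optional per-atom partial charges q
#' (elementary charge units) and an optional periodic box shared by all
#' samples in the batch.
#'
#' @slot positions N x 3 double matrix (Angstrom).
#' @slot atomicNumbers integer vector of length N (>= 1).
#' @slot batch integer vector of length N, values 0..B-1, non-decreasing.
#' @slot charges optional numeric vector of length N, or NULL.
#' @slot box optional [SimulationBox-class], or NULL (open boundaries).
#' @export
setClass("ParticleSystem",
         representation(positions = "matrix", atomicNumbers = "integer",
                        batch = "integer", charges = "numericOrNULL",
                        box = "SimulationBoxOrNULL"))

setValidity("ParticleSystem", function(object) {
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3L) return("positions must be N x 3")
  if (n > 0 && !all(is.finite(object@positions))) return("positions must be finite")
  if (length(object@atomicNumbers) != n) return("atomicNumbers length must match positions")
  if (n > 0 && any(object@atomicNumbers < 1L)) return("atomic numbers must be >= 1")
  if (length(object@batch) != n) return("batch length must match positions")
  if (n > 0) {
    b <- object@batch
    if (any(diff(b) < 0L)) return("batch must be non-decreasing (samples contiguous)")
    if (b[1] != 0L || !identical(sort(unique(b)), seq(0L, max(b)))) {
      return("batch values must be 0..B-1 with no gaps")
    }
  }
  if (!is.null(object@charges) && length(object@charges) != n) {
    return("charges length must match positions")
  }
  TRUE
})

#' Construct a particle system
#'
#' @param positions N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param atomicNumbers length-N integer vector of atomic numbers.
#' @param batch length-N integer batch assignment (default: all sample 0).
#' @param charges optional length-N numeric partial charges.
#' @param box optional [SimulationBox-class] (NULL = open boundaries).
#' @return a [ParticleSystem-class].
#' @examples
#' sys <- particleSystem(matrix(c(0, 0, 0, 1.1, 0, 0), 2, 3, byrow = TRUE),
#'                       atomicNumbers = c(8L, 1L))
#' nAtoms(sys)
#' @export
particleSystem <- function(positions, atomicNumbers,
                           batch = NULL, charges = NULL, box = NULL) {
  positions <- matrix(as.double(positions), ncol = 3L)
  n <- nrow(positions)
  if (is.null(batch)) batch <- rep(0L, n)
  new("ParticleSystem", positions = positions,
      atomicNumbers = as.integer(atomicNumbers),
      batch = as.integer(batch),
      charges = if (is.null(charges)) NULL else as.double(charges),
      box = box)
}

#' Accessors for ParticleSystem
#' @param x a [ParticleSystem-class].
#' @return the corresponding component.
#' @name particle-accessors
NULL

#' @rdname particle-accessors
#' @export
nAtoms <- function(x) nrow(x@positions)

#' @rdname particle-accessors
#' @export
nBatches <- function(x) if (nAtoms(x) == 0L) 0L else max(x@batch) + 1L

#' @rdname particle-accessors
#' @export
positions <- function(x) x@positions

#' @rdname particle-accessors
#' @export
atomicNumbers <- function(x) x@atomicNumbers

#' @rdname particle-accessors
#' @export
batchIndex <- function(x) x@batch

setMethod("show", "ParticleSystem", function(object) {
  cat(sprintf("ParticleSystem: %d atoms, %d sample(s), %s box%s\n",
              nAtoms(object), nBatches(object),
              if (is.null(object@box)) "open" else object@box@kind,
              if (is.null(object@charges)) "" else ", charged"))
})

#' NeighborList: fixed-capacity padded edge set
#'
#' Slots `[1, nFound]` hold real pairs; the remaining slots up to `capacity`
#' are padding carrying the sentinel -1 in both rows of `pairs`. Edge
#' vectors are minimum-image displacements `r[j] - r[i]`; `shifts` records
#' the periodic translation so that `edgeVectors = pos[j] - pos[i] + shifts`
#' exactly (needed to re-derive edge geometry differentiably).
#'
#' @slot pairs 2 x capacity integer matrix (1-based source/target; -1 pad).
#' @slot edgeVectors capacity x 3 double matrix.
#' @slot distances length-capacity double vector.
#' @slot shifts capacity x 3 double matrix of periodic image translations.
#' @slot nFound number of real pairs.
#' @slot capacity padded length.
#' @slot cutoff build cutoff (Angstrom).
#' @slot includeTranspose whether both edge directions are stored.
#' @export
setClass("NeighborList",
         representation(pairs = "matrix", edgeVectors = "matrix",
                        distances = "numeric", shifts = "matrix",
                        nFound = "integer", capacity = "integer",
                        cutoff = "numeric", includeTranspose = "logical"))

setValidity("NeighborList", function(object) {
  m <- object@capacity
  if (ncol(object@pairs) != m || nrow(object@pairs) != 2L) return("pairs must be 2 x capacity")
  if (nrow(object@edgeVectors) != m || length(object@distances) != m) {
    return("edgeVectors/distances must have `capacity` entries")
  }
  if (object@nFound > m) return("nFound exceeds capacity")
  if (m > object@nFound) {
    pad <- object@pairs[, (object@nFound + 1L):m, drop = FALSE]
    if (any(pad != -1L)) return("padding slots must carry the sentinel -1")
  }
  TRUE
})

setMethod("show", "NeighborList", function(object) {
  cat(sprintf("NeighborList: %d pair(s) (capacity %d, cutoff %.3g A, %s list)\n",
              object@nFound, object@capacity, object@cutoff,
              if (object@includeTranspose) "full" else "half"))
})

#' Accessors for NeighborList
#' @param x a [NeighborList-class].
#' @return real (non-padded) entries of the corresponding slot.
#' @name neighbor-accessors
NULL

#' @rdname neighbor-accessors
#' @export
nFound <- function(x) x@nFound

#' @rdname neighbor-accessors
#' @export
neighborPairs <- function(x) x@pairs[, seq_len(x@nFound), drop = FALSE]

#' @rdname neighbor-accessors
#' @export
edgeVectors <- function(x) x@edgeVectors[seq_len(x@nFound), , drop = FALSE]

#' @rdname neighbor-accessors
#' @export
edgeDistances <- function(x) x@distances[seq_len(x@nFound)]

#' Prediction: per-sample scalar output and optional negative gradient
#'
#' @slot y length-B numeric per-sample scalar (energy units).
#' @slot negDy N x 3 matrix of `-dy/dR` (forces), or NULL when the model was
#'   run without derivative.
#' @export
setClass("Prediction", representation(y = "numeric", negDy = "matrixOrNULL"))

setMethod("show", "Prediction", function(object) {
  cat(sprintf("Prediction: %d sample(s)%s\n", length(object@y),
              if (is.null(object@negDy)) "" else sprintf(", forces for %d atom(s)", nrow(object@negDy))))
  if (length(object@y)) cat("  y:", format(head(object@y, 5), digits = 6),
                            if (length(object@y) > 5) "..." else "", "\n")
})

#' @rdname Prediction-class
#' @param x a Prediction.
#' @export
predictionEnergy <- function(x) x@y

#' @rdname Prediction-class
#' @export
predictionForces <- function(x) x@negDy
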