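# Conformer datasets: the indexed (Z, R, y [, neg_dy, q]) collections that
# training consumes, plus loaders/writers for the NumPy "custom" layout and
# a documented HDF5 layout, and seed-deterministic train/val/test splits.

#' ConformerDataset: indexed conformer records
#'
#' Each record is a list with elements `z` (integer atomic numbers), `pos`
#' (n x 3 Angstrom), `y` (scalar energy), optional `negDy` (n x 3 forces)
#' and optional `q` (per-atom charges). Records may differ in atom count.
#'
#' @slot records list of records.
#' @export
setClass("ConformerDataset", representation(records = "list"))

setValidity("ConformerDataset", function(object) {
  for (k in seq_along(object@records)) {
    r <- object@records[[k]]
    n <- length(r$z)
    if (!is.matrix(r$pos) || nrow(r$pos) != n || ncol(r$pos) != 3L) {
      return(sprintf("record %d: pos must be %d x 3", k, n))
    }
    if (length(r$y) != 1L || !is.finite(r$y)) return(sprintf("record %d: y must be a finite scalar", k))
    if (!is.null(r$negDy) && (!is.matrix(r$negDy) || !all(dim(r$negDy) == dim(r$pos)))) {
      return(sprintf("record %d: negDy shape mismatch", k))
    }
    if (!is.null(r$q) && length(r$q) != n) return(sprintf("record %d: charge length mismatch", k))
  }
  TRUE
})

#' @rdname ConformerDataset-class
#' @param records list of conformer records.
#' @export
conformerDataset <- function(records) new("ConformerDataset", records = records)

#' @rdname ConformerDataset-class
#' @param x a ConformerDataset.
#' @export
setMethod("length", "ConformerDataset", function(x) length(x@records))

#' @rdname ConformerDataset-class
#' @param i record index.
#' @export
setMethod("[[", "ConformerDataset", function(x, i) x@records[[i]])

setMethod("show", "ConformerDataset", function(object) {
  ns <- vapply(object@records, function(r) length(r$z), integer(1))
  cat(sprintf("ConformerDataset: %d record(s), %s atoms/record, forces: %s\n",
              length(object@records),
              if (length(ns)) paste0(min(ns), "-", max(ns)) else "0",
              if (length(object@records) && !is.null(object@records[[1]]$negDy)) "yes" else "no"))
})

#' Does a dataset carry forces?
#' @param dataset a [ConformerDataset-class].
#' @return logical.
#' @export
hasForces <- function(dataset) {
  length(dataset@records) > 0 && !is.null(dataset@records[[1]]$negDy)
}

#' Collate dataset records into one batched ParticleSystem
#'
#' Concatenates the selected records, assigning consecutive batch indices;
#' targets are stacked alongside.
#'
#' @param dataset a [ConformerDataset-class].
#' @param idx record indices.
#' @return list with `system` ([ParticleSystem-class]), `y` (numeric),
#'   `negDy` (matrix or NULL).
#' @export
collateRecords <- function(dataset, idx) {
  recs <- dataset@records[idx]
  ns <- vapply(recs, function(r) length(r$z), integer(1))
  pos <- do.call(rbind, lapply(recs, function(r) r$pos))
  z <- unlist(lapply(recs, function(r) r$z))
  batch <- rep(seq_along(recs) - 1L, ns)
  q <- if (length(recs) && !is.null(recs[[1]]$q)) unlist(lapply(recs, function(r) r$q)) else NULL
  negDy <- if (length(recs) && !is.null(recs[[1]]$negDy)) {
    do.call(rbind, lapply(recs, function(r) r$negDy))
  } else NULL
  list(system = particleSystem(pos, z, batch = batch, charges = q),
       y = vapply(recs, function(r) as.double(r$y), double(1)),
       negDy = negDy)
}

# ---- NumPy custom layout ----------------------------------------------

.resolveGlob <- function(pattern, what) {
  files <- sort(Sys.glob(pattern))
  if (!length(files)) stop(sprintf("%s glob '%s' matches no files", what, pattern))
  files
}

#' Load a dataset from the NumPy "custom" layout
#'
#' One file group per molecule, matched by sorted glob order: coordinates
#' `(n_conf, n_atoms, 3)`, embedding indices (atomic numbers) `(n_atoms,)`
#' shared by all conformers of the molecule, energies `(n_conf, 1)` or
#' `(n_conf,)`, and optionally forces `(n_conf, n_atoms, 3)`.
#'
#' @param coordGlob,embedGlob,energyGlob,forceGlob glob patterns for the
#'   four file roles (`forceGlob` optional).
#' @return a [ConformerDataset-class].
#' @export
loadCustomNumpy <- function(coordGlob, embedGlob, energyGlob, forceGlob = NULL) {
  cf <- .resolveGlob(coordGlob, "coordinates")
  ef <- .resolveGlob(embedGlob, "embeddings")
  yf <- .resolveGlob(energyGlob, "energies")
  ff <- if (!is.null(forceGlob)) .resolveGlob(forceGlob, "forces") else NULL
  if (length(ef) != length(cf) || length(yf) != length(cf) ||
      (!is.null(ff) && length(ff) != length(cf))) {
    stop("custom dataset: file-group counts differ between roles")
  }
  records <- list()
  for (g in seq_along(cf)) {
    coords <- readNpy(cf[g])
    z <- as.integer(readNpy(ef[g]))
    y <- readNpy(yf[g])
    if (is.matrix(y)) y <- as.vector(y)
    dc <- dim(coords)
    if (is.null(dc) || length(dc) != 3L || dc[3] != 3L) {
      stop(sprintf("coordinate file '%s' must have shape (n_conf, n_atoms, 3)", cf[g]))
    }
    if (dc[2] != length(z)) {
      stop(sprintf("atom count mismatch between '%s' (%d) and '%s' (%d)",
                   cf[g], dc[2], ef[g], length(z)))
    }
    if (length(y) != dc[1]) {
      stop(sprintf("conformer count mismatch between '%s' (%d) and '%s' (%d)",
                   cf[g], dc[1], yf[g], length(y)))
    }
    forces <- NULL
    if (!is.null(ff)) {
      forces <- readNpy(ff[g])
      if (!identical(dim(forces), dc)) {
        stop(sprintf("force file '%s' shape differs from coordinates '%s'", ff[g], cf[g]))
      }
    }
    for (cfm in seq_len(dc[1])) {
      records[[length(records) + 1L]] <- list(
        z = z, pos = matrix(coords[cfm, , ], ncol = 3L), y = y[cfm],
        negDy = if (is.null(forces)) NULL else matrix(forces[cfm, , ], ncol = 3L),
        q = NULL)
    }
  }
  conformerDataset(records)
}

#' Write a dataset in the NumPy custom layout
#'
#' Records are grouped into molecules by identical atomic-number vectors
#' (conformers of one molecule share the embedding file).
#'
#' @param dataset a [ConformerDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the glob patterns to reload the files.
#' @export
writeCustomNumpy <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- vapply(dataset@records, function(r) paste(r$z, collapse = ","), "")
  groups <- split(seq_along(sig), factor(sig, levels = unique(sig)))
  withForces <- hasForces(dataset)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    recs <- dataset@records[idx]
    na <- length(recs[[1]]$z); nc <- length(recs)
    coords <- array(0, c(nc, na, 3L))
    forces <- if (withForces) array(0, c(nc, na, 3L)) else NULL
    for (k in seq_len(nc)) {
      coords[k, , ] <- recs[[k]]$pos
      if (withForces) forces[k, , ] <- recs[[k]]$negDy
    }
    base <- file.path(dir, sprintf("mol%03d", g))
    writeNpy(coords, paste0(base, "_coord.npy"))
    writeNpy(as.integer(recs[[1]]$z), paste0(base, "_embed.npy"))
    writeNpy(matrix(vapply(recs, function(r) r$y, 0), ncol = 1L),
             paste0(base, "_energy.npy"))
    if (withForces) writeNpy(forces, paste0(base, "_force.npy"))
  }
  invisible(list(coordGlob = file.path(dir, "*_coord.npy"),
                 embedGlob = file.path(dir, "*_embed.npy"),
                 energyGlob = file.path(dir, "*_energy.npy"),
                 forceGlob = if (withForces) file.path(dir, "*_force.npy") else NULL))
}

# ---- HDF5 layout ------------------------------------------------------

#' Load a dataset from the documented HDF5 layout
#'
#' One group per molecule with datasets `types` (n_atoms), `pos`
#' `(n_conf, n_atoms, 3)`, `energy` (n_conf), optionally `forces`
#' `(n_conf, n_atoms, 3)` and `partial_charges` (n_atoms). The whole file
#' is materialized on load (records are small R objects thereafter).
#'
#' @param path HDF5 file path.
#' @return a [ConformerDataset-class].
#' @export
loadHDF5 <- function(path) {
  raw <- cppH5Read(path)
  records <- list()
  for (gname in names(raw)) {
    g <- raw[[gname]]
    need <- c("types", "pos", "energy")
    miss <- setdiff(need, names(g))
    if (length(miss)) {
      stop(sprintf("HDF5 group '/%s' is missing dataset(s): %s", gname,
                   paste(miss, collapse = ", ")))
    }
    z <- as.integer(g$types$data)
    dp <- g$pos$dims
    if (length(dp) != 3L || dp[3] != 3L || dp[2] != length(z)) {
      stop(sprintf("HDF5 group '/%s': pos must be (n_conf, %d, 3)", gname, length(z)))
    }
    pos <- .fromCOrder(g$pos$data, dp)
    y <- as.vector(g$energy$data)
    if (length(y) != dp[1]) {
      stop(sprintf("HDF5 group '/%s': energy count %d != conformer count %d",
                   gname, length(y), dp[1]))
    }
    forces <- if (!is.null(g$forces)) .fromCOrder(g$forces$data, g$forces$dims) else NULL
    q <- if (!is.null(g$partial_charges)) as.double(g$partial_charges$data) else NULL
    for (k in seq_len(dp[1])) {
      records[[length(records) + 1L]] <- list(
        z = z, pos = matrix(pos[k, , ], ncol = 3L), y = y[k],
        negDy = if (is.null(forces)) NULL else matrix(forces[k, , ], ncol = 3L),
        q = q)
    }
  }
  conformerDataset(records)
}

#' Write a dataset in the HDF5 layout
#'
#' @param dataset a [ConformerDataset-class].
#' @param path output file (overwritten).
#' @return invisibly `path`.
#' @export
writeHDF5Dataset <- function(dataset, path) {
  sig <- vapply(dataset@records, function(r) paste(r$z, collapse = ","), "")
  groups <- split(seq_along(sig), factor(sig, levels = unique(sig)))
  payload <- list()
  withForces <- hasForces(dataset)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    recs <- dataset@records[idx]
    na <- length(recs[[1]]$z); nc <- length(recs)
    coords <- array(0, c(nc, na, 3L))
    forces <- if (withForces) array(0, c(nc, na, 3L)) else NULL
    for (k in seq_len(nc)) {
      coords[k, , ] <- recs[[k]]$pos
      if (withForces) forces[k, , ] <- recs[[k]]$negDy
    }
    entry <- list(
      types = list(data = as.integer(recs[[1]]$z), dims = na),
      pos = list(data = .cOrder(coords), dims = dim(coords)),
      energy = list(data = vapply(recs, function(r) r$y, 0), dims = nc))
    if (withForces) entry$forces <- list(data = .cOrder(forces), dims = dim(forces))
    if (!is.null(recs[[1]]$q)) {
      entry$partial_charges <- list(data = as.double(recs[[1]]$q), dims = na)
    }
    payload[[sprintf("mol%03d", g)]] <- entry
  }
  cppH5Write(path, payload)
  invisible(path)
}

# ---- splits -----------------------------------------------------------

#' Deterministic train/validation/test splits
#'
#' Sizes may be given as counts or as fractions (fractions are resolved by
#' rounding, remainder to the training set). The shuffled assignment is
#' reproducible from the seed and can be persisted to an NPZ index file
#' (1-based indices) for reuse.
#'
#' @param n dataset size.
#' @param trainSize,valSize,testSize counts or fractions; any one of them
#'   NULL means "the remainder".
#' @param seed RNG seed for the shuffle.
#' @param file optional path to persist the split as an NPZ index file.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @examples
#' s <- makeSplits(10, 6, 2, 2, seed = 1)
#' lengths(s)
#' @export
makeSplits <- function(n, trainSize, valSize, testSize, seed = 0L, file = NULL) {
  resolve <- function(x) {
    if (is.null(x)) return(NA_integer_)
    if (x < 1 && x > 0) as.integer(round(x * n)) else as.integer(x)
  }
  tr <- resolve(trainSize); va <- resolve(valSize); te <- resolve(testSize)
  sizes <- c(tr, va, te)
  if (sum(is.na(sizes)) > 1L) stop("at most one split size may be NULL")
  if (any(is.na(sizes))) sizes[is.na(sizes)] <- n - sum(sizes, na.rm = TRUE)
  if (any(sizes < 0) || sum(sizes) > n) {
    stop(sprintf("split sizes %d/%d/%d oversubscribe the dataset (n=%d)",
                 sizes[1], sizes[2], sizes[3], n))
  }
  rng <- .seededRNG(seed)
  perm <- order(rng(n))
  out <- list(train = sort(perm[seq_len(sizes[1])]),
              val = sort(perm[sizes[1] + seq_len(sizes[2])]),
              test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  if (!is.null(file)) saveSplits(out, file)
  out
}

#' @rdname makeSplits
#' @param splits a splits list as returned by `makeSplits`.
#' @export
saveSplits <- function(splits, file) {
  writeNpz(list(idx_train = as.integer(splits$train),
                idx_val = as.integer(splits$val),
                idx_test = as.integer(splits$test)), file)
  invisible(file)
}

#' @rdname makeSplits
#' @export
loadSplits <- function(file) {
  z <- readNpz(file)
  list(train = as.integer(z$idx_train), val = as.integer(z$idx_val),
       test = as.integer(z$idx_test))
}

# isolated RNG stream so library code does not disturb the caller's RNG
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
    out
  }
}
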