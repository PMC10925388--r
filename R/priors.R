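# Physics-based prior energies. All priors derive from the virtual S4
# class `Prior` and plug into the model through two generics: priorLevel()
# says whether the term modifies per-atom energies (before reduction) or
# per-sample energies (after), and priorEnergyNode() builds the term as a
# differentiable graph node, so forces automatically include every prior
# (contributions are added before the gradient is taken).
#
# Pairwise priors sum over each unordered pair once (half-list convention,
# realized by a mask on the full edge list).

#' Virtual base class for physical priors
#'
#' Extend this class and provide methods for [priorLevel] and
#' [priorEnergyNode] to add a custom prior; custom priors compose exactly
#' like the built-ins.
#' @export
setClass("Prior", representation("VIRTUAL"))

#' Prior generics
#'
#' @param prior a [Prior-class] object.
#' @param ctx evaluation context assembled by the model (graph nodes for
#'   distances, masks, indices; see the implementations).
#' @param params named list of parameter nodes for trainable priors.
#' @param prefix parameter-name prefix assigned to this prior instance.
#' @return `priorLevel`: `"atom"` or `"molecule"`. `priorEnergyNode`: an
#'   `adNode` -- per-atom column for atom-level priors, per-sample column
#'   (including the ghost batch row) for molecule-level priors.
#'   `priorTrainableParams`: named list of initial parameter matrices
#'   (empty for non-trainable priors).
#' @name prior-generics
#' @export
setGeneric("priorLevel", function(prior) standardGeneric("priorLevel"))

#' @rdname prior-generics
#' @export
setGeneric("priorEnergyNode", function(prior, ctx, params, prefix)
  standardGeneric("priorEnergyNode"))

#' @rdname prior-generics
#' @export
setGeneric("priorTrainableParams", function(prior) standardGeneric("priorTrainableParams"))

setMethod("priorTrainableParams", "Prior", function(prior) list())

# ---- Atomref ----------------------------------------------------------

#' Per-element reference energy prior
#'
#' Adds a per-element reference energy `table[z]` to every atom's energy.
#' With `trainable = TRUE` the table is a learnable parameter initialized
#' from the provided references; the network then only has to model the
#' residual (formation-energy-like) part.
#'
#' @slot table numeric vector indexed by atomic number (energy units).
#' @slot trainable logical.
#' @export
setClass("AtomrefPrior", contains = "Prior",
         representation(table = "numeric", trainable = "logical"))

#' @rdname AtomrefPrior-class
#' @param table numeric vector of reference energies indexed by atomic
#'   number (position 1 = hydrogen).
#' @param trainable make the table learnable (default FALSE).
#' @return an [AtomrefPrior-class].
#' @export
atomrefPrior <- function(table, trainable = FALSE) {
  new("AtomrefPrior", table = as.double(table), trainable = isTRUE(trainable))
}

setMethod("priorLevel", "AtomrefPrior", function(prior) "atom")

setMethod("priorTrainableParams", "AtomrefPrior", function(prior) {
  if (!prior@trainable) return(list())
  # stored with one trailing ghost row (zero) so the ghost atom looks up a
  # harmless entry
  list(atomref = matrix(c(prior@table, 0), ncol = 1L))
})

setMethod("priorEnergyNode", "AtomrefPrior", function(prior, ctx, params, prefix) {
  zReal <- ctx$z
  if (any(zReal > length(prior@table))) {
    bad <- min(zReal[zReal > length(prior@table)])
    stop(sprintf("atomref prior: no reference energy for element Z=%d", bad))
  }
  if (prior@trainable) {
    tab <- params[[paste0(prefix, ".atomref")]]
    ghostRow <- nrow(adValue(tab))
    idx <- c(zReal, rep(ghostRow, ctx$ntot - length(zReal)))
    adGather(tab, idx)
  } else {
    vals <- c(prior@table[zReal], rep(0, ctx$ntot - length(zReal)))
    adConst(matrix(vals, ncol = 1L))
  }
})

# ---- Coulomb ----------------------------------------------------------

#' Switched Coulomb electrostatic prior
#'
#' Pairwise energy `sw(r) k q_i q_j / r` summed over each unordered pair
#' within the neighbor cutoff, with the cosine switching function
#' `sw(r) = (1 - cos(pi r / r_sw)) / 2` for `r < r_sw` and 1 beyond, which
#' suppresses the short-range singularity (`sw(0) = 0`) and restores the
#' full Coulomb interaction smoothly at the switching distance. Requires
#' per-atom partial charges on the system.
#'
#' @slot switchingDistance r_sw in Angstrom.
#' @slot coulombConstant k in (energy unit) * Angstrom / e^2 (14.3996 for
#'   eV).
#' @export
setClass("CoulombPrior", contains = "Prior",
         representation(switchingDistance = "numeric", coulombConstant = "numeric"))

#' @rdname CoulombPrior-class
#' @param switchingDistance inner switching distance in Angstrom.
#' @param coulombConstant Coulomb constant in configured energy units
#'   (default eV: 14.3996 eV A / e^2).
#' @return a [CoulombPrior-class].
#' @export
coulombPrior <- function(switchingDistance, coulombConstant = 14.3996) {
  stopifnot(switchingDistance > 0)
  new("CoulombPrior", switchingDistance = as.double(switchingDistance),
      coulombConstant = as.double(coulombConstant))
}

setMethod("priorLevel", "CoulombPrior", function(prior) "molecule")

setMethod("priorEnergyNode", "CoulombPrior", function(prior, ctx, params, prefix) {
  if (is.null(ctx$q)) {
    stop("coulomb prior requires per-atom partial charges on the ParticleSystem")
  }
  rsw <- prior@switchingDistance
  d <- ctx$d
  dv <- adValue(d)
  inner <- adConst((dv < rsw) * 1)
  outer <- adConst((dv >= rsw) * 1)
  sw <- adAdd(adMul(adMul(adSub(1, adCos(adMul(d, pi / rsw))), 0.5), inner), outer)
  qq <- ctx$q[ctx$iReal] * ctx$q[ctx$jReal]  # zero-padded for ghost edges
  eTerm <- adMul(adRowScale(adDiv(sw, d), adConst(matrix(qq, ncol = 1L))),
                 prior@coulombConstant)
  adScatter(adMul(eTerm, ctx$halfMask), ctx$edgeBatch, ctx$nbatchTot)
})

# ---- ZBL --------------------------------------------------------------

#' Ziegler-Biersack-Littmark screened nuclear repulsion prior
#'
#' Universal screened Coulomb repulsion
#' `E = phi(r) * k Z_i Z_j / r * f(r / a_ij)` summed over unordered pairs,
#' with the four-exponential universal screening function
#' `f(x) = sum_m c_m exp(-e_m x)` (coefficients summing to 1 so `f(0) = 1`),
#' the Z-dependent screening length `a_ij = a0 / (Z_i^p + Z_j^p)`, and the
#' cosine cutoff envelope `phi` so every contribution vanishes smoothly at
#' the neighbor cutoff. Parameters are read from the packaged table (see
#' `inst/extdata/zbl_parameters.tsv`); only atomic numbers are needed.
#'
#' @slot coefficients four screening coefficients.
#' @slot exponents four screening exponents.
#' @slot lengthScale screening-length prefactor a0 (Angstrom).
#' @slot exponentZ exponent p of the Z-dependence of the screening length.
#' @slot coulombConstant k in configured energy units.
#' @export
setClass("ZBLPrior", contains = "Prior",
         representation(coefficients = "numeric", exponents = "numeric",
                        lengthScale = "numeric", exponentZ = "numeric",
                        coulombConstant = "numeric"))

#' Load the packaged ZBL parameters
#' @return named list of the screening constants.
#' @export
zblParameters <- function() {
  path <- system.file("extdata", "zbl_parameters.tsv", package = "NNPkit")
  tab <- utils::read.delim(path, comment.char = "#")
  vals <- stats::setNames(tab$value, tab$name)
  list(coefficients = unname(vals[c("c1", "c2", "c3", "c4")]),
       exponents = unname(vals[c("e1", "e2", "e3", "e4")]),
       lengthScale = unname(vals["a0"]),
       exponentZ = unname(vals["p"]))
}

#' @rdname ZBLPrior-class
#' @param coulombConstant k in configured energy units (default eV).
#' @param parameters screening constants (default: packaged table).
#' @return a [ZBLPrior-class].
#' @export
zblPrior <- function(coulombConstant = 14.3996, parameters = zblParameters()) {
  new("ZBLPrior", coefficients = parameters$coefficients,
      exponents = parameters$exponents,
      lengthScale = parameters$lengthScale,
      exponentZ = parameters$exponentZ,
      coulombConstant = as.double(coulombConstant))
}

#' Universal ZBL screening function
#' @param x reduced separation r / a.
#' @param prior a [ZBLPrior-class].
#' @return screening values f(x).
#' @export
zblScreening <- function(x, prior = zblPrior()) {
  out <- 0
  for (m in seq_along(prior@coefficients)) {
    out <- out + prior@coefficients[m] * exp(-prior@exponents[m] * x)
  }
  out
}

setMethod("priorLevel", "ZBLPrior", function(prior) "molecule")

setMethod("priorEnergyNode", "ZBLPrior", function(prior, ctx, params, prefix) {
  zi <- ctx$zEdgeI; zj <- ctx$zEdgeJ  # doubles, ghost edges carry 1
  a <- prior@lengthScale / (zi^prior@exponentZ + zj^prior@exponentZ)
  x <- adRowScale(ctx$d, adConst(matrix(1 / a, ncol = 1L)))
  f <- NULL
  for (m in seq_along(prior@coefficients)) {
    term <- adMul(adExp(adMul(x, -prior@exponents[m])), prior@coefficients[m])
    f <- if (is.null(f)) term else adAdd(f, term)
  }
  coul <- adRowScale(adDiv(adConst(matrix(1, length(zi), 1L)), ctx$d),
                     adConst(matrix(prior@coulombConstant * zi * zj, ncol = 1L)))
  eTerm <- adMul(adMul(coul, f), ctx$env)
  adScatter(adMul(eTerm, ctx$halfMask), ctx$edgeBatch, ctx$nbatchTot)
})

# ---- D2 dispersion ----------------------------------------------------

#' DFT-D2 dispersion correction prior
#'
#' Pairwise dispersion `-s6 * C6_ij / r^6 * f_dmp(r)` with geometric-mean
#' combination `C6_ij = sqrt(C6_i C6_j)`, Fermi damping
#' `f_dmp(r) = 1 / (1 + exp(-d (r / R_ij - 1)))` around the summed van der
#' Waals radii `R_ij = r0_i + r0_j`, summed over unordered pairs within the
#' neighbor cutoff (no long-range tail correction; the truncation at the
#' cutoff is documented behaviour). Element tables (C6 in J nm^6/mol, r0 in
#' Angstrom) ship in `inst/extdata/d2_parameters.tsv`; `c6Conversion`
#' rescales C6 to (energy unit) * A^6 (default eV).
#'
#' @slot c6 per-element C6 table indexed by atomic number (J nm^6/mol;
#'   NA marks uncovered elements).
#' @slot r0 per-element vdW radii (Angstrom).
#' @slot s6 global scaling factor.
#' @slot damping damping steepness d.
#' @slot c6Conversion conversion from J nm^6/mol to configured energy
#'   units times A^6.
#' @export
setClass("D2Prior", contains = "Prior",
         representation(c6 = "numeric", r0 = "numeric", s6 = "numeric",
                        damping = "numeric", c6Conversion = "numeric"))

#' Load the packaged DFT-D2 element table
#' @return data.frame with columns `element`, `z`, `c6`, `r0`.
#' @export
d2Parameters <- function() {
  path <- system.file("extdata", "d2_parameters.tsv", package = "NNPkit")
  utils::read.delim(path, comment.char = "#")
}

#' @rdname D2Prior-class
#' @param s6 global scale (functional dependent; 1.0 by default).
#' @param damping steepness of the Fermi damping (default 20).
#' @param c6Conversion C6 unit conversion (default 10.36436: J nm^6/mol to
#'   eV A^6).
#' @param table element table (default: packaged D2 parameters).
#' @return a [D2Prior-class].
#' @export
d2Prior <- function(s6 = 1.0, damping = 20.0, c6Conversion = 10.36436,
                    table = d2Parameters()) {
  zmax <- max(table$z)
  c6 <- rep(NA_real_, zmax); r0 <- rep(NA_real_, zmax)
  c6[table$z] <- table$c6
  r0[table$z] <- table$r0
  new("D2Prior", c6 = c6, r0 = r0, s6 = as.double(s6),
      damping = as.double(damping), c6Conversion = as.double(c6Conversion))
}

setMethod("priorLevel", "D2Prior", function(prior) "molecule")

#' D2 Fermi damping function
#' @param r separation (Angstrom).
#' @param rij summed vdW radii (Angstrom).
#' @param damping steepness.
#' @return damping values in (0, 1), equal to 1/2 at `r = rij`.
#' @export
d2Damping <- function(r, rij, damping = 20.0) {
  1 / (1 + exp(-damping * (r / rij - 1)))
}

setMethod("priorEnergyNode", "D2Prior", function(prior, ctx, params, prefix) {
  zAll <- unique(ctx$z)
  bad <- zAll[zAll > length(prior@c6) | is.na(prior@c6[zAll]) | is.na(prior@r0[zAll])]
  if (length(bad)) {
    stop(sprintf("D2 prior: no C6/r0 parameters for element Z=%d", min(bad)))
  }
  zi <- ctx$zEdgeI; zj <- ctx$zEdgeJ
  c6ij <- sqrt(prior@c6[zi] * prior@c6[zj]) * prior@c6Conversion
  c6ij[is.na(c6ij)] <- 0  # ghost edges
  rij <- prior@r0[zi] + prior@r0[zj]
  rij[is.na(rij)] <- 1
  x <- adMul(adSub(adRowScale(ctx$d, adConst(matrix(1 / rij, ncol = 1L))), 1),
             prior@damping)
  fdmp <- adSigmoid(x)
  inv6 <- adPow(ctx$d, -6)
  eTerm <- adMul(adRowScale(adMul(inv6, fdmp), adConst(matrix(c6ij, ncol = 1L))),
                 -prior@s6)
  adScatter(adMul(eTerm, ctx$halfMask), ctx$edgeBatch, ctx$nbatchTot)
})
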