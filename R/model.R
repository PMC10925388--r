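# Model assembly: representation + output head + ordered priors composed
# into one object that predicts a per-sample scalar y and, when the
# derivative flag is set, its negative position gradient neg_dy.
#
# The forward pass is built as one differentiable graph:
#   positions (leaf) -> edge vectors/distances -> radial features ->
#   representation -> output head (+ atom-level priors) -> per-sample
#   reduction (+ molecule-level priors) -> y
# so neg_dy = -dy/dR is exact by construction (energy conserving), and a
# second differentiation through the same graph serves force-matching
# training.
#
# Static-shape contract: every forward appends one ghost atom; padded
# neighbor slots are directed at it and masked to exact zeros. Real atoms'
# results are therefore bit-identical for every admissible capacity.

#' Output head configuration
#'
#' Per-atom scalars come from a two-layer perceptron (C -> C/2 -> 1); the
#' per-sample value is the configured reduction over each batch segment.
#'
#' @param hiddenChannels width of the hidden layer (default: half the
#'   embedding dimension, set at assembly time).
#' @param reduceOp `"sum"` (extensive quantities, default) or `"mean"`.
#' @return a list with class `OutputConfig`.
#' @export
outputConfig <- function(hiddenChannels = NULL, reduceOp = c("sum", "mean")) {
  reduceOp <- match.arg(reduceOp)
  if (!is.null(hiddenChannels)) stopifnot(hiddenChannels >= 1)
  structure(list(hiddenChannels = hiddenChannels, reduceOp = reduceOp),
            class = "OutputConfig")
}

#' AssembledModel: representation + output head + priors
#'
#' @slot repConfig a `RepresentationConfig`.
#' @slot outConfig an `OutputConfig`.
#' @slot priors ordered list of [Prior-class] objects.
#' @slot derivative compute neg_dy = -dy/dR.
#' @slot params named list of parameter matrices.
#' @slot maxNumNeighbors per-atom neighbor capacity used by the static
#'   capacity policy.
#' @export
setClass("AssembledModel",
         representation(repConfig = "ANY", outConfig = "ANY",
                        priors = "list", derivative = "logical",
                        params = "list", maxNumNeighbors = "integer"))

setValidity("AssembledModel", function(object) {
  if (!inherits(object@repConfig, "RepresentationConfig")) return("repConfig must be a RepresentationConfig")
  if (!inherits(object@outConfig, "OutputConfig")) return("outConfig must be an OutputConfig")
  for (p in object@priors) if (!is(p, "Prior")) return("priors must extend class Prior")
  TRUE
})

setMethod("show", "AssembledModel", function(object) {
  cat(sprintf("AssembledModel: %s (%d layer(s), %d channels, cutoff %.3g A)\n",
              object@repConfig$model, object@repConfig$numLayers,
              object@repConfig$embeddingDimension, object@repConfig$radial$cutoff))
  cat(sprintf("  priors: %s\n  derivative: %s, parameters: %d\n",
              if (length(object@priors)) paste(vapply(object@priors, function(p) class(p)[1], ""), collapse = ", ") else "none",
              object@derivative, countParameters(object)))
})

#' Assemble a neural network potential
#'
#' @param repConfig a [representationConfig].
#' @param outConfig an [outputConfig].
#' @param priors ordered list of [Prior-class] objects; atom-level priors
#'   modify per-atom energies before reduction, molecule-level priors add
#'   to per-sample energies after.
#' @param derivative also return neg_dy = -dy/dR from [predict].
#' @param maxNumNeighbors capacity policy: padded lists are sized
#'   `nAtoms * maxNumNeighbors` when no explicit capacity is given.
#' @param seed RNG seed for weight initialization (uniform fan-in scaled);
#'   NULL uses the current RNG state.
#' @return an [AssembledModel-class].
#' @examples
#' model <- assembleModel(representationConfig("graph_network",
#'                                             embeddingDimension = 8,
#'                                             numLayers = 1,
#'                                             radial = radialConfig(4.5, 8)),
#'                        seed = 1)
#' sys <- particleSystem(cbind(c(0, 1.2), 0, 0), c(8L, 1L))
#' predict(model, sys)
#' @export
assembleModel <- function(repConfig, outConfig = outputConfig(),
                          priors = list(), derivative = TRUE,
                          maxNumNeighbors = 32L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- repConfig$embeddingDimension
  if (is.null(outConfig$hiddenChannels)) {
    outConfig$hiddenChannels <- max(1L, C %/% 2L)
  }
  params <- representationInit(repConfig)
  params <- .flattenLin(params, "head1", .initLin(C, outConfig$hiddenChannels))
  params <- .flattenLin(params, "head2", .initLin(outConfig$hiddenChannels, 1L))
  if (repConfig$radial$trainableRbf) {
    init <- .rbfInit(repConfig$radial)
    params[["rbf.means"]] <- matrix(init$means, 1L)
    params[["rbf.betas"]] <- matrix(init$betas, 1L)
  }
  for (k in seq_along(priors)) {
    tp <- priorTrainableParams(priors[[k]])
    for (nm in names(tp)) params[[sprintf("prior%d.%s", k, nm)]] <- tp[[nm]]
  }
  new("AssembledModel", repConfig = repConfig, outConfig = outConfig,
      priors = priors, derivative = isTRUE(derivative), params = params,
      maxNumNeighbors = as.integer(maxNumNeighbors))
}

#' Count learnable parameters
#'
#' @param model an [AssembledModel-class].
#' @return total number of learnable scalars, with a per-component
#'   breakdown in attribute `"breakdown"`.
#' @export
countParameters <- function(model) {
  comp <- function(nm) sub("\\..*$", "", nm)
  sizes <- vapply(model@params, length, integer(1))
  groups <- tapply(sizes, vapply(names(sizes), comp, ""), sum)
  total <- sum(sizes)
  attr(total, "breakdown") <- groups
  total
}

# build the full differentiable forward graph; returns nodes
.modelForward <- function(model, system, capacity = NULL, paramNodes = NULL,
                          derivative = model@derivative, neighbors = NULL) {
  repC <- model@repConfig
  cutoff <- repC$radial$cutoff
  n <- nAtoms(system)
  B <- nBatches(system)
  if (any(system@atomicNumbers > repC$maxZ)) {
    stop(sprintf("element Z=%d exceeds the model's embedding table (maxZ=%d)",
                 max(system@atomicNumbers), repC$maxZ))
  }
  if (is.null(paramNodes)) paramNodes <- lapply(model@params, adLeaf)
  if (n == 0L) {
    return(list(y = adConst(matrix(0, 0, 1)), negDy = adConst(matrix(0, 0, 3)),
                posLeaf = adLeaf(matrix(0, 0, 3)), params = paramNodes))
  }
  if (is.null(neighbors)) {
    neighbors <- buildNeighbors(system, cutoff, capacity = capacity,
                                includeTranspose = TRUE)
  }
  mcap <- neighbors@capacity
  mreal <- neighbors@nFound
  ntot <- n + 1L            # one ghost atom owns all padded edges
  ghostIdx <- ntot

  posLeaf <- adLeaf(system@positions)
  posG <- adRBind(posLeaf, adConst(matrix(0, 1L, 3L)))

  iIdx <- rep(ghostIdx, mcap); jIdx <- rep(ghostIdx, mcap)
  if (mreal > 0) {
    iIdx[seq_len(mreal)] <- neighbors@pairs[1L, seq_len(mreal)]
    jIdx[seq_len(mreal)] <- neighbors@pairs[2L, seq_len(mreal)]
  }
  shifts <- matrix(0, mcap, 3L)
  if (mreal > 0) shifts[seq_len(mreal), ] <- neighbors@shifts[seq_len(mreal), ]
  if (mcap > mreal) shifts[(mreal + 1L):mcap, 1L] <- cutoff / 2  # keep pad distances well-defined

  maskVec <- c(rep(1, mreal), rep(0, mcap - mreal))
  mask <- adConst(matrix(maskVec, ncol = 1L))

  vEdge <- adAdd(adSub(adGather(posG, jIdx), adGather(posG, iIdx)),
                 adConst(shifts))
  dEdge <- adSqrt(adRowSums(adMul(vEdge, vEdge)))
  env <- .adCosineCutoff(dEdge, cutoff)
  envMask <- adMul(env, mask)
  u <- lapply(1:3, function(k) adDiv(adCols(vEdge, k), dEdge))

  means <- if (repC$radial$trainableRbf) paramNodes[["rbf.means"]] else NULL
  betas <- if (repC$radial$trainableRbf) paramNodes[["rbf.betas"]] else NULL
  rbf <- adRowScale(.adExpandDistances(dEdge, repC$radial, means, betas), mask)

  zIdx <- c(system@atomicNumbers, repC$maxZ + 1L)  # ghost -> dedicated row
  edgeBatchVec <- rep(B + 1L, mcap)
  if (mreal > 0) edgeBatchVec[seq_len(mreal)] <- system@batch[iIdx[seq_len(mreal)]] + 1L
  halfVec <- rep(0, mcap)
  if (mreal > 0) halfVec[seq_len(mreal)] <- as.double(iIdx[seq_len(mreal)] < jIdx[seq_len(mreal)])
  if (!neighbors@includeTranspose && mreal > 0) halfVec[seq_len(mreal)] <- 1
  zEdgeI <- rep(1, mcap); zEdgeJ <- rep(1, mcap)
  if (mreal > 0) {
    zEdgeI[seq_len(mreal)] <- system@atomicNumbers[iIdx[seq_len(mreal)]]
    zEdgeJ[seq_len(mreal)] <- system@atomicNumbers[jIdx[seq_len(mreal)]]
  }

  ctx <- list(ntot = ntot, zIdx = zIdx, z = system@atomicNumbers,
              iIdx = iIdx, jIdx = jIdx, iReal = iIdx, jReal = jIdx,
              d = dEdge, v = vEdge, u = u, rbf = rbf,
              mask = mask, env = env, envMask = envMask,
              halfMask = adConst(matrix(halfVec, ncol = 1L)),
              edgeBatch = edgeBatchVec, nbatchTot = B + 1L,
              zEdgeI = zEdgeI, zEdgeJ = zEdgeJ,
              q = if (is.null(system@charges)) NULL else c(system@charges, 0))

  repOut <- .repForward(repC, paramNodes, ctx)
  perAtom <- .adLinear(adSiLU(.adLinear(repOut$scalar, paramNodes, "head1")),
                       paramNodes, "head2")

  for (k in seq_along(model@priors)) {
    pr <- model@priors[[k]]
    if (priorLevel(pr) == "atom") {
      perAtom <- adAdd(perAtom, priorEnergyNode(pr, ctx, paramNodes,
                                                sprintf("prior%d", k)))
    }
  }

  atomMask <- adConst(matrix(c(rep(1, n), 0), ncol = 1L))
  perAtomMasked <- adMul(perAtom, atomMask)
  batchAtoms <- c(system@batch + 1L, B + 1L)
  yAll <- adScatter(perAtomMasked, batchAtoms, B + 1L)

  for (k in seq_along(model@priors)) {
    pr <- model@priors[[k]]
    if (priorLevel(pr) == "molecule") {
      yAll <- adAdd(yAll, priorEnergyNode(pr, ctx, paramNodes,
                                          sprintf("prior%d", k)))
    }
  }
  y <- adGather(yAll, seq_len(B))
  if (model@outConfig$reduceOp == "mean") {
    counts <- tabulate(system@batch + 1L, nbins = B)
    y <- adRowScale(y, adConst(matrix(1 / counts, ncol = 1L)))
  }

  negDy <- NULL
  if (derivative) {
    negDy <- adNeg(adGrad(adSumAll(y), posLeaf))
  }
  list(y = y, negDy = negDy, posLeaf = posLeaf, params = paramNodes,
       neighbors = neighbors, perAtom = perAtomMasked)
}

#' Predict energy (and forces) for a particle system
#'
#' Builds a neighbor list (strategy auto-selected by system size), runs
#' representation, output head and priors, and differentiates the total
#' per-sample scalar with respect to positions when the model's derivative
#' flag is set.
#'
#' @param object an [AssembledModel-class].
#' @param system a [ParticleSystem-class].
#' @param capacity optional padded neighbor capacity (static-shape mode);
#'   see [predictStatic].
#' @param ... unused.
#' @return a [Prediction-class].
#' @export
setMethod("predict", "AssembledModel", function(object, system, capacity = NULL, ...) {
  fw <- .modelForward(object, system, capacity = capacity)
  new("Prediction", y = as.vector(adValue(fw$y)),
      negDy = if (is.null(fw$negDy)) NULL else adValue(fw$negDy))
})

#' Static-shape prediction
#'
#' Identical to [predict] but with a caller-fixed neighbor capacity:
#' placeholder pairs up to `capacity` are attached to a ghost atom and
#' masked to exact zeros, so y and neg_dy are bit-identical to the
#' unpadded run for every `capacity >=` the actual pair count. Too small a
#' capacity raises a `neighborOverflowError` carrying the required size --
#' never a silent truncation.
#'
#' @param model an [AssembledModel-class].
#' @param system a [ParticleSystem-class].
#' @param capacity padded neighbor-list size; NULL uses the model's
#'   capacity policy `nAtoms * maxNumNeighbors`.
#' @return a [Prediction-class].
#' @export
predictStatic <- function(model, system, capacity = NULL) {
  if (is.null(capacity)) capacity <- nAtoms(system) * model@maxNumNeighbors
  predict(model, system, capacity = capacity)
}
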