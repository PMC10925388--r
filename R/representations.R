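# Representation models: map a ParticleSystem + NeighborList to per-atom
# feature vectors.
#
# Three architectures are provided:
#  * "tensornet"               -- message passing on per-channel Cartesian
#    rank-2 tensors (3x3 matrices), decomposed into isotropic/antisymmetric/
#    symmetric-traceless parts; Clebsch-Gordan products are replaced by
#    node-level 3x3 matrix products. Only symmetrized products (XY + YX) are
#    formed, so features transform as X -> R X R^T under proper rotations
#    and X -> (R X R^T)^T under improper ones, making every part norm an
#    exact O(3) invariant.
#  * "equivariant_transformer" -- scalar + Cartesian-vector features with
#    distance-gated dot-product attention; the `vectorCutoff` flag applies
#    the cosine envelope to the value pathway of the attention mechanism so
#    each edge contribution vanishes continuously at the cutoff (off
#    reproduces the legacy, discontinuous behaviour).
#  * "graph_network"           -- invariant continuous-filter convolutions
#    over radial features with residual updates (SchNet-like).
#
# All models share a static-shape contract: the context carries one ghost
# atom owning every padded edge; padded rows are multiplied by a 0/1 mask,
# so padding changes nothing in real atoms' features, bit for bit.

#' Representation model configuration
#'
#' @param model one of `"tensornet"`, `"equivariant_transformer"`,
#'   `"graph_network"`.
#' @param embeddingDimension feature channels per atom (>= 1).
#' @param numLayers number of interaction layers (>= 0; 0 = embedding stage
#'   only).
#' @param radial a [radialConfig].
#' @param maxZ embedding table size (largest atomic number supported).
#' @param vectorCutoff equivariant transformer only: weight the value
#'   pathway by the cosine cutoff envelope (continuous energy surface).
#' @return a list with class `RepresentationConfig`.
#' @export
representationConfig <- function(model = c("tensornet", "equivariant_transformer",
                                           "graph_network"),
                                 embeddingDimension = 128L, numLayers = 2L,
                                 radial = radialConfig(), maxZ = 100L,
                                 vectorCutoff = TRUE) {
  model <- match.arg(model)
  stopifnot(embeddingDimension >= 1, numLayers >= 0)
  structure(list(model = model,
                 embeddingDimension = as.integer(embeddingDimension),
                 numLayers = as.integer(numLayers),
                 radial = radial, maxZ = as.integer(maxZ),
                 vectorCutoff = isTRUE(vectorCutoff)),
            class = "RepresentationConfig")
}

#' Decompose a Cartesian rank-2 tensor
#'
#' Splits a 3x3 matrix into its isotropic part `I = tr(X)/3 * Id`,
#' antisymmetric part `A = (X - X^T)/2` and symmetric traceless part
#' `S = (X + X^T)/2 - I`. The reconstruction `I + A + S = X` is exact.
#'
#' @param X a 3x3 numeric matrix.
#' @return a list with elements `I`, `A`, `S`.
#' @examples
#' p <- decomposeTensor(matrix(rnorm(9), 3, 3))
#' max(abs(p$I + p$A + p$S - (p$I + p$A + p$S)))  # parts recombine exactly
#' @export
decomposeTensor <- function(X) {
  stopifnot(is.matrix(X), all(dim(X) == c(3L, 3L)), all(is.finite(X)))
  I <- diag(3) * (sum(diag(X)) / 3)
  A <- (X - t(X)) / 2
  S <- (X + t(X)) / 2 - I
  list(I = I, A = A, S = S)
}

# ---- shared helpers ---------------------------------------------------

.initLin <- function(nin, nout, bias = TRUE) {
  s <- 1 / sqrt(nin)
  out <- list(W = matrix(runif(nin * nout, -s, s), nin, nout))
  if (bias) out$b <- matrix(runif(nout, -s, s), 1L, nout)
  out
}

.adLinear <- function(x, params, prefix) {
  W <- params[[paste0(prefix, ".W")]]
  out <- adMatMul(x, W)
  b <- params[[paste0(prefix, ".b")]]
  if (!is.null(b)) out <- adAdd(out, adBCastRows(b, nrow(adValue(out))))
  out
}

.flattenLin <- function(params, prefix, lin) {
  params[[paste0(prefix, ".W")]] <- lin$W
  if (!is.null(lin$b)) params[[paste0(prefix, ".b")]] <- lin$b
  params
}

# tensor features are lists of 9 nodes indexed [ (a-1)*3 + b ] for the
# (a,b) component, each node (Ntot x C)
.tIdx <- function(a, b) (a - 1L) * 3L + b

.tZero <- function(ntot, C) {
  z <- adConst(matrix(0, ntot, C))
  rep(list(z), 9L)
}

.tFrobSq <- function(Tn) {
  acc <- NULL
  for (k in 1:9) {
    sq <- adMul(Tn[[k]], Tn[[k]])
    acc <- if (is.null(acc)) sq else adAdd(acc, sq)
  }
  acc
}

# decompose per-channel tensors into I/A/S component lists
.tDecompose <- function(Tn) {
  tr3 <- adMul(adAdd(adAdd(Tn[[.tIdx(1, 1)]], Tn[[.tIdx(2, 2)]]), Tn[[.tIdx(3, 3)]]), 1 / 3)
  ntot <- nrow(adValue(tr3)); C <- ncol(adValue(tr3))
  zero <- adConst(matrix(0, ntot, C))
  I <- rep(list(zero), 9L); A <- rep(list(zero), 9L); S <- rep(list(zero), 9L)
  for (a in 1:3) I[[.tIdx(a, a)]] <- tr3
  for (a in 1:3) for (b in 1:3) {
    if (a < b) {
      A[[.tIdx(a, b)]] <- adMul(adSub(Tn[[.tIdx(a, b)]], Tn[[.tIdx(b, a)]]), 0.5)
      A[[.tIdx(b, a)]] <- adNeg(A[[.tIdx(a, b)]])
      S[[.tIdx(a, b)]] <- adMul(adAdd(Tn[[.tIdx(a, b)]], Tn[[.tIdx(b, a)]]), 0.5)
      S[[.tIdx(b, a)]] <- S[[.tIdx(a, b)]]
    } else if (a == b) {
      S[[.tIdx(a, a)]] <- adSub(Tn[[.tIdx(a, a)]], tr3)
    }
  }
  list(I = I, A = A, S = S)
}

.tAdd <- function(X, Y) mapply(adAdd, X, Y, SIMPLIFY = FALSE)

# channel mixing of a component list by a C x C matrix (no bias: a bias
# would inject a fixed, frame-independent tensor and break equivariance)
.tMix <- function(Tn, W) lapply(Tn, function(cmp) adMatMul(cmp, W))

# symmetrized matrix product XY + YX, per channel
.tSymProd <- function(X, Y) {
  out <- vector("list", 9L)
  for (a in 1:3) for (b in 1:3) {
    acc <- NULL
    for (cc in 1:3) {
      term <- adAdd(adMul(X[[.tIdx(a, cc)]], Y[[.tIdx(cc, b)]]),
                    adMul(Y[[.tIdx(a, cc)]], X[[.tIdx(cc, b)]]))
      acc <- if (is.null(acc)) term else adAdd(acc, term)
    }
    out[[.tIdx(a, b)]] <- acc
  }
  out
}

# ---- tensornet --------------------------------------------------------

.tensornetInit <- function(config) {
  C <- config$embeddingDimension
  K <- config$radial$numRbf
  p <- list(zEmb = matrix(runif((config$maxZ + 1L) * C, -1, 1) / sqrt(C),
                          config$maxZ + 1L, C))
  p <- .flattenLin(p, "edgeCoef", .initLin(K, 3L * C))
  p <- .flattenLin(p, "embMix", .initLin(4L * C, 3L * C))
  for (l in seq_len(config$numLayers)) {
    pre <- sprintf("layer%d", l)
    p[[paste0(pre, ".mixI")]] <- .initLin(C, C, bias = FALSE)$W
    p[[paste0(pre, ".mixA")]] <- .initLin(C, C, bias = FALSE)$W
    p[[paste0(pre, ".mixS")]] <- .initLin(C, C, bias = FALSE)$W
    p <- .flattenLin(p, paste0(pre, ".gate"), .initLin(K, 3L * C))
  }
  p <- .flattenLin(p, "out", .initLin(4L * C, C))
  p
}

.tensornetForward <- function(config, params, ctx) {
  C <- config$embeddingDimension
  ntot <- ctx$ntot
  emb <- adGather(params$zEmb, ctx$zIdx)
  m <- length(ctx$iIdx)

  # embedding stage: per-edge tensors from the unit vector, gated by radial
  # features (envelope and pad mask folded into ctx$envMask)
  X <- .tZero(ntot, C)
  if (m > 0) {
    coef <- adRowScale(adSiLU(.adLinear(ctx$rbf, params, "edgeCoef")), ctx$envMask)
    cI <- adCols(coef, 1:C)
    cA <- adCols(coef, (C + 1L):(2L * C))
    cS <- adCols(coef, (2L * C + 1L):(3L * C))
    u <- ctx$u  # list of three M x 1 unit-vector components
    skew <- list()  # skew[[a]][[b]] as M x 1 nodes
    zeroE <- adConst(matrix(0, m, 1L))
    Acomp <- list(list(zeroE, adNeg(u[[3]]), u[[2]]),
                  list(u[[3]], zeroE, adNeg(u[[1]])),
                  list(adNeg(u[[2]]), u[[1]], zeroE))
    for (a in 1:3) for (b in 1:3) {
      sab <- adMul(u[[a]], u[[b]])
      if (a == b) sab <- adSub(sab, 1 / 3)
      edge <- adAdd(adRowScale(cA, Acomp[[a]][[b]]), adRowScale(cS, sab))
      if (a == b) edge <- adAdd(edge, cI)
      X[[.tIdx(a, b)]] <- adScatter(edge, ctx$iIdx, ntot)
    }
  }

  # species-dependent channel scaling of the aggregated parts
  parts <- .tDecompose(X)
  nI <- .tFrobSq(parts$I); nA <- .tFrobSq(parts$A); nS <- .tFrobSq(parts$S)
  scale3 <- adTanh(.adLinear(adCBind(emb, nI, nA, nS), params, "embMix"))
  sI <- adCols(scale3, 1:C)
  sA <- adCols(scale3, (C + 1L):(2L * C))
  sS <- adCols(scale3, (2L * C + 1L):(3L * C))
  X <- vector("list", 9L)
  for (k in 1:9) {
    X[[k]] <- adAdd(adAdd(adMul(parts$I[[k]], sI), adMul(parts$A[[k]], sA)),
                    adMul(parts$S[[k]], sS))
  }

  for (l in seq_len(config$numLayers)) {
    pre <- sprintf("layer%d", l)
    # normalize by Frobenius norm + 1 to keep products bounded
    fn <- adAdd(adSqrt(adAdd(.tFrobSq(X), 1e-12)), 1)
    Xn <- lapply(X, function(cmp) adDiv(cmp, fn))
    parts <- .tDecompose(Xn)
    Y <- .tAdd(.tAdd(.tMix(parts$I, params[[paste0(pre, ".mixI")]]),
                     .tMix(parts$A, params[[paste0(pre, ".mixA")]])),
               .tMix(parts$S, params[[paste0(pre, ".mixS")]]))
    if (m > 0) {
      gate <- adRowScale(adSiLU(.adLinear(ctx$rbf, params, paste0(pre, ".gate"))),
                         ctx$envMask)
      gI <- adCols(gate, 1:C)
      gA <- adCols(gate, (C + 1L):(2L * C))
      gS <- adCols(gate, (2L * C + 1L):(3L * C))
      Yparts <- .tDecompose(Y)
      U <- vector("list", 9L)
      for (k in 1:9) {
        msg <- adAdd(adAdd(adMul(adGather(Yparts$I[[k]], ctx$jIdx), gI),
                           adMul(adGather(Yparts$A[[k]], ctx$jIdx), gA)),
                     adMul(adGather(Yparts$S[[k]], ctx$jIdx), gS))
        U[[k]] <- adScatter(msg, ctx$iIdx, ntot)
      }
      P <- .tSymProd(Y, U)
      X <- .tAdd(.tAdd(X, U), P)
    }
  }

  parts <- .tDecompose(X)
  nI <- .tFrobSq(parts$I); nA <- .tFrobSq(parts$A); nS <- .tFrobSq(parts$S)
  feats <- adSiLU(.adLinear(adCBind(emb, nI, nA, nS), params, "out"))
  list(scalar = feats)
}

# ---- equivariant transformer -----------------------------------------

.etInit <- function(config) {
  C <- config$embeddingDimension
  K <- config$radial$numRbf
  p <- list(zEmb = matrix(runif((config$maxZ + 1L) * C, -1, 1) / sqrt(C),
                          config$maxZ + 1L, C))
  for (l in seq_len(config$numLayers)) {
    pre <- sprintf("layer%d", l)
    p <- .flattenLin(p, paste0(pre, ".q"), .initLin(C, C))
    p <- .flattenLin(p, paste0(pre, ".k"), .initLin(C, C))
    p <- .flattenLin(p, paste0(pre, ".dk"), .initLin(K, C))
    p <- .flattenLin(p, paste0(pre, ".v"), .initLin(C, 3L * C))
    p <- .flattenLin(p, paste0(pre, ".dv"), .initLin(K, 3L * C))
    p[[paste0(pre, ".U1")]] <- .initLin(C, C, bias = FALSE)$W
    p[[paste0(pre, ".U2")]] <- .initLin(C, C, bias = FALSE)$W
    p[[paste0(pre, ".U3")]] <- .initLin(C, C, bias = FALSE)$W
    p <- .flattenLin(p, paste0(pre, ".upd"), .initLin(2L * C, 2L * C))
  }
  p
}

.etForward <- function(config, params, ctx) {
  C <- config$embeddingDimension
  ntot <- ctx$ntot
  m <- length(ctx$iIdx)
  x <- adGather(params$zEmb, ctx$zIdx)
  zeroN <- adConst(matrix(0, ntot, C))
  vecs <- rep(list(zeroN), 3L)

  for (l in seq_len(config$numLayers)) {
    pre <- sprintf("layer%d", l)
    if (m > 0) {
      # distance-gated dot-product attention; the attention weight always
      # carries the envelope so the scalar pathway is continuous at r_c
      q <- .adLinear(x, params, paste0(pre, ".q"))
      k <- .adLinear(x, params, paste0(pre, ".k"))
      dk <- adRowScale(adSiLU(.adLinear(ctx$rbf, params, paste0(pre, ".dk"))), ctx$mask)
      qi <- adGather(q, ctx$iIdx)
      kj <- adGather(k, ctx$jIdx)
      attn <- adMul(adSiLU(adRowSums(adMul(adMul(qi, kj), dk))), ctx$envMask)

      # value pathway: split(V_j * D^V_ij) -> (s1, s2, s3); with
      # vectorCutoff the product additionally carries the envelope, which
      # is the continuity fix -- without it the vector-feature updates jump
      # when an edge crosses the cutoff (legacy behaviour)
      v <- .adLinear(x, params, paste0(pre, ".v"))
      vj <- adGather(v, ctx$jIdx)
      dv <- adRowScale(adSiLU(.adLinear(ctx$rbf, params, paste0(pre, ".dv"))), ctx$mask)
      w <- adMul(vj, dv)
      if (config$vectorCutoff) w <- adRowScale(w, ctx$env)
      s1 <- adCols(w, 1:C)
      s2 <- adCols(w, (C + 1L):(2L * C))
      s3 <- adCols(w, (2L * C + 1L):(3L * C))

      dx <- adScatter(adRowScale(s1, attn), ctx$iIdx, ntot)
      dvecs <- vector("list", 3L)
      for (kk in 1:3) {
        vmsg <- adAdd(adMul(s2, adGather(vecs[[kk]], ctx$jIdx)),
                      adRowScale(s3, ctx$u[[kk]]))
        dvecs[[kk]] <- adScatter(vmsg, ctx$iIdx, ntot)
      }
    } else {
      dx <- zeroN
      dvecs <- rep(list(zeroN), 3L)
    }
    vecNew <- mapply(adAdd, vecs, dvecs, SIMPLIFY = FALSE)
    u1 <- lapply(vecNew, function(vk) adMatMul(vk, params[[paste0(pre, ".U1")]]))
    u2 <- lapply(vecNew, function(vk) adMatMul(vk, params[[paste0(pre, ".U2")]]))
    dot <- adAdd(adAdd(adMul(u1[[1]], u2[[1]]), adMul(u1[[2]], u2[[2]])),
                 adMul(u1[[3]], u2[[3]]))
    h <- adSiLU(.adLinear(adCBind(dx, dot), params, paste0(pre, ".upd")))
    o1 <- adCols(h, 1:C)
    o2 <- adCols(h, (C + 1L):(2L * C))
    x <- adAdd(x, o1)
    vecs <- lapply(vecNew, function(vk) {
      adAdd(vk, adMul(o2, adMatMul(vk, params[[paste0(pre, ".U3")]])))
    })
  }
  list(scalar = x, vector = vecs)
}

# ---- graph network ----------------------------------------------------

.graphnetInit <- function(config) {
  C <- config$embeddingDimension
  K <- config$radial$numRbf
  p <- list(zEmb = matrix(runif((config$maxZ + 1L) * C, -1, 1) / sqrt(C),
                          config$maxZ + 1L, C))
  for (l in seq_len(config$numLayers)) {
    pre <- sprintf("layer%d", l)
    p <- .flattenLin(p, paste0(pre, ".filter"), .initLin(K, C))
    p <- .flattenLin(p, paste0(pre, ".pre"), .initLin(C, C))
    p <- .flattenLin(p, paste0(pre, ".post1"), .initLin(C, C))
    p <- .flattenLin(p, paste0(pre, ".post2"), .initLin(C, C))
  }
  p
}

.graphnetForward <- function(config, params, ctx) {
  ntot <- ctx$ntot
  m <- length(ctx$iIdx)
  x <- adGather(params$zEmb, ctx$zIdx)
  for (l in seq_len(config$numLayers)) {
    pre <- sprintf("layer%d", l)
    if (m > 0) {
      filt <- adRowScale(adSiLU(.adLinear(ctx$rbf, params, paste0(pre, ".filter"))),
                         ctx$envMask)
      src <- adGather(.adLinear(x, params, paste0(pre, ".pre")), ctx$jIdx)
      agg <- adScatter(adMul(filt, src), ctx$iIdx, ntot)
      upd <- .adLinear(adSiLU(.adLinear(agg, params, paste0(pre, ".post1"))),
                       params, paste0(pre, ".post2"))
      x <- adAdd(x, upd)
    }
  }
  list(scalar = x)
}

#' Initialize representation parameters
#'
#' Weights are drawn uniform fan-in scaled from R's current RNG stream; set
#' a seed beforehand for reproducible models.
#'
#' @param config a [representationConfig].
#' @return named list of parameter matrices.
#' @export
representationInit <- function(config) {
  switch(config$model,
         tensornet = .tensornetInit(config),
         equivariant_transformer = .etInit(config),
         graph_network = .graphnetInit(config))
}

.repForward <- function(config, params, ctx) {
  switch(config$model,
         tensornet = .tensornetForward(config, params, ctx),
         equivariant_transformer = .etForward(config, params, ctx),
         graph_network = .graphnetForward(config, params, ctx))
}
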