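# Reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity in the package (features, energies, prior
# terms, losses) is a node in a dynamically built computation graph. The
# backward rule of each primitive is itself expressed with these primitives,
# so gradients are again differentiable nodes: reverse-over-reverse yields
# the mixed second derivatives needed when training on forces.
#
# Values are always 2-D double matrices (scalars are 1x1). Shape rules are
# deliberately strict -- elementwise ops need equal shapes or a 1x1 operand;
# row/column broadcasting goes through explicit primitives so every backward
# rule is unambiguous.

.adState <- new.env(parent = emptyenv())
.adState$count <- 0L

.asMat <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  matrix(as.double(x), nrow = length(x), ncol = 1L)
}

#' Create an autodiff graph node
#'
#' Low-level constructor used by all primitives. `vjps` holds one
#' vector-Jacobian-product function per parent; each receives the upstream
#' gradient node and returns the gradient contribution for that parent,
#' built out of autodiff primitives so that higher-order differentiation
#' works.
#'
#' @param value numeric matrix held by the node.
#' @param parents list of parent `adNode` objects.
#' @param vjps list of backward functions, aligned with `parents`.
#' @param req does this node itself require gradients (leaf flag)?
#' @return an object of class `adNode`.
#' @keywords internal
adNode <- function(value, parents = list(), vjps = list(), req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$p <- parents
  e$vj <- vjps
  rq <- req
  if (!rq && length(parents)) {
    for (pp in parents) if (pp$rq) { rq <- TRUE; break }
  }
  e$rq <- rq
  .adState$count <- .adState$count + 1L
  e$id <- .adState$count
  class(e) <- "adNode"
  e
}

#' @rdname adNode
#' @param x numeric matrix, vector or scalar.
#' @export
adConst <- function(x) adNode(.asMat(x))

#' @rdname adNode
#' @export
adLeaf <- function(x) adNode(.asMat(x), req = TRUE)

#' Extract the numeric value of a node
#' @param x an `adNode` (plain numerics pass through).
#' @return a double matrix.
#' @export
adValue <- function(x) if (inherits(x, "adNode")) x$v else .asMat(x)

#' Detach a node from the graph
#' @param x an `adNode`.
#' @return a constant node with the same value.
#' @export
adDetach <- function(x) adConst(adValue(x))

.wrap <- function(x) if (inherits(x, "adNode")) x else adConst(x)
.isScalarNode <- function(x) nrow(x$v) == 1L && ncol(x$v) == 1L

.shapeCheck <- function(a, b, op) {
  if (.isScalarNode(a) || .isScalarNode(b)) return(invisible(TRUE))
  if (nrow(a$v) != nrow(b$v) || ncol(a$v) != ncol(b$v)) {
    stop(sprintf("ad %s: shape mismatch (%dx%d vs %dx%d)", op,
                 nrow(a$v), ncol(a$v), nrow(b$v), ncol(b$v)))
  }
  invisible(TRUE)
}

# reduce g to a 1x1 node when the corresponding operand was scalar
.reduceTo <- function(g, operand) {
  if (.isScalarNode(operand) && !(nrow(g$v) == 1L && ncol(g$v) == 1L)) adSumAll(g) else g
}

#' Elementwise arithmetic primitives
#'
#' Equal-shape or scalar-broadcast elementwise operations. The `Ops` group
#' method on `adNode` dispatches to these, so node arithmetic reads like
#' plain R.
#'
#' @param a,b nodes or numerics.
#' @return an `adNode`.
#' @name ad-arith
NULL

#' @rdname ad-arith
#' @export
adAdd <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b); .shapeCheck(a, b, "add")
  val <- if (.isScalarNode(a)) a$v[1L] + b$v else if (.isScalarNode(b)) a$v + b$v[1L] else a$v + b$v
  adNode(val, list(a, b), list(function(g) .reduceTo(g, a), function(g) .reduceTo(g, b)))
}

#' @rdname ad-arith
#' @export
adSub <- function(a, b) adAdd(a, adNeg(b))

#' @rdname ad-arith
#' @export
adNeg <- function(a) {
  a <- .wrap(a)
  adNode(-a$v, list(a), list(function(g) adNeg(g)))
}

#' @rdname ad-arith
#' @export
adMul <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b); .shapeCheck(a, b, "mul")
  val <- if (.isScalarNode(a)) a$v[1L] * b$v else if (.isScalarNode(b)) a$v * b$v[1L] else a$v * b$v
  adNode(val, list(a, b),
         list(function(g) .reduceTo(adMul(g, b), a),
              function(g) .reduceTo(adMul(g, a), b)))
}

#' @rdname ad-arith
#' @export
adDiv <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b); .shapeCheck(a, b, "div")
  val <- if (.isScalarNode(a)) a$v[1L] / b$v else if (.isScalarNode(b)) a$v / b$v[1L] else a$v / b$v
  out <- adNode(val, list(a, b), list(NULL, NULL))
  out$vj <- list(function(g) .reduceTo(adDiv(g, b), a),
                 function(g) .reduceTo(adNeg(adDiv(adMul(g, out), b)), b))
  out
}

#' @rdname ad-arith
#' @param p numeric exponent (not differentiated through).
#' @export
adPow <- function(a, p) {
  a <- .wrap(a)
  adNode(a$v^p, list(a), list(function(g) adMul(g, adMul(adPow(a, p - 1), p))))
}

#' @export
Ops.adNode <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(adNeg(e1))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not supported for adNode")
  }
  switch(.Generic,
         "+" = adAdd(e1, e2),
         "-" = adSub(e1, e2),
         "*" = adMul(e1, e2),
         "/" = adDiv(e1, e2),
         "^" = {
           if (inherits(e2, "adNode")) stop("adNode exponents are not supported; use adExp/adLog")
           adPow(e1, e2)
         },
         stop(.Generic, " not supported for adNode"))
}

#' Structural primitives (matrix product, transpose, reductions, broadcasts)
#' @param a,b nodes or numerics.
#' @return an `adNode`.
#' @name ad-structure
NULL

#' @rdname ad-structure
#' @export
adMatMul <- function(a, b) {
  a <- .wrap(a); b <- .wrap(b)
  adNode(a$v %*% b$v, list(a, b),
         list(function(g) adMatMul(g, adT(b)),
              function(g) adMatMul(adT(a), g)))
}

#' @rdname ad-structure
#' @export
adT <- function(a) {
  a <- .wrap(a)
  adNode(t(a$v), list(a), list(function(g) adT(g)))
}

#' @rdname ad-structure
#' @export
adSumAll <- function(a) {
  a <- .wrap(a)
  nr <- nrow(a$v); nc <- ncol(a$v)
  adNode(matrix(sum(a$v), 1L, 1L), list(a),
         list(function(g) adBCastFull(g, nr, nc)))
}

#' @rdname ad-structure
#' @param nr,nc target dimensions.
#' @export
adBCastFull <- function(a, nr, nc) {
  a <- .wrap(a)
  stopifnot(.isScalarNode(a))
  adNode(matrix(a$v[1L], nr, nc), list(a), list(function(g) adSumAll(g)))
}

#' @rdname ad-structure
#' @export
adRowSums <- function(a) {
  a <- .wrap(a)
  nc <- ncol(a$v)
  adNode(matrix(rowSums(a$v), ncol = 1L), list(a),
         list(function(g) adBCastCols(g, nc)))
}

#' @rdname ad-structure
#' @param k number of columns to broadcast a column vector across.
#' @export
adBCastCols <- function(a, k) {
  a <- .wrap(a)
  stopifnot(ncol(a$v) == 1L)
  adNode(matrix(a$v, nrow(a$v), k), list(a), list(function(g) adRowSums(g)))
}

#' @rdname ad-structure
#' @export
adColSums <- function(a) {
  a <- .wrap(a)
  nr <- nrow(a$v)
  adNode(matrix(colSums(a$v), nrow = 1L), list(a),
         list(function(g) adBCastRows(g, nr)))
}

#' @rdname ad-structure
#' @param n number of rows to broadcast a row vector across.
#' @export
adBCastRows <- function(a, n) {
  a <- .wrap(a)
  stopifnot(nrow(a$v) == 1L)
  val <- if (n == 0L) matrix(0, 0L, ncol(a$v)) else matrix(a$v, n, ncol(a$v), byrow = TRUE)
  adNode(val, list(a), list(function(g) adColSums(g)))
}

#' Scale each row of a matrix node by a column-vector node
#' @param a matrix node (n x k).
#' @param v column-vector node (n x 1).
#' @return an `adNode` with value `a * v` row-wise.
#' @export
adRowScale <- function(a, v) {
  a <- .wrap(a); v <- .wrap(v)
  stopifnot(ncol(v$v) == 1L, nrow(v$v) == nrow(a$v))
  adNode(a$v * as.vector(v$v), list(a, v),
         list(function(g) adRowScale(g, v),
              function(g) adRowSums(adMul(g, a))))
}

# deterministic scatter-add: rows of x summed into `n` rows by index; within
# each target row contributions are added in their order of appearance in x
.scatterRows <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx)) {
    rs <- rowsum(x, group = as.integer(idx), reorder = TRUE)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

#' Row gather / scatter-add primitives
#'
#' `adGather` selects rows by index; `adScatter` sum-accumulates rows into a
#' target of `n` rows (the adjoint of gather). Summation order within a
#' target row follows the order of appearance in the source, making
#' reductions reproducible bit-for-bit.
#'
#' @param a node.
#' @param idx integer row indices (1-based).
#' @param n number of output rows for scatter.
#' @return an `adNode`.
#' @name ad-gather
NULL

#' @rdname ad-gather
#' @export
adGather <- function(a, idx) {
  a <- .wrap(a)
  idx <- as.integer(idx)
  nsrc <- nrow(a$v)
  adNode(a$v[idx, , drop = FALSE], list(a),
         list(function(g) adScatter(g, idx, nsrc)))
}

#' @rdname ad-gather
#' @export
adScatter <- function(a, idx, n) {
  a <- .wrap(a)
  idx <- as.integer(idx)
  stopifnot(length(idx) == nrow(a$v))
  adNode(.scatterRows(a$v, idx, n), list(a),
         list(function(g) adGather(g, idx)))
}

#' Row and column binding of nodes
#' @param ... nodes to bind.
#' @return an `adNode`.
#' @name ad-bind
NULL

#' @rdname ad-bind
#' @export
adRBind <- function(...) {
  parts <- lapply(list(...), .wrap)
  rows <- vapply(parts, function(x) nrow(x$v), integer(1))
  ends <- cumsum(rows); starts <- c(1L, head(ends, -1L) + 1L)
  vjps <- lapply(seq_along(parts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    function(g) adGather(g, i0:i1)
  })
  adNode(do.call(rbind, lapply(parts, function(x) x$v)), parts, vjps)
}

#' @rdname ad-bind
#' @export
adCBind <- function(...) {
  parts <- lapply(list(...), .wrap)
  cols <- vapply(parts, function(x) ncol(x$v), integer(1))
  ends <- cumsum(cols); starts <- c(1L, head(ends, -1L) + 1L)
  vjps <- lapply(seq_along(parts), function(k) {
    j0 <- starts[k]; j1 <- ends[k]
    function(g) adCols(g, j0:j1)
  })
  adNode(do.call(cbind, lapply(parts, function(x) x$v)), parts, vjps)
}

#' Column slice of a node
#' @param a node.
#' @param jidx column indices (must be distinct).
#' @return an `adNode`.
#' @export
adCols <- function(a, jidx) {
  a <- .wrap(a)
  jidx <- as.integer(jidx)
  stopifnot(!anyDuplicated(jidx))
  nc <- ncol(a$v)
  adNode(a$v[, jidx, drop = FALSE], list(a),
         list(function(g) adColScatter(g, jidx, nc)))
}

#' @rdname adCols
#' @param k total number of columns of the scatter target.
#' @export
adColScatter <- function(a, jidx, k) {
  a <- .wrap(a)
  jidx <- as.integer(jidx)
  stopifnot(!anyDuplicated(jidx), length(jidx) == ncol(a$v))
  val <- matrix(0, nrow(a$v), k)
  val[, jidx] <- a$v
  adNode(val, list(a), list(function(g) adCols(g, jidx)))
}

#' Elementwise transcendental primitives
#' @param a node or numeric.
#' @return an `adNode`.
#' @name ad-elementwise
NULL

#' @rdname ad-elementwise
#' @export
adExp <- function(a) {
  a <- .wrap(a)
  out <- adNode(exp(a$v), list(a), list(NULL))
  out$vj <- list(function(g) adMul(g, out))
  out
}

#' @rdname ad-elementwise
#' @export
adLog <- function(a) {
  a <- .wrap(a)
  adNode(log(a$v), list(a), list(function(g) adDiv(g, a)))
}

#' @rdname ad-elementwise
#' @export
adSqrt <- function(a) {
  a <- .wrap(a)
  out <- adNode(sqrt(a$v), list(a), list(NULL))
  out$vj <- list(function(g) adDiv(adMul(g, 0.5), out))
  out
}

#' @rdname ad-elementwise
#' @export
adCos <- function(a) {
  a <- .wrap(a)
  adNode(cos(a$v), list(a), list(function(g) adNeg(adMul(g, adSin(a)))))
}

#' @rdname ad-elementwise
#' @export
adSin <- function(a) {
  a <- .wrap(a)
  adNode(sin(a$v), list(a), list(function(g) adMul(g, adCos(a))))
}

#' @rdname ad-elementwise
#' @export
adSigmoid <- function(a) {
  a <- .wrap(a)
  out <- adNode(1 / (1 + exp(-a$v)), list(a), list(NULL))
  out$vj <- list(function(g) adMul(g, adMul(out, adSub(1, out))))
  out
}

#' @rdname ad-elementwise
#' @export
adTanh <- function(a) {
  a <- .wrap(a)
  out <- adNode(tanh(a$v), list(a), list(NULL))
  out$vj <- list(function(g) adMul(g, adSub(1, adMul(out, out))))
  out
}

#' @rdname ad-elementwise
#' @export
adSiLU <- function(a) {
  a <- .wrap(a)
  adMul(a, adSigmoid(a))
}

# iterative topological order of the requires-grad subgraph reachable from out
.adTopo <- function(out) {
  order <- vector("list", 64L); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = out, stage = 1L)); nstack <- 1L
  while (nstack > 0L) {
    fr <- stack[[nstack]]; stack[[nstack]] <- NULL; nstack <- nstack - 1L
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      nstack <- nstack + 1L; stack[[nstack]] <- list(node = nd, stage = 2L)
      if (length(nd$p)) {
        for (pp in nd$p) {
          if (pp$rq && is.null(seen[[as.character(pp$id)]])) {
            nstack <- nstack + 1L; stack[[nstack]] <- list(node = pp, stage = 1L)
          }
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- nd
    }
  }
  order[seq_len(norder)]
}

#' Reverse-mode gradient
#'
#' Computes gradients of a scalar (1x1) node with respect to a list of leaf
#' nodes. The returned gradients are themselves graph nodes, so they can be
#' combined into new objectives and differentiated again (needed for
#' force-matching losses, where the force is already a gradient).
#'
#' @param out scalar `adNode` to differentiate.
#' @param wrt a single `adNode` or list of nodes to differentiate with
#'   respect to.
#' @param seed optional upstream gradient node matching `out`'s shape
#'   (defaults to 1).
#' @return a list of `adNode` gradients aligned with `wrt` (a single node if
#'   `wrt` was one node); absent paths yield zero constants.
#' @export
adGrad <- function(out, wrt, seed = NULL) {
  single <- inherits(wrt, "adNode")
  wrtList <- if (single) list(wrt) else wrt
  if (is.null(seed)) {
    if (nrow(out$v) != 1L || ncol(out$v) != 1L) {
      stop("adGrad without a seed requires a scalar output node")
    }
    seed <- adConst(matrix(1, 1L, 1L))
  } else {
    seed <- .wrap(seed)
  }
  grads <- new.env(parent = emptyenv())
  if (out$rq) {
    topo <- .adTopo(out)
    assign(as.character(out$id), seed, envir = grads)
    for (i in rev(seq_along(topo))) {
      nd <- topo[[i]]
      key <- as.character(nd$id)
      g <- grads[[key]]
      if (is.null(g)) next
      if (length(nd$p)) {
        for (k in seq_along(nd$p)) {
          pp <- nd$p[[k]]
          if (!pp$rq) next
          contrib <- nd$vj[[k]](g)
          pkey <- as.character(pp$id)
          prev <- grads[[pkey]]
          grads[[pkey]] <- if (is.null(prev)) contrib else adAdd(prev, contrib)
        }
      }
    }
  }
  res <- lapply(wrtList, function(w) {
    g <- grads[[as.character(w$id)]]
    if (is.null(g)) adConst(matrix(0, nrow(w$v), ncol(w$v))) else g
  })
  if (single) res[[1L]] else res
}

#' @export
print.adNode <- function(x, ...) {
  cat(sprintf("<adNode %dx%d%s>\n", nrow(x$v), ncol(x$v),
              if (x$rq) ", requires grad" else ""))
  invisible(x)
}
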