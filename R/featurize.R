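# Distance featurization shared by all representation models: the cosine
# cutoff envelope and an exponential-Gaussian radial basis expansion.

#' Cosine cutoff envelope
#'
#' `phi(d) = 0.5 * (cos(pi d / r_c) + 1)` for `d <= r_c` and 0 beyond.
#' Continuous everywhere, once-differentiable at the cutoff (both value and
#' slope vanish there), so edge contributions weighted by it switch off
#' smoothly as atoms cross the cutoff sphere.
#'
#' @param d distances (Angstrom), any non-negative numeric.
#' @param cutoff cutoff radius r_c (Angstrom).
#' @return weights in `[0, 1]`, same shape as `d`.
#' @examples
#' cosineCutoff(c(0, 2.25, 4.5), 4.5)  # 1, 0.5, 0
#' @export
cosineCutoff <- function(d, cutoff) {
  w <- 0.5 * (cos(pi * pmin(d, cutoff) / cutoff) + 1)
  w[d >= cutoff] <- 0
  w
}

# graph-node version; the hard indicator is baked in as a constant mask so
# the envelope (and everything it multiplies) is exactly zero beyond r_c
.adCosineCutoff <- function(dNode, cutoff) {
  ind <- adConst((adValue(dNode) < cutoff) * 1)
  w <- adMul(adAdd(adCos(adMul(dNode, pi / cutoff)), 1), 0.5)
  adMul(w, ind)
}

#' Radial basis configuration
#'
#' @param cutoff cutoff radius in Angstrom (> 0).
#' @param numRbf number of radial basis functions (>= 1).
#' @param trainableRbf should basis centers/widths be trained (default off)?
#' @return a list with class `RadialConfig`.
#' @export
radialConfig <- function(cutoff = 4.5, numRbf = 32L, trainableRbf = FALSE) {
  stopifnot(cutoff > 0, numRbf >= 1)
  structure(list(cutoff = as.double(cutoff), numRbf = as.integer(numRbf),
                 trainableRbf = isTRUE(trainableRbf)),
            class = "RadialConfig")
}

# initial centers/width of the exponential-Gaussian basis
# exp(-beta (exp(-d) - mu_k)^2): mu_k evenly spaced from 1 down to
# exp(-r_c) (so the first basis peaks at d = 0), shared beta chosen so
# adjacent bases overlap at ~half maximum
.rbfInit <- function(config) {
  means <- seq(1, exp(-config$cutoff), length.out = config$numRbf)
  beta <- (2 / config$numRbf * (1 - exp(-config$cutoff)))^-2
  list(means = means, betas = rep(beta, config$numRbf))
}

#' Expand distances in a smooth radial basis
#'
#' Exponential-Gaussian bases `exp(-beta_k (exp(-d) - mu_k)^2)`, each
#' multiplied by the cosine cutoff envelope so every feature vanishes (with
#' zero slope) at and beyond the cutoff. The first basis is the one peaked
#' at `d = 0`.
#'
#' @param d numeric vector of M distances (Angstrom).
#' @param config a [radialConfig].
#' @param means,betas optional basis parameters overriding the defaults
#'   (used when `trainableRbf` made them learnable).
#' @return M x numRbf feature matrix.
#' @export
expandDistances <- function(d, config, means = NULL, betas = NULL) {
  init <- .rbfInit(config)
  if (is.null(means)) means <- init$means
  if (is.null(betas)) betas <- init$betas
  d <- as.double(d)
  env <- cosineCutoff(d, config$cutoff)
  ed <- exp(-d)
  feat <- exp(-outer(ed, means, "-")^2 * rep(betas, each = length(d)))
  feat * env
}

# graph-node version working on an M x 1 distance node; means/betas may be
# nodes (trainable) or numerics
.adExpandDistances <- function(dNode, config, means = NULL, betas = NULL) {
  init <- .rbfInit(config)
  if (is.null(means)) means <- adConst(matrix(init$means, 1L))
  if (is.null(betas)) betas <- adConst(matrix(init$betas, 1L))
  m <- nrow(adValue(dNode))
  k <- config$numRbf
  env <- .adCosineCutoff(dNode, config$cutoff)
  ed <- adBCastCols(adExp(adNeg(dNode)), k)
  mu <- adBCastRows(means, m)
  bt <- adBCastRows(betas, m)
  diff <- adSub(ed, mu)
  feat <- adExp(adNeg(adMul(bt, adMul(diff, diff))))
  adRowScale(feat, env)
}
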