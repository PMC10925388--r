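# Training stack: weighted energy/force MSE loss, L1/MSE validation
# metrics, EMA smoothing of logged losses, an Adam optimizer with
# plateau-based learning-rate decay, the mini-batch training loop, and
# checkpointing. The loop is fully deterministic under a fixed seed
# (single-threaded dense arithmetic, seeded shuffles, RNG state carried
# through checkpoints for exact resume).

#' Loss weights for energy/force training
#'
#' @param lambdaEnergy weight of the energy MSE term (>= 0).
#' @param lambdaForce weight of the force MSE term (>= 0); not both zero.
#' @return a list with class `LossWeights`.
#' @export
lossWeights <- function(lambdaEnergy = 1.0, lambdaForce = 0.0) {
  stopifnot(lambdaEnergy >= 0, lambdaForce >= 0,
            lambdaEnergy > 0 || lambdaForce > 0)
  structure(list(lambdaEnergy = as.double(lambdaEnergy),
                 lambdaForce = as.double(lambdaForce)), class = "LossWeights")
}

#' Weighted energy/force MSE loss
#'
#' `lambda_E MSE(y, y*) + lambda_F MSE(neg_dy, neg_dy*)`, each MSE averaged
#' over all elements of its tensor (per-sample for energies, per-component
#' for forces).
#'
#' @param pred a [Prediction-class] (or list with `y`/`negDy`).
#' @param target list with `y` and optionally `negDy`.
#' @param weights a [lossWeights].
#' @return scalar loss.
#' @export
lossFunction <- function(pred, target, weights = lossWeights()) {
  y <- if (is(pred, "Prediction")) pred@y else pred$y
  negDy <- if (is(pred, "Prediction")) pred@negDy else pred$negDy
  total <- 0
  if (weights$lambdaEnergy > 0) {
    total <- total + weights$lambdaEnergy * mean((y - target$y)^2)
  }
  if (weights$lambdaForce > 0) {
    if (is.null(negDy) || is.null(target$negDy)) {
      stop("force loss requested (lambdaForce > 0) but forces are missing from prediction or target")
    }
    total <- total + weights$lambdaForce * mean((negDy - target$negDy)^2)
  }
  total
}

#' Validation metrics: L1 and MSE for energies and forces
#'
#' @inheritParams lossFunction
#' @return named list `l1Energy`, `mseEnergy`, `l1Force`, `mseForce`
#'   (force entries NA when forces are absent). Test reporting
#'   conventionally uses the L1 pair only.
#' @export
validationMetrics <- function(pred, target) {
  y <- if (is(pred, "Prediction")) pred@y else pred$y
  negDy <- if (is(pred, "Prediction")) pred@negDy else pred$negDy
  out <- list(l1Energy = mean(abs(y - target$y)),
              mseEnergy = mean((y - target$y)^2),
              l1Force = NA_real_, mseForce = NA_real_)
  if (!is.null(negDy) && !is.null(target$negDy)) {
    out$l1Force <- mean(abs(negDy - target$negDy))
    out$mseForce <- mean((negDy - target$negDy)^2)
  }
  out
}

#' Exponential moving average of logged metrics
#'
#' `new = alpha * value + (1 - alpha) * old`; the first observation
#' initializes the state, so a constant stream is a fixed point.
#'
#' @param alpha decay in (0, 1]; `alpha = 1` tracks raw values.
#' @param state an EMA state created by `emaState`.
#' @param value new observation.
#' @return `emaState`: a fresh state; `emaUpdate`: the updated state (the
#'   smoothed value sits in `$value`).
#' @export
emaState <- function(alpha = 0.3) {
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(alpha = alpha, value = NULL), class = "EMAState")
}

#' @rdname emaState
#' @export
emaUpdate <- function(state, value) {
  state$value <- if (is.null(state$value)) value
                 else state$alpha * value + (1 - state$alpha) * state$value
  state
}

# ---- Adam -------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (opt$m[[nm]] / bc1) /
      (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

# loss as a graph node for one collated batch; exercises second-order
# differentiation when lambdaForce > 0 (the force is itself a gradient)
.batchLossNode <- function(model, batchData, paramNodes, weights) {
  fw <- .modelForward(model, batchData$system, paramNodes = paramNodes,
                      derivative = weights$lambdaForce > 0)
  lossNode <- NULL
  if (weights$lambdaEnergy > 0) {
    dy <- adSub(fw$y, adConst(matrix(batchData$y, ncol = 1L)))
    term <- adMul(adSumAll(adMul(dy, dy)), weights$lambdaEnergy / length(batchData$y))
    lossNode <- term
  }
  if (weights$lambdaForce > 0) {
    if (is.null(batchData$negDy)) {
      stop("force loss requested (lambdaForce > 0) but the dataset carries no forces")
    }
    df <- adSub(fw$negDy, adConst(batchData$negDy))
    term <- adMul(adSumAll(adMul(df, df)),
                  weights$lambdaForce / length(batchData$negDy))
    lossNode <- if (is.null(lossNode)) term else adAdd(lossNode, term)
  }
  lossNode
}

.evalSplit <- function(model, dataset, idx, batchSize, weights) {
  if (!length(idx)) return(list(loss = NA_real_, metrics = NULL))
  needForces <- weights$lambdaForce > 0 && hasForces(dataset)
  chunks <- split(idx, ceiling(seq_along(idx) / batchSize))
  ys <- c(); yt <- c(); fs <- NULL; ft <- NULL
  for (ch in chunks) {
    bd <- collateRecords(dataset, ch)
    fw <- .modelForward(model, bd$system, derivative = needForces)
    ys <- c(ys, as.vector(adValue(fw$y)))
    yt <- c(yt, bd$y)
    if (needForces) {
      fs <- rbind(fs, adValue(fw$negDy))
      ft <- rbind(ft, bd$negDy)
    }
  }
  pred <- list(y = ys, negDy = fs)
  targ <- list(y = yt, negDy = ft)
  list(loss = lossFunction(pred, targ, weights),
       metrics = validationMetrics(pred, targ))
}

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param batchSize mini-batch size (records per step).
#' @param learningRate initial Adam learning rate.
#' @param lambdaEnergy,lambdaForce loss weights.
#' @param emaAlpha EMA decay for logged losses (smoothing only; weights are
#'   never averaged).
#' @param seed seed controlling shuffles (and hence the whole run).
#' @param lrFactor,lrPatience,lrMin plateau schedule: multiply the learning
#'   rate by `lrFactor` after `lrPatience` epochs without validation
#'   improvement, never below `lrMin`.
#' @param trainableParams optional regex; only matching parameter names are
#'   updated (e.g. `"^prior1\\."` to fit a learnable prior alone).
#' @param checkpointDir optional directory for per-epoch checkpoints
#'   (`last.ckpt`, `best.ckpt`).
#' @param verbose print per-epoch progress.
#' @return a list with class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 100L, batchSize = 32L, learningRate = 5e-3,
                        lambdaEnergy = 1.0, lambdaForce = 0.0,
                        emaAlpha = 0.3, seed = 0L, lrFactor = 0.8,
                        lrPatience = 10L, lrMin = 1e-5,
                        trainableParams = NULL, checkpointDir = NULL,
                        verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 weights = lossWeights(lambdaEnergy, lambdaForce),
                 emaAlpha = emaAlpha, seed = as.integer(seed),
                 lrFactor = lrFactor, lrPatience = as.integer(lrPatience),
                 lrMin = lrMin, trainableParams = trainableParams,
                 checkpointDir = checkpointDir, verbose = isTRUE(verbose)),
            class = "TrainConfig")
}

#' Mini-batch training loop
#'
#' Adam on the weighted energy/force MSE with per-epoch validation
#' (EMA-smoothed logging), best-checkpoint tracking on the validation loss,
#' plateau learning-rate decay, and exact deterministic resume from a
#' checkpoint. Heterogeneous atom counts are handled through the batch
#' index vector (no sample padding).
#'
#' @param model an [AssembledModel-class].
#' @param dataset a [ConformerDataset-class].
#' @param splits list with `train`/`val` (and optionally `test`) index
#'   vectors, as from [makeSplits].
#' @param config a [trainConfig].
#' @param resumeFrom optional checkpoint path to continue from.
#' @return list with the trained `model`, `history` (one data.frame row
#'   per epoch), `best` (epoch/loss of the best validation), and
#'   checkpoint paths when a checkpoint directory was configured.
#' @export
trainLoop <- function(model, dataset, splits, config = trainConfig(),
                      resumeFrom = NULL) {
  weights <- config$weights
  if (weights$lambdaForce > 0 && !hasForces(dataset)) {
    stop("force loss requested (lambdaForce > 0) but the dataset carries no forces")
  }
  params <- model@params
  trainNames <- names(params)
  if (!is.null(config$trainableParams)) {
    trainNames <- grep(config$trainableParams, trainNames, value = TRUE)
    if (!length(trainNames)) stop("trainableParams regex matches no parameters")
  }
  opt <- .adamInit(params[trainNames])
  history <- list()
  startEpoch <- 1L
  lr <- config$learningRate
  bestVal <- Inf; bestEpoch <- NA_integer_; sinceBest <- 0L
  emaTrain <- emaState(config$emaAlpha)
  emaVal <- emaState(config$emaAlpha)
  set.seed(config$seed)
  if (!is.null(resumeFrom)) {
    ck <- .readCheckpoint(resumeFrom)
    params <- ck$params
    opt <- ck$optState$opt
    lr <- ck$optState$lr
    bestVal <- ck$optState$bestVal; bestEpoch <- ck$optState$bestEpoch
    sinceBest <- ck$optState$sinceBest
    emaTrain <- ck$optState$emaTrain; emaVal <- ck$optState$emaVal
    history <- ck$optState$historyList
    startEpoch <- ck$epoch + 1L
    if (!is.null(ck$optState$rngState)) assign(".Random.seed", ck$optState$rngState, globalenv())
  }
  ckDir <- config$checkpointDir
  if (!is.null(ckDir)) dir.create(ckDir, showWarnings = FALSE, recursive = TRUE)

  workModel <- model
  for (epoch in seq(startEpoch, length.out = max(0L, config$epochs - startEpoch + 1L))) {
    idx <- splits$train[sample.int(length(splits$train))]
    batches <- split(idx, ceiling(seq_along(idx) / config$batchSize))
    epochLoss <- 0
    for (bi in seq_along(batches)) {
      bd <- collateRecords(dataset, batches[[bi]])
      workModel@params <- params
      paramNodes <- lapply(params, adLeaf)
      lossNode <- .batchLossNode(workModel, bd, paramNodes, weights)
      lossVal <- adValue(lossNode)[1]
      if (!is.finite(lossVal)) {
        stop(sprintf("non-finite training loss (%.4g) at epoch %d, batch %d",
                     lossVal, epoch, bi))
      }
      gradNodes <- adGrad(lossNode, paramNodes[trainNames])
      grads <- lapply(gradNodes, adValue)
      names(grads) <- trainNames
      stepped <- .adamStep(opt, params, grads, lr)
      opt <- stepped$opt
      params <- stepped$params
      epochLoss <- epochLoss + lossVal * length(batches[[bi]])
    }
    epochLoss <- epochLoss / length(idx)
    emaTrain <- emaUpdate(emaTrain, epochLoss)

    workModel@params <- params
    valRes <- .evalSplit(workModel, dataset, splits$val, config$batchSize, weights)
    valLoss <- valRes$loss
    emaVal <- emaUpdate(emaVal, valLoss)

    improved <- is.finite(valLoss) && valLoss < bestVal - 1e-12
    if (improved) {
      bestVal <- valLoss; bestEpoch <- epoch; sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= config$lrPatience) {
        lr <- max(config$lrMin, lr * config$lrFactor)
        sinceBest <- 0L
      }
    }

    history[[length(history) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, trainLoss = epochLoss,
      trainLossEma = emaTrain$value, valLoss = valLoss,
      valLossEma = emaVal$value,
      l1Energy = valRes$metrics$l1Energy, mseEnergy = valRes$metrics$mseEnergy,
      l1Force = valRes$metrics$l1Force, mseForce = valRes$metrics$mseForce)
    if (config$verbose) {
      message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.3g",
                      epoch, epochLoss, valLoss, lr))
    }

    if (!is.null(ckDir)) {
      optState <- list(opt = opt, lr = lr, bestVal = bestVal,
                       bestEpoch = bestEpoch, sinceBest = sinceBest,
                       emaTrain = emaTrain, emaVal = emaVal,
                       historyList = history,
                       rngState = get(".Random.seed", globalenv()))
      saveCheckpoint(workModel, file.path(ckDir, "last.ckpt"),
                     optState = optState, epoch = epoch)
      if (improved) {
        saveCheckpoint(workModel, file.path(ckDir, "best.ckpt"),
                       optState = optState, epoch = epoch)
      }
    }
  }
  workModel@params <- params
  list(model = workModel,
       history = do.call(rbind, history),
       best = list(epoch = bestEpoch, valLoss = bestVal),
       checkpoints = if (!is.null(ckDir)) {
         list(last = file.path(ckDir, "last.ckpt"),
              best = file.path(ckDir, "best.ckpt"))
       } else NULL)
}

# ---- checkpoints ------------------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint carries the full model configuration, weights, prior
#' objects (with their tables), optimizer state, epoch and metric history;
#' `loadModel(saveCheckpoint(m, ...))` predicts bit-identically to `m`.
#'
#' @param model an [AssembledModel-class].
#' @param path checkpoint file path.
#' @param optState optimizer/loop state (internal use by [trainLoop]).
#' @param epoch epoch counter stored alongside.
#' @return `saveCheckpoint`: invisibly `path`. `loadModel`: an
#'   [AssembledModel-class].
#' @export
saveCheckpoint <- function(model, path, optState = NULL, epoch = 0L) {
  obj <- list(format = "NNPkit-checkpoint", version = 1L,
              repConfig = model@repConfig, outConfig = model@outConfig,
              priors = model@priors, derivative = model@derivative,
              params = model@params, maxNumNeighbors = model@maxNumNeighbors,
              optState = optState, epoch = as.integer(epoch))
  saveRDS(obj, path)
  invisible(path)
}

.readCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable checkpoint '", path, "': ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "NNPkit-checkpoint")) {
    stop("file '", path, "' is not an NNPkit checkpoint")
  }
  obj
}

#' @rdname saveCheckpoint
#' @param derivative optionally override the stored derivative flag at
#'   load time (e.g. enable forces on a model trained without them).
#' @export
loadModel <- function(path, derivative = NULL) {
  ck <- .readCheckpoint(path)
  model <- new("AssembledModel", repConfig = ck$repConfig,
               outConfig = ck$outConfig, priors = ck$priors,
               derivative = if (is.null(derivative)) ck$derivative else isTRUE(derivative),
               params = ck$params, maxNumNeighbors = ck$maxNumNeighbors)
  model
}
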