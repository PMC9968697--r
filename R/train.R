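# Optimization: Adam with a Noam-style warmup/decay schedule, masked
# losses, per-epoch validation selection, and cross-validated training.

.adamInit <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

.adamStep <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1 ^ state$t
  b2t <- 1 - beta2 ^ state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g ^ 2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(flat = flat, state = state)
}

# Noam-like schedule: linear warmup from initLr to maxLr over warmupSteps,
# then exponential decay to finalLr at totalSteps.
.lrAt <- function(step, schedule) {
  if (schedule$kind == "constant") return(schedule$lr)
  w <- schedule$warmupSteps
  if (step <= w) {
    schedule$initLr + (schedule$maxLr - schedule$initLr) * step / max(w, 1)
  } else {
    total <- max(schedule$totalSteps - w, 1)
    gamma <- (schedule$finalLr / schedule$maxLr) ^ (1 / total)
    max(schedule$maxLr * gamma ^ (step - w), schedule$finalLr)
  }
}

#' Training configuration
#'
#' @param epochs Maximum training epochs.
#' @param batchSize Molecules per optimization step.
#' @param lrSchedule \code{"noam"} (linear warmup to \code{maxLr} over
#'   \code{warmupEpochs}, then exponential decay to \code{finalLr}) or
#'   \code{"constant"}.
#' @param lr Learning rate for the constant schedule.
#' @param initLr,maxLr,finalLr,warmupEpochs Noam schedule parameters.
#' @param metric Validation metric (\code{"rmse"}, \code{"mae"},
#'   \code{"auroc"}, \code{"auprc"}); defaults to rmse for regression and
#'   auroc for classification.
#' @param stopAtMetric Optional numeric; training stops early once the
#'   monitored metric reaches this value (>= for maximized metrics, <=
#'   otherwise).
#' @param seed Integer seed covering shuffling, dropout and initialization
#'   of normalization.
#' @param verbose Print per-epoch progress.
#' @return A list of class \code{trainConfig}.
#' @export
trainConfig <- function(epochs = 30L, batchSize = 16L,
                        lrSchedule = c("noam", "constant"), lr = 1e-3,
                        initLr = 1e-4, maxLr = 1e-3, finalLr = 1e-4,
                        warmupEpochs = 2, metric = NULL,
                        stopAtMetric = NULL, seed = 0L, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 lrSchedule = match.arg(lrSchedule), lr = lr,
                 initLr = initLr, maxLr = maxLr, finalLr = finalLr,
                 warmupEpochs = warmupEpochs, metric = metric,
                 stopAtMetric = stopAtMetric, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "trainConfig")
}

.maskedColStats <- function(y) {
  mu <- apply(y, 2, function(c) mean(c, na.rm = TRUE))
  sd <- apply(y, 2, function(c) stats::sd(c, na.rm = TRUE))
  mu[!is.finite(mu)] <- 0
  sd[!is.finite(sd) | sd <= 0] <- 1
  list(mean = mu, sd = sd)
}

#' Train an ABT-MPNN
#'
#' Adam optimization of the masked mean-squared error (regression, on
#' Z-scored targets) or masked binary cross-entropy with logits
#' (classification). Descriptor and target normalization statistics are
#' fitted on the training indices only. After every epoch the model is
#' scored on the validation split (or the training split when the split has
#' no validation indices) and the parameters with the best score are
#' returned.
#'
#' @param model An \code{\linkS4class{ABTModel}}.
#' @param graphs List of featurized \code{\linkS4class{MolGraph}}.
#' @param targets Numeric matrix (molecules x tasks); NA = missing target.
#' @param split List with \code{train}/\code{validation} index vectors, or
#'   NULL to train on everything.
#' @param config A \code{\link{trainConfig}}.
#' @return List with \code{model} (best checkpoint), \code{history}
#'   (data.frame epoch/loss/lr/metric), \code{bestEpoch},
#'   \code{bestMetric}, \code{metric}.
#' @export
trainModel <- function(model, graphs, targets, split = NULL,
                       config = trainConfig()) {
  targets <- as.matrix(targets)
  cf <- model@config
  stopifnot(length(graphs) == nrow(targets), ncol(targets) == cf$nTasks)
  if (is.null(split)) split <- list(train = seq_along(graphs),
                                    validation = integer(0))
  tr <- split$train
  va <- split$validation
  metric <- config$metric
  if (is.null(metric))
    metric <- if (cf$taskType == "regression") "rmse" else "auroc"
  maximize <- metricMaximized(metric)

  set.seed(config$seed)
  # normalization fitted on the training split only
  descRaw <- t(vapply(graphs[tr], function(g) {
    d <- g@descriptors
    if (length(d) == 0L) numeric(model@schema$nDescriptors) else d
  }, numeric(model@schema$nDescriptors)))
  ds <- fitDescriptorStats(descRaw)
  model@norm$descriptorMean <- ds$mean
  model@norm$descriptorSd <- ds$sd
  yFit <- targets
  if (cf$taskType == "regression") {
    ts <- .maskedColStats(targets[tr, , drop = FALSE])
    model@norm$targetMean <- ts$mean
    model@norm$targetSd <- ts$sd
    yFit <- sweep(sweep(targets, 2, ts$mean, "-"), 2, ts$sd, "/")
  }

  preps <- lapply(graphs, .prepareMolecule, model = model)
  flat <- .flattenParams(model@params)
  state <- .adamInit(flat)
  stepsPerEpoch <- max(1L, ceiling(length(tr) / config$batchSize))
  schedule <- if (config$lrSchedule == "constant")
    list(kind = "constant", lr = config$lr)
  else list(kind = "noam", initLr = config$initLr, maxLr = config$maxLr,
            finalLr = config$finalLr,
            warmupSteps = config$warmupEpochs * stepsPerEpoch,
            totalSteps = config$epochs * stepsPerEpoch)

  evalIdx <- if (length(va) > 0) va else tr
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        lr = numeric(0), metric = numeric(0))
  best <- NULL
  bestScore <- if (maximize) -Inf else Inf
  bestEpoch <- 0L
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- sample(tr)
    epochLoss <- 0
    nbatch <- 0L
    for (b0 in seq(1, length(perm), by = config$batchSize)) {
      batch <- perm[b0:min(b0 + config$batchSize - 1L, length(perm))]
      step <- step + 1L
      lr <- .lrAt(step, schedule)
      tape <- ag_tape()
      model@params <- .unflattenParams(flat, model@params)
      pnodes <- lapply_params_var(model@params, tape)
      loss <- NULL
      for (i in batch) {
        out <- ag_forward_molecule(preps[[i]], pnodes, cf, tape,
                                   training = TRUE)
        yi <- matrix(yFit[i, ], 1)
        maski <- matrix(as.numeric(!is.na(yi)), 1)
        li <- if (cf$taskType == "regression")
          ag_mse_masked(out, ifelse(is.na(yi), 0, yi), maski, tape)
        else ag_bce_masked(out, yi, maski, tape)
        loss <- if (is.null(loss)) li else ag_add(loss, li, tape)
      }
      loss <- ag_scale(loss, 1 / length(batch), tape)
      if (!is.finite(loss$val[1]))
        stop("non-finite loss at epoch ", epoch, " (lr ", lr, ")",
             call. = FALSE)
      ag_backward(tape, loss)
      grads <- .collectGrads(pnodes)
      upd <- .adamStep(flat, grads, state, lr)
      flat <- upd$flat
      state <- upd$state
      epochLoss <- epochLoss + loss$val[1]
      nbatch <- nbatch + 1L
    }
    model@params <- .unflattenParams(flat, model@params)
    predEval <- modelForward(model, graphs[evalIdx])
    yEval <- targets[evalIdx, , drop = FALSE]
    if (cf$taskType == "regression") {
      predEval <- sweep(sweep(predEval, 2, model@norm$targetSd, "*"), 2,
                        model@norm$targetMean, "+")
    }
    score <- computeMetric(predEval, yEval, metric)
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epochLoss / nbatch, lr = lr, metric = score))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.5f  %s %.5f", epoch,
                      epochLoss / nbatch, metric, score))
    if (!is.na(score) &&
        ((maximize && score > bestScore) || (!maximize && score < bestScore))) {
      bestScore <- score
      bestEpoch <- epoch
      best <- flat
    }
    if (!is.null(config$stopAtMetric) && !is.na(score) &&
        ((maximize && score >= config$stopAtMetric) ||
         (!maximize && score <= config$stopAtMetric))) break
  }
  if (!is.null(best)) model@params <- .unflattenParams(best, model@params)
  list(model = model, history = history, bestEpoch = bestEpoch,
       bestMetric = bestScore, metric = metric)
}

#' Cross-validated training
#'
#' Trains one model per fold and reports the per-fold test metric with its
#' mean and standard deviation. Folds are either independent seeded
#' 80:10:10 re-partitions (default) or a rotating k-fold partition from
#' \code{\link{kfoldCV}}.
#'
#' @param makeModel Zero-argument function returning a fresh
#'   \code{\linkS4class{ABTModel}}.
#' @param graphs,targets As in \code{\link{trainModel}}.
#' @param k Number of folds (default 5).
#' @param scheme \code{"repartition"} or \code{"kfold"}.
#' @param splitKind \code{"random"} or \code{"scaffold"} (repartition
#'   scheme; scaffold re-partitions are identical across folds so only the
#'   model seed varies).
#' @param config A \code{\link{trainConfig}}; the fold index is added to
#'   its seed.
#' @param seed Base seed for fold generation.
#' @return List with \code{scores}, \code{mean}, \code{sd}, \code{fits}.
#' @export
trainCV <- function(makeModel, graphs, targets, k = 5L,
                    scheme = c("repartition", "kfold"),
                    splitKind = c("random", "scaffold"),
                    config = trainConfig(), seed = 0L) {
  scheme <- match.arg(scheme)
  splitKind <- match.arg(splitKind)
  targets <- as.matrix(targets)
  n <- length(graphs)
  splits <- if (scheme == "kfold") kfoldCV(n, k, seed)
  else lapply(seq_len(k), function(i) {
    if (splitKind == "random") randomSplit(n, seed = seed + i)
    else scaffoldSplit(graphs)
  })
  scores <- numeric(k)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- trainModel(makeModel(), graphs, targets, splits[[i]], cfg)
    pred <- predictMolecules(fit$model, graphs[splits[[i]]$test])
    scores[i] <- computeMetric(pred, targets[splits[[i]]$test, , drop = FALSE],
                               fit$metric)
    fits[[i]] <- fit
  }
  list(scores = scores, mean = mean(scores), sd = stats::sd(scores),
       fits = fits)
}
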