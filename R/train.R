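#' Training configuration
#'
#' AdamW (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) at a constant learning
#' rate of 1e-3 minimizing cross-entropy on logits; mini-batches of 16
#' for training and 8 for validation, the test set in one full batch; up
#' to 200 epochs with early stopping once validation loss has failed to
#' improve (strictly) for `patience` consecutive epochs; best-validation
#' parameters restored at stop.
#'
#' @param lr learning rate.
#' @param beta1,beta2,eps AdamW moment/stability constants.
#' @param weightDecay decoupled weight decay on weight matrices.
#' @param batchTrain,batchVal mini-batch sizes.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stopping patience (epochs), must be < maxEpochs.
#' @param seed seed for shuffling, dropout and initialization.
#' @return list of class `earstress_trainconfig`.
#' @export
trainConfig <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        weightDecay = 0.01, batchTrain = 16L, batchVal = 8L,
                        maxEpochs = 200L, patience = 30L, seed = 42L) {
  if (patience >= maxEpochs)
    stopTyped("earstress_bad_config", "patience must be < maxEpochs")
  if (batchTrain < 1L || batchVal < 1L)
    stopTyped("earstress_bad_config", "batch sizes must be >= 1")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 weightDecay = weightDecay, batchTrain = as.integer(batchTrain),
                 batchVal = as.integer(batchVal),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "earstress_trainconfig")
}

#' Subject-level cross-validation folds
#'
#' Subjects are sorted, shuffled once with `seed`, and partitioned
#' contiguously into `k` disjoint test groups that jointly cover all
#' subjects. Within each fold the remaining subjects are split 6:1 by
#' subject count into training and validation sets (the validation block
#' is taken from the end of the rotated shuffled order), so no subject
#' ever appears in two roles.
#'
#' @param subjectIds character vector of subject ids (repeats allowed).
#' @param k number of folds (default 8).
#' @param seed shuffling seed.
#' @return list of fold specs: `foldId`, `testSubjects`, `trainSubjects`,
#'   `valSubjects`.
#' @export
makeSubjectFolds <- function(subjectIds, k = 8L, seed = 42L) {
  ids <- sort(unique(subjectIds))
  if (k > length(ids))
    stopTyped("earstress_bad_config", "k = %d exceeds %d subjects",
              k, length(ids))
  shuffled <- withSeed(seed, sample(ids))
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- cumsum(c(0L, sizes))
  lapply(seq_len(k), function(f) {
    test <- shuffled[(bounds[f] + 1L):bounds[f + 1L]]
    rest <- setdiff(c(shuffled[-seq_len(bounds[f + 1L])],
                      shuffled[seq_len(bounds[f])]), test)
    nVal <- max(1L, round(length(rest) / 7))
    val <- tail(rest, nVal)
    list(foldId = f, testSubjects = test,
         trainSubjects = setdiff(rest, val), valSubjects = val)
  })
}

epochLoss <- function(model, X, y, batch) {
  N <- dim(X)[1]
  total <- 0
  for (s in seq(1L, N, by = batch)) {
    idx <- s:min(N, s + batch - 1L)
    lg <- forwardModel(model, X[idx, , , drop = FALSE], training = FALSE)$logits
    total <- total + softmaxCrossEntropy(lg, y[idx])$loss * length(idx)
  }
  total / N
}

#' Train a model on explicit train / validation epoch sets
#'
#' @param model an `earstressModel` (freshly built).
#' @param trainSet,valSet [EpochSet-class] objects.
#' @param cfg a [trainConfig()].
#' @return list: `model` (best-validation parameters restored), `history`
#'   (data.frame epoch/trainLoss/valLoss), `epochsTrained`, `bestEpoch`.
#' @export
trainModel <- function(model, trainSet, valSet, cfg = trainConfig()) {
  if (nEpochs(trainSet) == 0L || nEpochs(valSet) == 0L)
    stopTyped("earstress_bad_config", "empty training or validation set")
  Xtr <- earEpochs(trainSet); ytr <- epochLabels(trainSet)
  Xva <- earEpochs(valSet); yva <- epochLabels(valSet)
  opt <- adamwInit(model$params)
  best <- list(loss = Inf, params = model$params, bnState = model$bnState,
               epoch = 0L)
  wait <- 0L
  hist <- vector("list", cfg$maxEpochs)
  withSeed(subSeed(cfg$seed, "training-loop"), {
    for (ep in seq_len(cfg$maxEpochs)) {
      ord <- sample(dim(Xtr)[1])
      epLoss <- 0
      for (s in seq(1L, length(ord), by = cfg$batchTrain)) {
        idx <- ord[s:min(length(ord), s + cfg$batchTrain - 1L)]
        fw <- forwardModel(model, Xtr[idx, , , drop = FALSE],
                           training = TRUE, keepCache = TRUE)
        model$bnState <- fw$bnState
        ce <- softmaxCrossEntropy(fw$logits, ytr[idx])
        epLoss <- epLoss + ce$loss * length(idx)
        grads <- backwardModel(model, fw$cache, ce$dlogits)
        upd <- adamwStep(model$params, grads, opt, lr = cfg$lr,
                         beta1 = cfg$beta1, beta2 = cfg$beta2, eps = cfg$eps,
                         weightDecay = cfg$weightDecay)
        model$params <- upd$params
        opt <- upd$state
      }
      valLoss <- epochLoss(model, Xva, yva, cfg$batchVal)
      hist[[ep]] <- data.frame(epoch = ep, trainLoss = epLoss / length(ord),
                               valLoss = valLoss)
      if (valLoss < best$loss) {
        best <- list(loss = valLoss, params = model$params,
                     bnState = model$bnState, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$bnState <- best$bnState
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  list(model = model, history = history, epochsTrained = nrow(history),
       bestEpoch = best$epoch)
}

#' Train one cross-validation fold
#'
#' Subsets the epoch set by the fold's train/validation subjects (the test
#' subjects never reach training or early stopping) and trains.
#'
#' @param model an `earstressModel`.
#' @param fold a fold spec from [makeSubjectFolds()].
#' @param epochs the full [EpochSet-class].
#' @param cfg a [trainConfig()].
#' @return as [trainModel()], plus `fold`.
#' @export
trainFold <- function(model, fold, epochs, cfg = trainConfig()) {
  subs <- epochSubjects(epochs)
  missing <- setdiff(c(fold$trainSubjects, fold$valSubjects,
                       fold$testSubjects), subs)
  if (length(missing))
    stopTyped("earstress_bad_config", "fold subjects absent from epochs: %s",
              paste(missing, collapse = ", "))
  res <- trainModel(model,
                    subsetEpochs(epochs, which(subs %in% fold$trainSubjects)),
                    subsetEpochs(epochs, which(subs %in% fold$valSubjects)),
                    cfg)
  res$fold <- fold
  res
}

#' Evaluate a trained model on test epochs
#'
#' Single full-batch evaluation-mode pass; accuracy plus macro F1 (the
#' unweighted mean of per-class harmonic means of precision and recall;
#' a class with no predictions and no members contributes F1 = 0).
#'
#' @param model trained `earstressModel`.
#' @param testEpochs [EpochSet-class].
#' @return list: `accuracy`, `macroF1`, `perClass` (data.frame with
#'   precision/recall/f1 for relax and stress), `n`.
#' @export
evaluateFold <- function(model, testEpochs) {
  if (nEpochs(testEpochs) == 0L)
    stopTyped("earstress_bad_config", "empty test set")
  y <- epochLabels(testEpochs)
  pred <- predictLabels(model, testEpochs, batchSize = nEpochs(testEpochs))
  metricsFromPredictions(pred, y)
}

# confusion-matrix metrics shared by evaluateFold and its tests
metricsFromPredictions <- function(pred, y) {
  perClass <- do.call(rbind, lapply(c(relax = 0L, stress = 1L), function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(precision = precision, recall = recall, f1 = f1)
  }))
  rownames(perClass) <- c("relax", "stress")
  list(accuracy = mean(pred == y), macroF1 = mean(perClass$f1),
       perClass = perClass, n = length(y))
}

#' Subject-independent cross-validation
#'
#' Eight-fold (by default) subject-level cross-validation of one
#' architecture variant: per fold a fresh model is built (initialization
#' seeded from the root seed and fold id), trained on the fold's training
#' subjects with early stopping on its validation subjects, and evaluated
#' on the held-out test subjects.
#'
#' @param epochs full [EpochSet-class].
#' @param variant architecture variant name.
#' @param modelCfg a [modelConfig()].
#' @param trainCfg a [trainConfig()].
#' @param k number of folds.
#' @param seed root seed (folds, initialization, training).
#' @param verbose print per-fold progress.
#' @return list: `perFold` data.frame (fold, accuracy, macroF1,
#'   epochsTrained), `summary` (mean/sd per metric), `models`, `folds`.
#' @export
runCrossValidation <- function(epochs, variant = "full",
                               modelCfg = modelConfig(),
                               trainCfg = trainConfig(), k = 8L,
                               seed = trainCfg$seed, verbose = FALSE) {
  folds <- makeSubjectFolds(epochSubjects(epochs), k = k, seed = seed)
  rows <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    model <- buildVariant(modelCfg, variant,
                          seed = subSeed(seed, "init", f))
    cfgF <- trainCfg
    cfgF$seed <- subSeed(seed, "train", f)
    tr <- trainFold(model, folds[[f]], epochs, cfgF)
    ev <- evaluateFold(tr$model,
                       subsetEpochs(epochs, which(epochSubjects(epochs) %in%
                                                    folds[[f]]$testSubjects)))
    rows[[f]] <- data.frame(fold = f, accuracy = ev$accuracy,
                            macroF1 = ev$macroF1,
                            epochsTrained = tr$epochsTrained)
    models[[f]] <- tr$model
    if (verbose)
      message(sprintf("fold %d/%d: acc %.3f macroF1 %.3f (%d epochs)",
                      f, k, ev$accuracy, ev$macroF1, tr$epochsTrained))
  }
  perFold <- do.call(rbind, rows)
  list(perFold = perFold,
       summary = data.frame(
         metric = c("accuracy", "macroF1"),
         mean = c(mean(perFold$accuracy), mean(perFold$macroF1)),
         sd = c(sd(perFold$accuracy), sd(perFold$macroF1))),
       models = models, folds = folds)
}

#' Fold-wise model comparison
#'
#' Paired Wilcoxon signed-rank tests of a reference model against each
#' other model over the shared cross-validation folds, with
#' Benjamini-Hochberg correction across the comparisons. Identical metric
#' vectors (no nonzero differences) are reported as `noDifference` with
#' p = NA and excluded from the adjustment.
#'
#' @param metricsByModel named list of per-fold metric vectors (same folds,
#'   same order); the first entry is the reference.
#' @param Q target FDR.
#' @return data.frame: comparison, p, q, z, r, significant, noDifference.
#' @export
compareModels <- function(metricsByModel, Q = 0.05) {
  stopifnot(length(metricsByModel) >= 2L)
  lens <- vapply(metricsByModel, length, integer(1))
  if (length(unique(lens)) != 1L)
    stopTyped("earstress_bad_config", "models evaluated on different folds")
  ref <- names(metricsByModel)[1]
  others <- names(metricsByModel)[-1]
  rows <- lapply(others, function(nm) {
    res <- tryCatch(
      wilcoxonSignedRank(metricsByModel[[ref]], metricsByModel[[nm]]),
      earstress_degenerate_data = function(e) NULL)
    if (is.null(res))
      data.frame(comparison = paste(ref, "vs", nm), p = NA_real_,
                 z = NA_real_, r = NA_real_, noDifference = TRUE)
    else
      data.frame(comparison = paste(ref, "vs", nm), p = res$p, z = res$z,
                 r = res$r, noDifference = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$significant <- FALSE
  ok <- !is.na(out$p)
  if (any(ok)) {
    adj <- bhFdrAdjust(out$p[ok], Q = Q)
    out$q[ok] <- adj$q
    out$significant[ok] <- adj$significant
  }
  out[, c("comparison", "p", "q", "z", "r", "significant", "noDifference")]
}
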