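#' Capture bidirectional cross-attention maps
#'
#' Evaluation-mode forward pass recording, for every epoch, the two
#' row-stochastic `T' x T'` attention maps (left-to-right: left-stream
#' queries against right-stream keys/values; right-to-left: the reverse).
#' Rows index query time bins, columns key time bins.
#'
#' @param model an `earstressModel` whose variant includes cross-attention
#'   (`full` or `no_pointwise`); other variants raise a typed error.
#' @param x an [EpochSet-class] or `(N, 2, 7500)` array.
#' @param batchSize samples per forward chunk.
#' @return list (one entry per epoch) of `list(LR = map, RL = map)`.
#' @export
captureAttention <- function(model, x, batchSize = 64L) {
  if (!usesCrossAttention(model$variant))
    stopTyped("earstress_unsupported_variant",
              "variant '%s' has no cross-attention maps to capture",
              model$variant)
  X <- asInputArray(x)
  N <- dim(X)[1]
  maps <- vector("list", N)
  for (s in seq(1L, N, by = batchSize)) {
    idx <- s:min(N, s + batchSize - 1L)
    fw <- forwardModel(model, X[idx, , , drop = FALSE], training = FALSE,
                       capture = TRUE)
    maps[idx] <- fw$attention
  }
  maps
}

#' Row-wise attention entropy
#'
#' Each row is renormalized to a distribution `P[i, j] = A[i, j] / sum_j
#' A[i, j]` and its Shannon entropy `H_i = -sum_j P[i, j] log P[i, j]`
#' (natural log, `0 log 0 = 0`) is returned together with the row mean.
#' `normalized = TRUE` additionally divides by `log(T')`, mapping into
#' `[0, 1]`.
#'
#' @param map nonnegative `T' x T'` matrix with positive row sums.
#' @param normalized divide by the maximum entropy `log(T')`.
#' @return list: `perRow` (numeric `T'`), `mean`.
#' @export
rowEntropy <- function(map, normalized = FALSE) {
  if (any(map < 0))
    stopTyped("earstress_bad_map", "attention map must be nonnegative")
  rs <- rowSums(map)
  if (any(rs <= 0))
    stopTyped("earstress_bad_map", "attention map has a zero row")
  P <- map / rs
  terms <- ifelse(P > 0, P * log(P), 0)
  H <- -rowSums(terms)
  if (normalized) H <- H / log(ncol(map))
  list(perRow = H, mean = mean(H))
}

#' Directional asymmetry of an attention map
#'
#' Frobenius-norm ratio `||A - A'||_F / ||A||_F`: 0 for a symmetric map,
#' larger for stronger directional (look-ahead vs look-behind) bias,
#' bounded above by 2.
#'
#' @param map numeric square matrix; must not be all zero.
#' @return scalar asymmetry index.
#' @export
directionalAsymmetry <- function(map) {
  denom <- sqrt(sum(map^2))
  if (denom == 0)
    stopTyped("earstress_bad_map", "asymmetry undefined for an all-zero map")
  sqrt(sum((map - t(map))^2)) / denom
}

#' Zero-baseline temporal occlusion
#'
#' Slides a `wS`-second window (step `stepS` s) over the two-channel
#' input, zeroes both channels inside the window, and records the change
#' in the class logit `delta_c(t) = logit_c(x) - logit_c(x_occ(t))`.
#' Positive values mark supportive time segments for class `classC`
#' (masking removes evidence), negative values counterevidence. Windows
#' are half-open sample ranges `[start, start + W)`; positions that would
#' overlap the epoch end are dropped; times are reported at window
#' centers.
#'
#' @param model trained `earstressModel`, or a plain function mapping an
#'   `(N, 2, T)` array to an `N x 2` logit matrix with columns
#'   (relax, stress) — useful for closed-form surrogate checks.
#' @param epoch a `2 x 7500` matrix (channels earL, earR).
#' @param classC `"stress"` or `"relax"`.
#' @param wS window width in seconds (default 0.5 -> 62 samples at 125 Hz).
#' @param stepS step in seconds (default 0.1 -> 12 samples).
#' @param fs sampling rate of the epoch (Hz).
#' @param batchSize occluded inputs per forward chunk.
#' @return list of class `earstress_occlusion`: `times` (window centers,
#'   s), `deltaLogit`, `peakTimeS`, `positiveArea`, `negativeArea`,
#'   `windowS`, `stepS`, `class`.
#' @export
temporalOcclusion <- function(model, epoch, classC = "stress", wS = 0.5,
                              stepS = 0.1, fs = 125, batchSize = 128L) {
  if (wS <= 0 || stepS <= 0)
    stopTyped("earstress_bad_config", "window and step must be positive")
  stopifnot(is.matrix(epoch), nrow(epoch) == 2L)
  Tn <- ncol(epoch)
  W <- floor(wS * fs)
  step <- floor(stepS * fs)
  if (W >= Tn)
    stopTyped("earstress_bad_config", "window longer than the epoch")
  starts <- seq(0L, Tn - W, by = step)    # 0-based window starts
  cls <- match.arg(classC, c("stress", "relax"))
  logitsOf <- function(x) {
    if (is.function(model)) {
      lg <- model(asInputArray(x))
      colnames(lg) <- c("relax", "stress")
      lg
    } else classify(model, x)
  }
  base <- logitsOf(epoch)[1, cls]
  nW <- length(starts)
  delta <- numeric(nW)
  for (s in seq(1L, nW, by = batchSize)) {
    idx <- s:min(nW, s + batchSize - 1L)
    Xb <- array(0, c(length(idx), 2L, Tn))
    for (j in seq_along(idx)) {
      occ <- epoch
      rng <- (starts[idx[j]] + 1L):(starts[idx[j]] + W)
      occ[, rng] <- 0
      Xb[j, , ] <- occ
    }
    delta[idx] <- base - logitsOf(Xb)[, cls]
  }
  times <- (starts + W / 2) / fs
  structure(list(times = times, deltaLogit = delta,
                 peakTimeS = times[which.max(delta)],
                 positiveArea = sum(delta[delta > 0]),
                 negativeArea = sum(delta[delta < 0]),
                 windowS = wS, stepS = stepS, class = cls, nWindows = nW),
            class = "earstress_occlusion")
}

#' Per-sample attention summaries for an epoch set
#'
#' @param model cross-attention `earstressModel`.
#' @param epochs [EpochSet-class].
#' @param foldId fold identifier attached to every row.
#' @return data.frame: foldId, sample, subjectId, label, direction,
#'   meanRowEntropy (nats), asymmetry.
#' @export
summarizeAttention <- function(model, epochs, foldId = 1L) {
  maps <- captureAttention(model, epochs)
  lab <- ifelse(epochLabels(epochs) == 1L, "stress", "relax")
  rows <- lapply(seq_along(maps), function(i) {
    do.call(rbind, lapply(c("LR", "RL"), function(d) {
      data.frame(foldId = foldId, sample = i,
                 subjectId = epochSubjects(epochs)[i], label = lab[i],
                 direction = d,
                 meanRowEntropy = rowEntropy(maps[[i]][[d]])$mean,
                 asymmetry = directionalAsymmetry(maps[[i]][[d]]),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Stress-minus-relax delta summaries per fold
#'
#' Groups per-sample statistics by fold (and direction, when present),
#' averages within label, and reports the stress-minus-relax delta of
#' every numeric statistic per fold, plus across-fold means and sign
#' counts. Negative entropy deltas mean more concentrated attention under
#' stress; positive asymmetry deltas mean stronger directional bias.
#'
#' @param df data.frame with columns `foldId`, `label` (stress/relax),
#'   optionally `direction`, and one or more numeric statistic columns
#'   (e.g. from [summarizeAttention()], or mean occlusion delta-logits).
#' @return list: `perFold` (one delta row per fold x direction),
#'   `acrossFolds` (mean delta and positive/negative fold counts per
#'   direction and statistic).
#' @export
deltaSummaries <- function(df) {
  stopifnot(all(c("foldId", "label") %in% names(df)))
  if (!"direction" %in% names(df)) df$direction <- "all"
  statCols <- names(df)[vapply(df, is.numeric, logical(1))]
  statCols <- setdiff(statCols, c("foldId", "sample"))
  groups <- split(df, list(df$foldId, df$direction), drop = TRUE)
  perFold <- do.call(rbind, lapply(groups, function(g) {
    if (!all(c("stress", "relax") %in% g$label))
      stopTyped("earstress_single_label",
                "fold %s has only one label; deltas undefined", g$foldId[1])
    s <- g[g$label == "stress", , drop = FALSE]
    r <- g[g$label == "relax", , drop = FALSE]
    out <- data.frame(foldId = g$foldId[1], direction = g$direction[1])
    for (cl in statCols) out[[paste0("delta_", cl)]] <-
        mean(s[[cl]]) - mean(r[[cl]])
    out
  }))
  rownames(perFold) <- NULL
  perFold <- perFold[order(perFold$direction, perFold$foldId), ]
  acrossFolds <- do.call(rbind, lapply(split(perFold, perFold$direction),
    function(g) {
      do.call(rbind, lapply(paste0("delta_", statCols), function(cl) {
        data.frame(direction = g$direction[1], statistic = cl,
                   mean = mean(g[[cl]]), nPositive = sum(g[[cl]] > 0),
                   nNegative = sum(g[[cl]] < 0), nFolds = nrow(g))
      }))
    }))
  rownames(acrossFolds) <- NULL
  list(perFold = perFold, acrossFolds = acrossFolds)
}

#' Explainability summaries across cross-validation folds
#'
#' For every fold of a [runCrossValidation()] result: captures attention
#' on the fold's held-out test epochs, computes entropy/asymmetry
#' summaries, runs temporal occlusion per test epoch, and aggregates
#' stress-minus-relax deltas (mean over samples within label, then delta,
#' then across-fold mean).
#'
#' @param cv result of [runCrossValidation()] (cross-attention variant).
#' @param epochs the same [EpochSet-class] used for the cross-validation.
#' @param classC occlusion class (default "stress").
#' @param occlusion run the (slower) occlusion profiles too.
#' @param occlusionStepS occlusion window step in seconds.
#' @return list: `attention` and (optionally) `occlusion` delta summaries
#'   (see [deltaSummaries()]), plus raw per-sample data frames.
#' @export
explainCrossValidation <- function(cv, epochs, classC = "stress",
                                   occlusion = TRUE, occlusionStepS = 0.1) {
  subs <- epochSubjects(epochs)
  attRows <- list()
  occRows <- list()
  for (f in seq_along(cv$folds)) {
    idx <- which(subs %in% cv$folds[[f]]$testSubjects)
    test <- subsetEpochs(epochs, idx)
    model <- cv$models[[f]]
    attRows[[f]] <- summarizeAttention(model, test, foldId = f)
    if (occlusion) {
      lab <- ifelse(epochLabels(test) == 1L, "stress", "relax")
      occRows[[f]] <- do.call(rbind, lapply(seq_len(nEpochs(test)),
        function(i) {
          prof <- temporalOcclusion(model, earEpochs(test)[i, , ],
                                    classC = classC,
                                    stepS = occlusionStepS)
          data.frame(foldId = f, sample = i, label = lab[i],
                     meanDeltaLogit = mean(prof$deltaLogit),
                     peakTimeS = prof$peakTimeS,
                     positiveArea = prof$positiveArea,
                     negativeArea = prof$negativeArea,
                     stringsAsFactors = FALSE)
        }))
    }
  }
  att <- do.call(rbind, attRows)
  out <- list(attentionSamples = att, attention = deltaSummaries(att))
  if (occlusion) {
    occ <- do.call(rbind, occRows)
    out$occlusionSamples <- occ
    out$occlusion <- deltaSummaries(
      occ[, c("foldId", "label", "meanDeltaLogit", "positiveArea",
              "negativeArea")])
  }
  out
}
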