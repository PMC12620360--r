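#' Band-pass and notch filtering
#'
#' Applies a sixth-order Butterworth band-pass (default 1-40 Hz) followed by
#' a second-order IIR notch (default 60 Hz, quality factor 30). By default
#' both filters are applied forward-backward (zero phase, so the effective
#' attenuation order doubles and no group delay biases epoch alignment);
#' set `zeroPhase = FALSE` for causal single-pass filtering.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band edges in Hz.
#' @param order band-pass filter order (6 = three biquad pole pairs per edge).
#' @param notch notch center frequency in Hz; `NULL` disables it.
#' @param notchQ notch quality factor (center / -3 dB bandwidth).
#' @param zeroPhase forward-backward filtering if `TRUE` (default).
#' @return filtered [EEGRecording-class] with identical shape and labels.
#' @export
bandpassNotch <- function(rec, low = 1, high = 40, order = 6, notch = 60,
                          notchQ = 30, zeroPhase = TRUE) {
  fs <- rec@fs
  if (fs <= 2 * high)
    stopTyped("earstress_bad_band",
              "sampling rate %g Hz too low for a %g Hz band edge", fs, high)
  if (order %% 2 != 0)
    stopTyped("earstress_bad_band", "band-pass order must be even")
  bp <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  apply1 <- function(x, flt) {
    if (zeroPhase) signal::filtfilt(flt, x) else
      as.numeric(signal::filter(flt, x))
  }
  out <- t(apply(rec@data, 1, apply1, flt = bp))
  if (!is.null(notch) && notch < fs / 2) {
    nf <- designNotch(notch, fs, notchQ)
    out <- t(apply(out, 1, apply1, flt = nf))
  }
  EEGRecording(out, fs = fs, channelLabels = rec@channelLabels,
               subjectId = rec@subjectId, condition = rec@condition)
}

# Second-order IIR notch (constrained biquad): unit gain in the pass band,
# zero at f0, -3 dB bandwidth f0 / Q.
designNotch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

#' Down-sample a recording to a target rate
#'
#' Decimates by keeping every `fs / targetFs`-th sample. The 40 Hz low-pass
#' of [bandpassNotch()] already suppresses energy above the 62.5 Hz Nyquist
#' of the 125 Hz target, so no additional anti-alias filter is applied;
#' apply the band-pass first (the intended order of operations).
#'
#' @param rec an [EEGRecording-class].
#' @param targetFs target sampling rate in Hz; must divide `fs`.
#' @return decimated [EEGRecording-class].
#' @export
resampleToTarget <- function(rec, targetFs = 125) {
  fs <- rec@fs
  if (targetFs > fs)
    stopTyped("earstress_bad_resample",
              "target rate %g Hz exceeds recording rate %g Hz", targetFs, fs)
  factor <- fs / targetFs
  if (abs(factor - round(factor)) > 1e-9)
    stopTyped("earstress_bad_resample",
              "fs %g Hz is not an integer multiple of target %g Hz", fs, targetFs)
  factor <- as.integer(round(factor))
  idx <- seq(1L, ncol(rec@data), by = factor)
  EEGRecording(rec@data[, idx, drop = FALSE], fs = targetFs,
               channelLabels = rec@channelLabels,
               subjectId = rec@subjectId, condition = rec@condition)
}

#' Run the full preprocessing chain on one recording
#'
#' Band-pass + notch at the raw rate, then decimation to `targetFs`.
#'
#' @inheritParams bandpassNotch
#' @param targetFs target sampling rate (Hz).
#' @return preprocessed [EEGRecording-class].
#' @export
preprocessRecording <- function(rec, low = 1, high = 40, order = 6,
                                notch = 60, targetFs = 125,
                                zeroPhase = TRUE) {
  resampleToTarget(
    bandpassNotch(rec, low = low, high = high, order = order, notch = notch,
                  zeroPhase = zeroPhase),
    targetFs = targetFs)
}

#' Extract fixed-length epochs from preprocessed recordings
#'
#' Takes the first `epochS` seconds of each recording as one epoch (the
#' whole 1-min rest block at the defaults), ear channels ordered
#' (earL, earR), scalp channels retained in parallel when present. Labels:
#' stress = 1, relax = 0. Multi-epoch slicing (consecutive non-overlapping
#' `epochS`-second windows from longer recordings, a data-augmentation
#' mode) is available via `maxEpochsPerRecording` but off by default:
#' classification operates on whole rest blocks.
#'
#' @param recordings list of preprocessed [EEGRecording-class] (125 Hz).
#' @param epochS epoch length in seconds (default 60 -> 7500 samples).
#' @param maxEpochsPerRecording maximum consecutive epochs sliced from
#'   each recording (default 1).
#' @return an [EpochSet-class].
#' @export
extractEpochs <- function(recordings, epochS = 60,
                          maxEpochsPerRecording = 1L) {
  stopifnot(length(recordings) > 0, maxEpochsPerRecording >= 1L)
  fs <- recordings[[1]]@fs
  nSamp <- as.integer(round(epochS * fs))
  hasScalp <- all(vapply(recordings, function(r)
    all(SCALP_CHANNELS %in% r@channelLabels), logical(1)))
  ears <- list(); scalps <- list(); labels <- integer(0)
  subjects <- character(0)
  for (rec in recordings) {
    if (abs(rec@fs - fs) > 1e-9)
      stopTyped("earstress_bad_epoching", "recordings have mixed sampling rates")
    if (ncol(rec@data) < nSamp)
      stopTyped("earstress_too_short",
                "recording %s/%s has %.2f s, epoch needs %g s",
                rec@subjectId, rec@condition, ncol(rec@data) / fs, epochS)
    missing <- setdiff(EAR_CHANNELS, rec@channelLabels)
    if (length(missing))
      stopTyped("earstress_missing_channel", "missing channel(s): %s",
                paste(missing, collapse = ", "))
    nAvail <- min(maxEpochsPerRecording, ncol(rec@data) %/% nSamp)
    for (w in seq_len(nAvail)) {
      idx <- ((w - 1L) * nSamp + 1L):(w * nSamp)
      ears[[length(ears) + 1L]] <- rec@data[EAR_CHANNELS, idx]
      if (hasScalp)
        scalps[[length(scalps) + 1L]] <- rec@data[SCALP_CHANNELS, idx]
      labels <- c(labels, if (rec@condition == "stress") 1L else 0L)
      subjects <- c(subjects, rec@subjectId)
    }
  }
  n <- length(ears)
  ear <- array(NA_real_, c(n, 2, nSamp))
  scalp <- if (hasScalp) array(NA_real_, c(n, 6, nSamp)) else
    array(numeric(0), c(0, 0, 0))
  for (i in seq_len(n)) {
    ear[i, , ] <- ears[[i]]
    if (hasScalp) scalp[i, , ] <- scalps[[i]]
  }
  dimnames(ear) <- list(NULL, EAR_CHANNELS, NULL)
  if (hasScalp) dimnames(scalp) <- list(NULL, SCALP_CHANNELS, NULL)
  EpochSet(earEpochs = ear, labels = labels, subjectIds = subjects, fs = fs,
           scalpEpochs = scalp)
}

#' Simulate, preprocess and epoch in one call
#'
#' Convenience wrapper: [generatePairedDataset()] then
#' [preprocessRecording()] then [extractEpochs()].
#'
#' @param config a [generatorConfig()].
#' @param targetFs target sampling rate (Hz).
#' @return an [EpochSet-class].
#' @export
simulateEpochs <- function(config, targetFs = 125) {
  recs <- generatePairedDataset(config)
  extractEpochs(lapply(recs, preprocessRecording, targetFs = targetFs))
}
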