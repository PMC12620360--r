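#' @title Core containers for ear/scalp EEG recordings and epochs
#' @name earstress-classes
#' @description S4 containers used throughout the package: `EEGRecording`
#'   holds one labeled multichannel time series; `EpochSet` holds the
#'   fixed-length (7500-sample, 125 Hz) two-channel ear epochs fed to the
#'   classifier, with the parallel six-channel scalp epochs used for
#'   paradigm validation.
NULL

# The montage is fixed by the recording setup: two preauricular ear channels
# plus six scalp channels used only for paradigm validation.
EAR_CHANNELS   <- c("earL", "earR")
SCALP_CHANNELS <- c("AF7", "Fpz", "AF8", "C3", "Cz", "C4")
ALL_CHANNELS   <- c(EAR_CHANNELS, SCALP_CHANNELS)
CONDITIONS     <- c("stress", "relax")

#' EEGRecording: one labeled multichannel EEG time series
#'
#' @slot data numeric matrix, channels x samples, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector naming the rows of `data`.
#' @slot subjectId subject identifier.
#' @slot condition `"stress"` (post-stressor rest) or `"relax"`
#'   (post-relaxation rest).
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    subjectId = "character",
    condition = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msgs <- character(0)
  if (nrow(object@data) != length(object@channelLabels))
    msgs <- c(msgs, "data row count must equal channel label count")
  if (anyDuplicated(object@channelLabels))
    msgs <- c(msgs, "channel labels must be unique")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (!all(is.finite(object@data)))
    msgs <- c(msgs, "data must contain only finite samples")
  if (!object@condition %in% CONDITIONS)
    msgs <- c(msgs, sprintf("condition must be one of %s",
                            paste(CONDITIONS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channelLabels row names for `data`.
#' @param subjectId subject identifier.
#' @param condition `"stress"` or `"relax"`.
#' @return an [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fs, channelLabels, subjectId, condition) {
  rownames(data) <- channelLabels
  new("EEGRecording", data = data, fs = fs,
      channelLabels = as.character(channelLabels),
      subjectId = as.character(subjectId), condition = condition)
}

#' @describeIn EEGRecording channels x samples matrix.
#' @param x an `EEGRecording`.
#' @export
recordingData <- function(x) x@data

#' @describeIn EEGRecording sampling rate (Hz).
#' @export
samplingRate <- function(x) x@fs

#' @describeIn EEGRecording channel labels.
#' @export
channelLabels <- function(x) x@channelLabels

#' @describeIn EEGRecording subject identifier.
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn EEGRecording condition label.
#' @export
condition <- function(x) x@condition

#' Number of samples in a recording
#' @param x an `EEGRecording`.
#' @export
nSamples <- function(x) ncol(x@data)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording: subject %s, %s | %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@subjectId, object@condition, nrow(object@data), ncol(object@data),
    object@fs, ncol(object@data) / object@fs))
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

#' EpochSet: fixed-length epochs ready for classification and validation
#'
#' Ear epochs are stored as an `n x 2 x T` array (channel order earL, earR);
#' scalp epochs, when present, as `n x 6 x T`. Labels use stress = 1,
#' relax = 0.
#'
#' @slot earEpochs numeric array `n x 2 x T`.
#' @slot scalpEpochs numeric array `n x 6 x T` or a 0-length array.
#' @slot labels integer vector in {0, 1}.
#' @slot subjectIds character vector, one per epoch.
#' @slot fs sampling rate (Hz) of the epochs.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    earEpochs = "array",
    scalpEpochs = "array",
    labels = "integer",
    subjectIds = "character",
    fs = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msgs <- character(0)
  d <- dim(object@earEpochs)
  n <- d[1]
  if (length(d) != 3L || d[2] != 2L)
    msgs <- c(msgs, "earEpochs must be an n x 2 x T array")
  if (!all(object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0 (relax) or 1 (stress)")
  if (length(object@labels) != n || length(object@subjectIds) != n)
    msgs <- c(msgs, "labels and subjectIds must have one entry per epoch")
  if (length(object@scalpEpochs)) {
    ds <- dim(object@scalpEpochs)
    if (length(ds) != 3L || ds[1] != n || ds[2] != 6L || ds[3] != d[3])
      msgs <- c(msgs, "scalpEpochs must be an n x 6 x T array parallel to earEpochs")
  }
  if (length(msgs)) msgs else TRUE
})

EpochSet <- function(earEpochs, labels, subjectIds, fs,
                     scalpEpochs = array(numeric(0), c(0, 0, 0))) {
  new("EpochSet", earEpochs = earEpochs, scalpEpochs = scalpEpochs,
      labels = as.integer(labels), subjectIds = as.character(subjectIds),
      fs = fs)
}

#' @describeIn EpochSet n x 2 x T ear-channel array.
#' @param x an `EpochSet`.
#' @export
earEpochs <- function(x) x@earEpochs

#' @describeIn EpochSet n x 6 x T scalp-channel array (may be empty).
#' @export
scalpEpochs <- function(x) x@scalpEpochs

#' @describeIn EpochSet integer labels (stress = 1, relax = 0).
#' @export
epochLabels <- function(x) x@labels

#' @describeIn EpochSet subject id per epoch.
#' @export
epochSubjects <- function(x) x@subjectIds

#' @describeIn EpochSet number of epochs.
#' @export
nEpochs <- function(x) dim(x@earEpochs)[1]

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@earEpochs)
  cat(sprintf(
    "EpochSet: %d epochs x %d samples @ %g Hz | %d stress / %d relax | %d subjects%s\n",
    d[1], d[3], object@fs, sum(object@labels == 1L), sum(object@labels == 0L),
    length(unique(object@subjectIds)),
    if (length(object@scalpEpochs)) " | scalp channels attached" else ""))
})

# subset an EpochSet by epoch index
subsetEpochs <- function(x, idx) {
  EpochSet(
    earEpochs = x@earEpochs[idx, , , drop = FALSE],
    labels = x@labels[idx],
    subjectIds = x@subjectIds[idx],
    fs = x@fs,
    scalpEpochs = if (length(x@scalpEpochs))
      x@scalpEpochs[idx, , , drop = FALSE] else array(numeric(0), c(0, 0, 0))
  )
}
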