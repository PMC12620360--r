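# The seven canonical scalp-EEG stress markers computed per epoch:
# frontal alpha asymmetry ln a(AF8) - ln a(AF7); alpha power (8-13 Hz) at
# AF7 and AF8; beta power (14-30 Hz) at Cz; theta/beta ratio at Cz
# (4-7 / 14-30 Hz); mean high-beta (23-36 Hz) coherence over the AF7-C3,
# AF8-C4 and Fpz-Cz pairs; frontal-midline theta power (4-7 Hz) at Fpz.

MARKER_NAMES <- c("faa", "alphaAF7", "alphaAF8", "betaCz", "thetaBetaCz",
                  "highBetaCoh", "fmThetaFpz")

COHERENCE_PAIRS <- list(c("AF7", "C3"), c("AF8", "C4"), c("Fpz", "Cz"))

#' Compute the seven scalp-EEG stress markers
#'
#' One marker row per epoch, computed from the six scalp channels with the
#' package's Welch estimator (2-s Hamming segments, 50% overlap).
#'
#' @param epochs an [EpochSet-class] with scalp channels attached.
#' @return data.frame with columns subjectId, condition and the seven
#'   markers: `faa` (unitless log-ratio), `alphaAF7`, `alphaAF8`, `betaCz`,
#'   `fmThetaFpz` (uV^2), `thetaBetaCz` (unitless), `highBetaCoh`
#'   (mean coherence in `[0, 1]`).
#' @export
computeMarkers <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  if (!length(scalpEpochs(epochs)))
    stopTyped("earstress_missing_channel",
              "epoch set has no scalp channels; markers need %s",
              paste(SCALP_CHANNELS, collapse = ", "))
  scalp <- scalpEpochs(epochs)
  fs <- epochs@fs
  n <- nEpochs(epochs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- function(name) scalp[i, name, ]
    aAF7 <- welchBandPower(ch("AF7"), fs, BANDS$alpha)
    aAF8 <- welchBandPower(ch("AF8"), fs, BANDS$alpha)
    if (aAF7 <= 0 || aAF8 <= 0)
      stopTyped("earstress_degenerate_marker",
                "zero alpha power; frontal alpha asymmetry undefined")
    bCz <- welchBandPower(ch("Cz"), fs, BANDS$beta)
    tCz <- welchBandPower(ch("Cz"), fs, BANDS$theta)
    coh <- mean(vapply(COHERENCE_PAIRS, function(pr)
      bandCoherence(ch(pr[1]), ch(pr[2]), fs, BANDS$highBeta), numeric(1)))
    out[[i]] <- data.frame(
      subjectId = epochSubjects(epochs)[i],
      condition = if (epochLabels(epochs)[i] == 1L) "stress" else "relax",
      faa = log(aAF8) - log(aAF7),
      alphaAF7 = aAF7, alphaAF8 = aAF8, betaCz = bCz,
      thetaBetaCz = tCz / bCz, highBetaCoh = coh,
      fmThetaFpz = welchBandPower(ch("Fpz"), fs, BANDS$theta),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
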