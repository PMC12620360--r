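#' Welch power spectral density
#'
#' Mean periodogram over Hamming-windowed segments (default 2 s with 50%
#' overlap — 0.5 Hz resolution and ~59 averages on a 60-s, 125 Hz epoch).
#' Segment means are removed before windowing. One-sided density scaling:
#' integrating the PSD over frequency recovers signal variance.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param segSeconds segment length in seconds.
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `freq` (Hz) and `psd` (power per Hz, e.g. uV^2/Hz).
#' @export
welchPsd <- function(x, fs, segSeconds = 2, overlap = 0.5) {
  L <- round(segSeconds * fs)
  if (length(x) < L)
    stopTyped("earstress_bad_band",
              "signal shorter than one Welch segment (%d samples)", L)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)) # Hamming
  seg <- matrix(x[outer(0:(L - 1), starts, "+")], nrow = L)
  seg <- sweep(seg, 2, colMeans(seg))
  X <- stats::mvfft(seg * w)
  nb <- floor(L / 2) + 1L
  P <- Mod(X[seq_len(nb), , drop = FALSE])^2 / (fs * sum(w^2))
  onesided <- rowMeans(P)
  # double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nb] <- 1
  list(freq = (seq_len(nb) - 1) * fs / L, psd = onesided * dbl)
}

#' Band power from the Welch PSD
#'
#' Trapezoidal integral of the Welch PSD over the closed band
#' `[band[1], band[2]]` (grid points with center frequency inside the band).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param band numeric length-2, band edges in Hz; must lie in (0, fs/2).
#' @param ... passed to [welchPsd()].
#' @return band power (uV^2 for microvolt signals).
#' @export
welchBandPower <- function(x, fs, band, ...) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[2] <= band[1])
    stopTyped("earstress_bad_band",
              "band [%g, %g] Hz outside (0, %g) Hz", band[1], band[2], fs / 2)
  p <- welchPsd(x, fs, ...)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  if (sum(sel) < 2L)
    stopTyped("earstress_bad_band", "band [%g, %g] Hz spans < 2 PSD bins",
              band[1], band[2])
  trapz(p$freq[sel], p$psd[sel])
}

#' Band-averaged magnitude-squared coherence
#'
#' Welch cross-spectral estimate with the same segmentation as
#' [welchPsd()]; the magnitude-squared coherence
#' `|Sxy|^2 / (Sxx * Syy)` is averaged (arithmetic mean) over the
#' frequency bins whose center lies in the closed band.
#'
#' @param x,y numeric signal vectors of equal length.
#' @param fs sampling rate (Hz).
#' @param band numeric length-2, band edges in Hz.
#' @param segSeconds segment length in seconds.
#' @param overlap fractional overlap.
#' @return mean coherence in `[0, 1]`.
#' @export
bandCoherence <- function(x, y, fs, band, segSeconds = 2, overlap = 0.5) {
  stopifnot(length(x) == length(y))
  L <- round(segSeconds * fs)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  if (length(starts) < 2L)
    stopTyped("earstress_bad_band", "coherence needs at least two segments")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  segmentFfts <- function(v) {
    seg <- matrix(v[outer(0:(L - 1), starts, "+")], nrow = L)
    seg <- sweep(seg, 2, colMeans(seg))
    stats::mvfft(seg * w)
  }
  X <- segmentFfts(x); Y <- segmentFfts(y)
  nb <- floor(L / 2) + 1L
  X <- X[seq_len(nb), , drop = FALSE]; Y <- Y[seq_len(nb), , drop = FALSE]
  Sxy <- rowMeans(X * Conj(Y))
  Sxx <- rowMeans(Mod(X)^2)
  Syy <- rowMeans(Mod(Y)^2)
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  freq <- (seq_len(nb) - 1) * fs / L
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel))
    stopTyped("earstress_bad_band", "no PSD bins inside [%g, %g] Hz",
              band[1], band[2])
  mean(coh[sel])
}
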