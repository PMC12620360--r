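#' Condition effect sizes for the synthetic generator
#'
#' Multiplicative band-power gains and additive shifts applied to the
#' post-stressor (`stress`) condition relative to post-relaxation rest.
#' All `*Gain` entries are power gains (a gain of 1 = no effect); `faaShift`
#' is the additive shift injected into the frontal alpha asymmetry
#' log-ratio ln a(AF8) - ln a(AF7); `earLagMs` is the baseline cross-ear
#' mixing lag and `earLagShiftMs` the additional lag under stress.
#'
#' Defaults encode the directions reported for the validation markers
#' (frontal-midline theta up, AF7/AF8 alpha suppressed, Cz beta up,
#' high-beta coherence up, asymmetry shifted toward symmetry under stress)
#' at moderate magnitudes.
#'
#' @param fmThetaGain frontal-midline theta (4-7 Hz, Fpz) power gain.
#' @param alphaGain alpha (8-13 Hz, AF7/AF8 and ear sources) power gain.
#' @param czBetaGain beta (14-30 Hz, Cz and ear sources) power gain.
#' @param coherenceGain power gain of the shared high-beta (23-36 Hz)
#'   source mixed into the frontal-central pairs.
#' @param faaShift additive shift of the frontal alpha asymmetry under
#'   stress (log power units).
#' @param earLagMs cross-ear mixing lag, milliseconds.
#' @param earLagShiftMs additional cross-ear lag under stress, milliseconds.
#' @return a named list of class `earstress_effects`.
#' @export
effectSizes <- function(fmThetaGain = 2.0, alphaGain = 0.7, czBetaGain = 1.5,
                        coherenceGain = 1.6, faaShift = -0.15,
                        earLagMs = 8, earLagShiftMs = 2) {
  es <- list(fmThetaGain = fmThetaGain, alphaGain = alphaGain,
             czBetaGain = czBetaGain, coherenceGain = coherenceGain,
             faaShift = faaShift, earLagMs = earLagMs,
             earLagShiftMs = earLagShiftMs)
  gains <- unlist(es[c("fmThetaGain", "alphaGain", "czBetaGain", "coherenceGain")])
  if (any(!is.finite(gains)) || any(gains <= 0))
    stopTyped("earstress_bad_gain", "all effect gains must be positive")
  class(es) <- "earstress_effects"
  es
}

#' Null effect configuration: stress and relax identically distributed
#' @export
nullEffectSizes <- function() {
  effectSizes(fmThetaGain = 1, alphaGain = 1, czBetaGain = 1,
              coherenceGain = 1, faaShift = 0, earLagMs = 8,
              earLagShiftMs = 0)
}

#' Strong effect configuration for power / learnability studies
#' @export
strongEffectSizes <- function() {
  effectSizes(fmThetaGain = 6, alphaGain = 0.25, czBetaGain = 4,
              coherenceGain = 4, faaShift = -0.6, earLagMs = 8,
              earLagShiftMs = 6)
}

#' Synthetic generator configuration
#'
#' @param nSubjects number of subjects (>= 2); each contributes one stress
#'   and one relax recording.
#' @param fsRaw raw sampling rate in Hz (default 500).
#' @param duration recording duration in seconds (default 60).
#' @param noiseExponent 1/f background slope (default 1).
#' @param effects an [effectSizes()] object.
#' @param subjectSd between-subject log-gain standard deviation; subject
#'   band gains are log-normal and shared across conditions, making subject
#'   identity a confound that subject-level cross-validation must overcome.
#' @param seed integer root seed; all draws are keyed substreams of it.
#' @return a list of class `earstress_genconfig`.
#' @export
generatorConfig <- function(nSubjects, fsRaw = 500, duration = 60,
                            noiseExponent = 1.0, effects = effectSizes(),
                            subjectSd = 0.4, seed = 1L) {
  if (nSubjects < 2) stopTyped("earstress_bad_config", "nSubjects must be >= 2")
  if (fsRaw <= 2 * 40) stopTyped("earstress_bad_config",
                                 "fsRaw must exceed twice the 40 Hz band edge")
  if (duration <= 0) stopTyped("earstress_bad_config", "duration must be positive")
  stopifnot(inherits(effects, "earstress_effects"))
  cfg <- list(nSubjects = as.integer(nSubjects), fsRaw = fsRaw,
              duration = duration, noiseExponent = noiseExponent,
              effects = effects, subjectSd = subjectSd, seed = as.integer(seed))
  class(cfg) <- "earstress_genconfig"
  cfg
}

# Oscillator RMS amplitudes in microvolts. The background bands sit at
# O(1 uV) and the oscillators at O(1-10 uV); the scale is a documented
# convention, not fitted to any cohort.
OSC_AMP <- list(
  noise = 2.0,      # 1/f background, every channel
  fmTheta = 3.0,    # theta at Fpz
  czTheta = 1.0,    # small unmodulated theta at Cz (theta/beta ratio support)
  alpha = 4.0,      # alpha at AF7 / AF8
  czBeta = 3.0,     # beta at Cz
  scBeta = 1.5,     # unmodulated beta at C3 / C4
  hbShared = 1.2,   # shared high-beta source (coherence driver)
  hbPrivate = 1.2,  # channel-private high-beta
  earAlpha = 3.0,   # alpha component of each temporal (ear) source
  earBeta = 2.5,    # beta component of each temporal (ear) source
  earCross = 0.35   # cross-ear mixing weight of the lagged opposite source
)

BANDS <- list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30),
              highBeta = c(23, 36))

# --- frequency-domain synthesis -------------------------------------------
#
# Every signal component (background noise or band-limited oscillator) is
# white Gaussian noise shaped in the frequency domain and normalized to unit
# RMS via Parseval's identity. Components are stored as positive-frequency
# coefficients; a channel is assembled by summing scaled (and, for lagged
# mixtures, phase-ramped) component spectra and applying a single inverse
# FFT. Random draws are made once per component under its own substream
# seed, so adding channels or effects never perturbs existing draws.

# band-limited component: unit-gain mask over [lo, hi] with raised-cosine
# edges of width `taper` Hz, applied to complex white noise
bandComponent <- function(n, fs, lo, hi, seed, taper = 0.5) {
  kmax <- floor((n - 1) / 2)
  k0 <- max(1L, floor((lo - taper) * n / fs))
  k1 <- min(kmax, ceiling((hi + taper) * n / fs))
  idx <- k0:k1
  f <- idx * fs / n
  env <- numeric(length(idx))
  env[f >= lo & f <= hi] <- 1
  lo_t <- f >= lo - taper & f < lo
  hi_t <- f > hi & f <= hi + taper
  env[lo_t] <- 0.5 * (1 + cos(pi * (lo - f[lo_t]) / taper))
  env[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - hi) / taper))
  z <- withSeed(seed,
    complex(real = rnorm(length(idx)), imaginary = rnorm(length(idx)))) * env
  normalizeComponent(list(idx = idx, z = z), n)
}

# 1/f^a background: amplitude prop. to f^(-a/2) over the whole grid
pinkComponent <- function(n, fs, exponent, seed) {
  kmax <- floor((n - 1) / 2)
  idx <- seq_len(kmax)
  env <- (idx * fs / n)^(-exponent / 2)
  z <- withSeed(seed,
    complex(real = rnorm(kmax), imaginary = rnorm(kmax))) * env
  normalizeComponent(list(idx = idx, z = z), n)
}

# scale coefficients so the synthesized real signal has RMS 1
# (Parseval: sum(x^2) = sum(|X_k|^2) / n over the full, mirrored spectrum)
normalizeComponent <- function(comp, n) {
  rms <- sqrt(2 * sum(Mod(comp$z)^2)) / n
  if (rms > 0) comp$z <- comp$z / rms
  comp
}

# accumulate `amp * component`, delayed by `lag` samples (circular), into a
# positive-frequency accumulator vector
addComponent <- function(acc, comp, amp, n, lag = 0) {
  w <- comp$z * amp
  if (lag != 0)
    w <- w * exp(complex(imaginary = -2 * pi * comp$idx * lag / n))
  acc[comp$idx] <- acc[comp$idx] + w
  acc
}

# half-spectrum accumulator -> real time series (one inverse FFT)
synthesizeChannel <- function(acc, n) {
  spec <- complex(real = numeric(n))
  kmax <- length(acc)
  spec[1 + seq_len(kmax)] <- acc
  spec[n + 1 - seq_len(kmax)] <- Conj(acc)
  Re(fft(spec, inverse = TRUE)) / n
}

#' Generate one synthetic recording
#'
#' Builds an 8-channel, `fsRaw`-Hz, `duration`-second recording as 1/f
#' background noise plus band-limited oscillators: theta strongest at Fpz,
#' alpha at AF7/AF8, beta at Cz, and a shared high-beta source mixed into
#' the AF7-C3, AF8-C4 and Fpz-Cz pairs. The two ear channels are lagged
#' mixtures of left/right temporal sources carrying alpha and beta energy.
#' Under `condition = "stress"` the configured effect gains are applied to
#' oscillator amplitudes and mixing weights only; random substreams are
#' keyed by (seed, subject, condition, component), so gains never perturb
#' which numbers are drawn and the stress/relax pair differs exactly by the
#' injected effects plus independent noise draws.
#'
#' @param config a [generatorConfig()].
#' @param subjectId subject identifier string.
#' @param condition `"stress"` or `"relax"`.
#' @param channels channels to synthesize (default: the full montage).
#'   Per-component substream seeding makes any subset identical to the
#'   corresponding rows of the full montage.
#' @return an [EEGRecording-class].
#' @export
generateSubjectRecording <- function(config, subjectId, condition,
                                     channels = ALL_CHANNELS) {
  stopifnot(inherits(config, "earstress_genconfig"))
  if (!condition %in% CONDITIONS)
    stopTyped("earstress_bad_condition", "unknown condition '%s'", condition)
  channels <- match.arg(channels, ALL_CHANNELS, several.ok = TRUE)
  fs <- config$fsRaw
  n <- round(fs * config$duration)
  es <- config$effects
  stress <- condition == "stress"

  # subject-level log-normal band gains, shared across conditions
  g <- withSeed(subSeed(config$seed, subjectId, "subject-gains"),
                exp(rnorm(4, 0, config$subjectSd)))
  gT <- g[1]; gA <- g[2]; gB <- g[3]; gH <- g[4]

  key <- function(...) subSeed(config$seed, subjectId, condition, ...)
  osc <- function(name, band) bandComponent(n, fs, band[1], band[2], key(name))
  kmax <- floor((n - 1) / 2)

  # amplitude multipliers realizing the configured power gains under stress
  sqrtIf <- function(gain) if (stress) sqrt(gain) else 1
  thetaMul <- sqrtIf(es$fmThetaGain)
  betaMul <- sqrtIf(es$czBetaGain)
  alphaMulL <- sqrtIf(es$alphaGain) * (if (stress) exp(-es$faaShift / 4) else 1)
  alphaMulR <- sqrtIf(es$alphaGain) * (if (stress) exp(+es$faaShift / 4) else 1)
  alphaMulEar <- sqrtIf(es$alphaGain)
  sharedMul <- sqrtIf(es$coherenceGain)
  lagMs <- es$earLagMs + if (stress) es$earLagShiftMs else 0
  lag <- round(lagMs / 1000 * fs)

  needShared <- any(channels %in% c("AF7", "AF8", "Fpz", "C3", "Cz", "C4"))
  hbShared <- if (needShared) osc("hb-shared", BANDS$highBeta) else NULL
  needEar <- any(channels %in% EAR_CHANNELS)
  if (needEar) {
    earAlphaL <- osc("ear-alpha-L", BANDS$alpha)
    earAlphaR <- osc("ear-alpha-R", BANDS$alpha)
    earBetaL <- osc("ear-beta-L", BANDS$beta)
    earBetaR <- osc("ear-beta-R", BANDS$beta)
  }

  buildChannel <- function(ch) {
    acc <- complex(real = numeric(kmax))
    acc <- addComponent(acc, pinkComponent(n, fs, config$noiseExponent,
                                           key("noise", ch)),
                        OSC_AMP$noise, n)
    addHb <- function(acc) {
      acc <- addComponent(acc, hbShared, OSC_AMP$hbShared * gH * sharedMul, n)
      addComponent(acc, osc(paste0("hb-", ch), BANDS$highBeta),
                   OSC_AMP$hbPrivate * gH, n)
    }
    acc <- switch(ch,
      AF7 = addHb(addComponent(acc, osc("alpha-AF7", BANDS$alpha),
                               OSC_AMP$alpha * gA * alphaMulL, n)),
      AF8 = addHb(addComponent(acc, osc("alpha-AF8", BANDS$alpha),
                               OSC_AMP$alpha * gA * alphaMulR, n)),
      Fpz = addHb(addComponent(acc, osc("theta-Fpz", BANDS$theta),
                               OSC_AMP$fmTheta * gT * thetaMul, n)),
      Cz = addHb(addComponent(addComponent(acc, osc("beta-Cz", BANDS$beta),
                                           OSC_AMP$czBeta * gB * betaMul, n),
                              osc("theta-Cz", BANDS$theta),
                              OSC_AMP$czTheta * gT, n)),
      C3 = addHb(addComponent(acc, osc("beta-C3", BANDS$beta),
                              OSC_AMP$scBeta * gB, n)),
      C4 = addHb(addComponent(acc, osc("beta-C4", BANDS$beta),
                              OSC_AMP$scBeta * gB, n)),
      earL = {
        acc <- addComponent(acc, earAlphaL, OSC_AMP$earAlpha * gA * alphaMulEar, n)
        acc <- addComponent(acc, earBetaL, OSC_AMP$earBeta * gB * betaMul, n)
        acc <- addComponent(acc, earAlphaR,
                            OSC_AMP$earCross * OSC_AMP$earAlpha * gA * alphaMulEar,
                            n, lag = lag)
        addComponent(acc, earBetaR,
                     OSC_AMP$earCross * OSC_AMP$earBeta * gB * betaMul,
                     n, lag = lag)
      },
      earR = {
        acc <- addComponent(acc, earAlphaR, OSC_AMP$earAlpha * gA * alphaMulEar, n)
        acc <- addComponent(acc, earBetaR, OSC_AMP$earBeta * gB * betaMul, n)
        acc <- addComponent(acc, earAlphaL,
                            OSC_AMP$earCross * OSC_AMP$earAlpha * gA * alphaMulEar,
                            n, lag = lag)
        addComponent(acc, earBetaL,
                     OSC_AMP$earCross * OSC_AMP$earBeta * gB * betaMul,
                     n, lag = lag)
      })
    synthesizeChannel(acc, n)
  }

  data <- do.call(rbind, lapply(channels, buildChannel))
  EEGRecording(data, fs = fs, channelLabels = channels,
               subjectId = subjectId, condition = condition)
}

#' Generate a paired stress/relax dataset
#'
#' @param config a [generatorConfig()].
#' @param channels channels to synthesize (default: the full montage).
#' @return a list of `2 * nSubjects` [EEGRecording-class] objects (one
#'   stress and one relax per subject) with a `manifest` attribute
#'   (data.frame: subjectId, condition, index).
#' @export
generatePairedDataset <- function(config, channels = ALL_CHANNELS) {
  stopifnot(inherits(config, "earstress_genconfig"))
  ids <- sprintf("S%02d", seq_len(config$nSubjects))
  grid <- expand.grid(condition = CONDITIONS, subjectId = ids,
                      stringsAsFactors = FALSE)[, 2:1]
  recs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    recs[[i]] <- generateSubjectRecording(config, grid$subjectId[i],
                                          grid$condition[i], channels = channels)
  }
  attr(recs, "manifest") <- data.frame(subjectId = grid$subjectId,
                                       condition = grid$condition,
                                       index = seq_len(nrow(grid)),
                                       stringsAsFactors = FALSE)
  recs
}
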