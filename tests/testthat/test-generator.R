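# Synthetic paired-condition EEG generator

test_that("generation is deterministic and channel-subset consistent", {
  cfg <- generatorConfig(2, seed = 11)
  a <- generateSubjectRecording(cfg, "S01", "stress")
  b <- generateSubjectRecording(cfg, "S01", "stress")
  expect_identical(recordingData(a), recordingData(b))
  ears <- generateSubjectRecording(cfg, "S01", "stress",
                                   channels = c("earL", "earR"))
  expect_identical(recordingData(a)[c("earL", "earR"), ],
                   recordingData(ears))
  # different subject / condition give different draws
  expect_false(identical(
    recordingData(generateSubjectRecording(cfg, "S02", "stress")),
    recordingData(a)))
  expect_false(identical(
    recordingData(generateSubjectRecording(cfg, "S01", "relax")),
    recordingData(a)))
})

test_that("recordings satisfy the container invariants", {
  cfg <- generatorConfig(2, duration = 10, seed = 3)
  rec <- generateSubjectRecording(cfg, "S01", "relax")
  expect_s4_class(rec, "EEGRecording")
  expect_equal(dim(recordingData(rec)), c(8L, 5000L))
  expect_true(all(is.finite(recordingData(rec))))
  expect_equal(samplingRate(rec), 500)
  expect_error(generateSubjectRecording(cfg, "S01", "calm"),
               class = "earstress_bad_condition")
  expect_error(effectSizes(fmThetaGain = 0), class = "earstress_bad_gain")
  expect_error(generatorConfig(1), class = "earstress_bad_config")
})

test_that("paired dataset has one stress and one relax recording per subject", {
  cfg <- generatorConfig(4, duration = 5, seed = 5)
  recs <- generatePairedDataset(cfg)
  expect_length(recs, 8L)
  man <- attr(recs, "manifest")
  expect_equal(nrow(man), 8L)
  expect_equal(length(unique(man$subjectId)), 4L)
  counts <- table(man$subjectId, man$condition)
  expect_true(all(counts == 1L))
  # identical config regenerates identical data and manifest
  recs2 <- generatePairedDataset(cfg)
  expect_identical(attr(recs2, "manifest"), man)
  expect_identical(recordingData(recs2[[3]]), recordingData(recs[[3]]))
})

test_that("injected effects move their markers in the configured direction", {
  # direct Welch band power on the raw generated signals, one channel each
  cfg <- generatorConfig(30, effects = effectSizes(fmThetaGain = 4),
                        seed = 17)
  ratio <- vapply(sprintf("S%02d", 1:30), function(id) {
    s <- generateSubjectRecording(cfg, id, "stress", channels = "Fpz")
    r <- generateSubjectRecording(cfg, id, "relax", channels = "Fpz")
    welchBandPower(recordingData(s)[1, ], 500, c(4, 7)) /
      welchBandPower(recordingData(r)[1, ], 500, c(4, 7))
  }, numeric(1))
  expect_gte(mean(ratio > 1), 0.95)
  # the injected power gain is recovered on average (multiplicative, ~4x)
  expect_gt(exp(mean(log(ratio))), 2.5)
  expect_lt(exp(mean(log(ratio))), 6.5)
})

test_that("null-effect configuration makes conditions exchangeable", {
  cfg <- generatorConfig(40, effects = nullEffectSizes(), duration = 20,
                        seed = 23)
  diffs <- vapply(sprintf("S%02d", 1:40), function(id) {
    s <- generateSubjectRecording(cfg, id, "stress", channels = "Cz")
    r <- generateSubjectRecording(cfg, id, "relax", channels = "Cz")
    log(welchBandPower(recordingData(s)[1, ], 500, c(14, 30))) -
      log(welchBandPower(recordingData(r)[1, ], 500, c(14, 30)))
  }, numeric(1))
  # paired log-power differences should be centered at zero
  expect_gt(wilcoxonSignedRank(diffs, numeric(40) * 0)$p, 0.001)
  expect_lt(abs(mean(diffs)), 0.2)
})
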