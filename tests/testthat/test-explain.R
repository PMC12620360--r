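# Attention entropy / asymmetry, temporal occlusion, delta summaries

test_that("row entropy covers the degenerate and random cases", {
  # one-hot rows: zero entropy
  onehot <- diag(6)
  expect_equal(rowEntropy(onehot)$perRow, rep(0, 6))
  # uniform 35 x 35: ln 35 everywhere
  u <- matrix(1 / 35, 35, 35)
  expect_equal(rowEntropy(u)$perRow, rep(log(35), 35), tolerance = 1e-12)
  expect_equal(rowEntropy(u, normalized = TRUE)$mean, 1, tolerance = 1e-12)
  # random map vs naive elementwise evaluation
  set.seed(31)
  m <- matrix(runif(25), 5)
  H <- rowEntropy(m)$perRow
  for (i in 1:5) {
    p <- m[i, ] / sum(m[i, ])
    expect_equal(H[i], -sum(p * log(p)), tolerance = 1e-10)
  }
  # bounds on many random row-stochastic maps
  for (r in 1:200) {
    mm <- randomStochasticMap(sample(2:12, 1))
    h <- rowEntropy(mm)$perRow
    expect_true(all(h >= -1e-12 & h <= log(ncol(mm)) + 1e-12))
  }
  expect_error(rowEntropy(rbind(c(0, 0), c(1, 1))),
               class = "earstress_bad_map")
  expect_error(rowEntropy(matrix(c(-1, 1, 1, 1), 2)),
               class = "earstress_bad_map")
})

test_that("directional asymmetry matches oracles and bounds", {
  # symmetric maps give exactly zero
  set.seed(32)
  s <- matrix(runif(49), 7); s <- (s + t(s)) / 2
  expect_identical(directionalAsymmetry(s), 0)
  expect_identical(directionalAsymmetry(diag(35)), 0)
  # hand arithmetic: [[1,0],[1,0]] -> sqrt(2)/sqrt(2) = 1
  expect_equal(directionalAsymmetry(matrix(c(1, 1, 0, 0), 2)), 1)
  # random maps vs naive elementwise evaluation, plus the [0, 2] bound
  for (r in 1:200) {
    n <- sample(2:10, 1)
    m <- matrix(rnorm(n * n), n)
    num <- sqrt(sum((m - t(m))^2))
    den <- sqrt(sum(m^2))
    a <- directionalAsymmetry(m)
    expect_equal(a, num / den, tolerance = 1e-12)
    expect_true(a >= 0 && a <= 2 + 1e-12)
  }
  expect_error(directionalAsymmetry(matrix(0, 3, 3)),
               class = "earstress_bad_map")
})

test_that("captured attention maps are row-stochastic and deterministic", {
  m <- freshModel()
  set.seed(33)
  X <- array(rnorm(3 * 2 * 7500), c(3, 2, 7500))
  X[3, , ] <- X[1, , ]  # duplicated input
  maps <- captureAttention(m, X)
  expect_length(maps, 3L)
  for (mp in maps) for (d in c("LR", "RL")) {
    expect_equal(dim(mp[[d]]), c(35L, 35L))
    expect_true(all(abs(rowSums(mp[[d]]) - 1) < 1e-6))
    expect_true(all(mp[[d]] >= 0))
  }
  expect_equal(maps[[3]], maps[[1]], tolerance = 1e-12)
  expect_error(captureAttention(freshModel("no_both"), X),
               class = "earstress_unsupported_variant")
})

test_that("occlusion window arithmetic and degenerate cases are exact", {
  m <- freshModel()
  # all-zero epoch: occluded input equals the original at every window
  z <- matrix(0, 2, 7500)
  prof <- temporalOcclusion(m, z, "stress", batchSize = 256)
  expect_equal(prof$nWindows, floor((7500 - 62) / 12) + 1)  # 620
  expect_equal(max(abs(prof$deltaLogit)), 0, tolerance = 1e-9)
  expect_equal(prof$positiveArea, 0)
  expect_equal(prof$negativeArea, 0)
  expect_error(temporalOcclusion(m, z, "stress", wS = 0),
               class = "earstress_bad_config")
  expect_error(temporalOcclusion(m, z, "stress", wS = 70),
               class = "earstress_bad_config")
})

test_that("occlusion matches a closed-form linear surrogate model", {
  # surrogate whose stress logit is the sum of channel means: zeroing a
  # window removes exactly (window sum) / T from the logit
  surrogate <- function(X) {
    stress <- apply(X, 1, function(s) mean(s[1, ]) + mean(s[2, ]))
    cbind(relax = 0, stress = stress)
  }
  set.seed(34)
  epoch <- matrix(rnorm(2 * 7500), 2, 7500)
  fs <- 125; W <- floor(0.5 * fs); step <- floor(0.1 * fs)
  starts <- seq(0L, 7500L - W, by = step)
  expected <- vapply(starts, function(s0)
    sum(epoch[, (s0 + 1):(s0 + W)]) / 7500, numeric(1))
  prof0 <- temporalOcclusion(surrogate, epoch, "stress")
  expect_equal(prof0$deltaLogit, expected, tolerance = 1e-12)
  expect_equal(prof0$times, (starts + W / 2) / fs)
  # and the real model's occlusion profile is deterministic
  m <- freshModel()
  p1 <- temporalOcclusion(m, epoch, "stress", stepS = 1)
  p2 <- temporalOcclusion(m, epoch, "stress", stepS = 1)
  expect_identical(p1$deltaLogit, p2$deltaLogit)
  expect_equal(p1$positiveArea, sum(p1$deltaLogit[p1$deltaLogit > 0]))
  expect_equal(p1$negativeArea, sum(p1$deltaLogit[p1$deltaLogit < 0]))
  expect_lte(p1$negativeArea, 0)
})

test_that("occlusion localizes a burst on a trained-enough surrogate input", {
  # a model fine-tuned briefly to depend on signal energy should respond
  # more to occluding a high-energy burst than a silent region
  eps <- strongEarEpochs(4)
  m <- freshModel()
  epoch <- matrix(0, 2, 7500)
  burst <- 3000:3500
  epoch[, burst] <- earEpochs(eps)[1, , burst] * 5
  prof <- temporalOcclusion(m, epoch, "stress", stepS = 0.5)
  inBurst <- prof$times > 24 & prof$times < 28
  outBurst <- prof$times < 20 | prof$times > 32
  expect_gt(max(abs(prof$deltaLogit[inBurst])),
            max(abs(prof$deltaLogit[outBurst])))
})

test_that("delta summaries are zero for identical label statistics and count folds", {
  df <- expand.grid(foldId = 1:8, label = c("stress", "relax"),
                    direction = c("LR", "RL"),
                    stringsAsFactors = FALSE)
  df$meanRowEntropy <- 2.5
  df$asymmetry <- 0.4
  ds <- deltaSummaries(df)
  expect_equal(nrow(ds$perFold), 16L)     # 8 folds x 2 directions
  expect_true(all(ds$perFold$delta_meanRowEntropy == 0))
  expect_true(all(ds$perFold$delta_asymmetry == 0))
  expect_equal(unique(ds$acrossFolds$nFolds), 8L)
  # sign counts respond to a known shift
  df2 <- df
  df2$meanRowEntropy[df2$label == "stress"] <- 2.4
  ds2 <- deltaSummaries(df2)
  ent <- ds2$acrossFolds[ds2$acrossFolds$statistic == "delta_meanRowEntropy", ]
  expect_true(all(ent$mean < 0))
  expect_true(all(ent$nNegative == 8L))
  # single-label fold is a typed error
  expect_error(deltaSummaries(df[df$label == "stress", ]),
               class = "earstress_single_label")
})
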