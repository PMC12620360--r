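# Architecture assembly, determinism, variants

test_that("default build maps (N, 2, 7500) to logits and 35 x 35 attention", {
  m <- freshModel()
  set.seed(11)
  X <- array(rnorm(4 * 2 * 7500), c(4, 2, 7500))
  fw <- earstress:::forwardModel(m, X, training = FALSE, capture = TRUE)
  expect_equal(dim(fw$logits), c(4L, 2L))
  expect_length(fw$attention, 4L)
  expect_equal(dim(fw$attention[[1]]$LR), c(35L, 35L))
  expect_equal(dim(fw$attention[[1]]$RL), c(35L, 35L))
  for (a in fw$attention) {
    expect_true(all(abs(rowSums(a$LR) - 1) < 1e-6))
    expect_true(all(a$LR >= 0))
  }
  expect_equal(m$tokens, 35L)
})

test_that("builds are deterministic in the seed", {
  a <- buildModel(modelConfig(), seed = 123)
  b <- buildModel(modelConfig(), seed = 123)
  c <- buildModel(modelConfig(), seed = 124)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
  # parameter count is stable and in the documented vicinity (~0.06 M)
  expect_equal(parameterCount(a), parameterCount(b))
  expect_gt(parameterCount(a), 4e4)
  expect_lt(parameterCount(a), 1e5)
})

test_that("configurations that do not yield 35 tokens are rejected at build", {
  bad <- modelConfig(pool = list(c(5, 5), c(6, 6), c(6, 6)))
  expect_error(buildModel(bad), class = "earstress_bad_architecture")
  expect_error(modelConfig(kernelLengths = c(125, 63, 64, 20)),
               class = "earstress_bad_architecture")
  expect_error(modelConfig(kernelLengths = c(120, 63, 31, 20)),
               class = "earstress_bad_architecture")
})

test_that("evaluation mode is deterministic, permutation-equivariant and batch-size invariant", {
  m <- freshModel()
  set.seed(12)
  X <- array(rnorm(6 * 2 * 7500), c(6, 2, 7500))
  l1 <- classify(m, X)
  l2 <- classify(m, X)
  expect_identical(l1, l2)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(classify(m, X[perm, , ]), l1[perm, ], tolerance = 1e-10)
  single <- classify(m, X[3, , ])
  expect_equal(single[1, ], l1[3, ], tolerance = 1e-5)
})

test_that("all six variants build, run forward, and order parameters sensibly", {
  set.seed(13)
  X <- array(rnorm(2 * 2 * 7500), c(2, 2, 7500))
  counts <- sapply(c("full", "no_cross_attention", "no_pointwise", "no_both",
                     "self_attention", "lightweight_transformer"),
    function(v) {
      m <- buildVariant(modelConfig(), v, seed = 3)
      lg <- classify(m, X)
      expect_equal(dim(lg), c(2L, 2L))
      expect_true(all(is.finite(lg)))
      parameterCount(m)
    })
  # proposed cross-attention model is smaller than the transformer baseline
  expect_lt(counts["full"], counts["lightweight_transformer"])
  # attention-free variants expose no attention maps
  expect_error(captureAttention(freshModel("no_cross_attention"), X),
               class = "earstress_unsupported_variant")
  expect_error(buildVariant(modelConfig(), "does_not_exist"))
})

test_that("shared-stream encoders halve the encoder parameters", {
  sep <- buildModel(modelConfig(), seed = 1)
  sha <- buildModel(modelConfig(shareStreams = TRUE), seed = 1)
  expect_lt(parameterCount(sha), parameterCount(sep))
  set.seed(14)
  X <- array(rnorm(2 * 2 * 7500), c(2, 2, 7500))
  expect_true(all(is.finite(classify(sha, X))))
})

test_that("gradient flows to every trainable parameter (no dead branches)", {
  set.seed(15)
  X <- array(rnorm(4 * 2 * 7500), c(4, 2, 7500))
  y <- c(0L, 1L, 0L, 1L)
  for (v in c("full", "self_attention", "lightweight_transformer")) {
    m <- buildVariant(modelConfig(dropoutP = 0), v, seed = 2)
    fw <- earstress:::forwardModel(m, X, training = TRUE, keepCache = TRUE)
    ce <- earstress:::softmaxCrossEntropy(fw$logits, y)
    gr <- earstress:::backwardModel(m, fw$cache, ce$dlogits)
    expect_setequal(names(gr), names(m$params))
    # conv biases are absorbed by batch norm (gradient identically ~0);
    # every other parameter must receive nonzero gradient
    nonBias <- setdiff(names(m$params),
                       grep("conv[0-9]\\.b$", names(m$params), value = TRUE))
    for (nm in nonBias)
      expect_gt(max(abs(gr[[nm]])), 0, label = sprintf("%s/%s", v, nm))
  }
})

test_that("full-model gradients match numeric differentiation at spot-checked parameters", {
  set.seed(16)
  X <- array(rnorm(2 * 2 * 7500), c(2, 2, 7500))
  y <- c(0L, 1L)
  m <- buildModel(modelConfig(dropoutP = 0), seed = 5)
  lossAt <- function(model) {
    f <- earstress:::forwardModel(model, X, training = TRUE)
    earstress:::softmaxCrossEntropy(f$logits, y)$loss
  }
  fw <- earstress:::forwardModel(m, X, training = TRUE, keepCache = TRUE)
  ce <- earstress:::softmaxCrossEntropy(fw$logits, y)
  gr <- earstress:::backwardModel(m, fw$cache, ce$dlogits)
  eps <- 1e-5
  for (nm in c("encL.conv1.W", "encR.conv3.W", "encL.bn2.gamma",
               "encL.pw.W", "att.LR.Wq", "att.RL.Wv", "clf.W1")) {
    i <- 1L
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4, label = nm)
  }
})
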