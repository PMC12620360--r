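# Subject-level folds, training behaviour, metrics, model comparison

test_that("32 subjects give 8 folds of 4 test / 24 train / 4 val subjects", {
  ids <- sprintf("S%02d", 1:32)
  folds <- makeSubjectFolds(ids, k = 8, seed = 42)
  expect_length(folds, 8L)
  for (f in folds) {
    expect_length(f$testSubjects, 4L)
    expect_length(f$trainSubjects, 24L)
    expect_length(f$valSubjects, 4L)
    expect_length(intersect(f$testSubjects, f$trainSubjects), 0L)
    expect_length(intersect(f$testSubjects, f$valSubjects), 0L)
    expect_length(intersect(f$trainSubjects, f$valSubjects), 0L)
  }
  # test sets partition the subjects
  allTest <- unlist(lapply(folds, `[[`, "testSubjects"))
  expect_equal(sort(allTest), ids)
  expect_equal(anyDuplicated(allTest), 0L)
  # deterministic in the seed
  expect_identical(folds, makeSubjectFolds(ids, k = 8, seed = 42))
  expect_false(identical(folds, makeSubjectFolds(ids, k = 8, seed = 1)))
  expect_error(makeSubjectFolds(ids[1:4], k = 8),
               class = "earstress_bad_config")
})

test_that("training configuration invariants are enforced", {
  expect_error(trainConfig(patience = 200, maxEpochs = 200),
               class = "earstress_bad_config")
  expect_error(trainConfig(batchTrain = 0), class = "earstress_bad_config")
})

test_that("zero learning rate leaves the model unchanged; losses stay constant", {
  eps <- strongEarEpochs(4)
  subs <- epochSubjects(eps)
  tr <- earstress:::subsetEpochs(eps, which(subs %in% c("S01", "S02", "S03")))
  va <- earstress:::subsetEpochs(eps, which(subs == "S04"))
  m <- buildModel(modelConfig(dropoutP = 0), seed = 9)
  res <- trainModel(m, tr, va, trainConfig(lr = 0, maxEpochs = 4,
                                           patience = 3, seed = 1))
  expect_equal(res$model$params, m$params, tolerance = 1e-12)
  # validation loss may drift minutely as batch-norm running statistics
  # accumulate, but with frozen parameters it must stay essentially flat
  expect_lt(diff(range(res$history$valLoss)), 0.02)
})

test_that("training reduces loss on strong-effect data and respects patience", {
  eps <- strongEarEpochs(8)
  folds <- makeSubjectFolds(epochSubjects(eps), k = 4, seed = 7)
  m <- buildModel(modelConfig(), seed = 7)
  res <- trainFold(m, folds[[1]], eps, trainConfig(maxEpochs = 8,
                                                   patience = 4, seed = 7))
  h <- res$history
  expect_lte(nrow(h), 8L)
  # overall downward trend in training loss over the run
  expect_lt(mean(tail(h$trainLoss, 3)), mean(head(h$trainLoss, 2)))
  expect_gte(res$bestEpoch, 1L)
  # early stopping: patience flat validation epochs halt training
  expect_lte(nrow(h), res$bestEpoch + 4L)
})

test_that("fold metrics match a confusion-matrix oracle", {
  # hand example: stress TP 3 FN 1, relax TN 4 FP 0
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  met <- earstress:::metricsFromPredictions(pred, y)
  expect_equal(met$accuracy, 7 / 8)
  expect_equal(met$macroF1, (0.857142857 + 0.888888889) / 2,
               tolerance = 1e-6)
  # all correct
  expect_equal(earstress:::metricsFromPredictions(y, y)$macroF1, 1)
  # constant predictor on a balanced set
  met0 <- earstress:::metricsFromPredictions(rep(0, 8), y)
  expect_equal(met0$accuracy, 0.5)
  expect_equal(met0$macroF1, (2 / 3 + 0) / 2)
  # random pairs vs an independent table-based computation
  set.seed(21)
  for (i in 1:25) {
    p <- sample(0:1, 30, replace = TRUE)
    t <- sample(0:1, 30, replace = TRUE)
    met <- earstress:::metricsFromPredictions(p, t)
    expect_equal(met$accuracy, mean(p == t))
    f1 <- sapply(0:1, function(cl) {
      tp <- sum(p == cl & t == cl)
      pr <- if (sum(p == cl)) tp / sum(p == cl) else 0
      rc <- if (sum(t == cl)) tp / sum(t == cl) else 0
      if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    })
    expect_equal(met$macroF1, mean(f1))
  }
})

test_that("no test subject leaks into training or validation batches", {
  eps <- strongEarEpochs(8)
  folds <- makeSubjectFolds(epochSubjects(eps), k = 4, seed = 3)
  for (f in folds) {
    trainIdx <- which(epochSubjects(eps) %in% f$trainSubjects)
    valIdx <- which(epochSubjects(eps) %in% f$valSubjects)
    expect_length(intersect(epochSubjects(eps)[c(trainIdx, valIdx)],
                            f$testSubjects), 0L)
    # every subject is used exactly once per fold
    expect_equal(sort(c(f$trainSubjects, f$valSubjects, f$testSubjects)),
                 sort(unique(epochSubjects(eps))))
  }
})

test_that("model comparison handles wins, structure and degenerate ties", {
  # strict winner on all 8 folds: two-sided exact p = 2/256
  a <- c(0.9, 0.85, 0.95, 0.88, 0.92, 0.9, 0.87, 0.93)
  b <- a - seq(0.10, 0.17, by = 0.01)   # distinct margins: tie-free exact test
  cmp <- compareModels(list(modelA = a, modelB = b))
  expect_equal(cmp$p, 2 / 256)
  # three comparisons give three q >= p
  cmp3 <- compareModels(list(ref = a, m1 = b, m2 = a - 0.02, m3 = a + 0.01))
  expect_equal(nrow(cmp3), 3L)
  expect_true(all(cmp3$q >= cmp3$p - 1e-12))
  # identical vectors surface as "no difference"
  cmpEq <- compareModels(list(ref = a, same = a))
  expect_true(cmpEq$noDifference)
  expect_true(is.na(cmpEq$p))
})
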