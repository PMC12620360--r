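#' Read a pipeline run configuration
#'
#' YAML file with optional sections `generator` (nSubjects, duration,
#' effects preset name or explicit gains, subjectSd), `preprocess` (low,
#' high, order, notch, targetFs), `model` (variant, shareStreams, ...),
#' `train` (lr, maxEpochs, patience, batchTrain, ...), `crossval` (k,
#' variants), and top-level `seed`, `outDir`. Unknown keys are rejected.
#'
#' @param path YAML config path; `NULL` gives the defaults.
#' @param overrides named list merged over the file values.
#' @return list of class `earstress_runconfig`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("generator", "preprocess", "model", "train", "crossval",
             "explain", "seed", "outDir", "logLevel")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stopTyped("earstress_bad_config", "unknown config keys: %s",
              paste(bad, collapse = ", "))
  for (nm in names(overrides)) raw[[nm]] <- overrides[[nm]]
  raw$seed <- as.integer(raw$seed %||% 42L)
  raw$outDir <- raw$outDir %||% "earstress-run"
  raw$generator <- raw$generator %||% list()
  raw$preprocess <- raw$preprocess %||% list()
  raw$model <- raw$model %||% list()
  raw$train <- raw$train %||% list()
  raw$crossval <- raw$crossval %||% list()
  raw$explain <- raw$explain %||% list()
  class(raw) <- "earstress_runconfig"
  raw
}

rcGenConfig <- function(rc) {
  g <- rc$generator
  eff <- g$effects %||% "default"
  effects <- if (is.character(eff)) {
    switch(eff, default = effectSizes(), null = nullEffectSizes(),
           strong = strongEffectSizes(),
           stopTyped("earstress_bad_config", "unknown effects preset '%s'", eff))
  } else do.call(effectSizes, eff)
  generatorConfig(nSubjects = g$nSubjects %||% 32L,
                  fsRaw = g$fsRaw %||% 500,
                  duration = g$duration %||% 60,
                  noiseExponent = g$noiseExponent %||% 1.0,
                  effects = effects,
                  subjectSd = g$subjectSd %||% 0.4,
                  seed = rc$seed)
}

writeReproRecord <- function(rc, dir, stage) {
  rec <- list(stage = stage, seed = rc$seed,
              config = unclass(rc),
              package = as.character(packageVersion("earstress")),
              rVersion = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file.path(dir, sprintf("repro-%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic dataset + manifest), `preprocess`
#' (filter/decimate a manifest of recordings and write the result),
#' `validate` (markers + paired statistics TSV), `train` (train one
#' variant on a single subject-level fold, writing metrics and the
#' per-epoch loss log), `crossval` (subject-level CV of one or more
#' variants, summary TSV), `explain` (attention/occlusion delta summaries
#' TSV), `report` (collate the stage outputs into one JSON bundle).
#' Every stage rewrites its outputs
#' deterministically and drops a reproducibility record (config snapshot,
#' seed, package version) beside them.
#'
#' @param command stage name.
#' @param config an `earstress_runconfig` (see [readRunConfig()]).
#' @return invisibly, a list of produced artifact paths.
#' @export
dispatch <- function(command, config = readRunConfig()) {
  commands <- c("simulate", "preprocess", "validate", "train", "crossval",
                "explain", "report")
  if (!command %in% commands)
    stopTyped("earstress_bad_command", "unknown command '%s' (use one of %s)",
              command, paste(commands, collapse = ", "))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(command,
    simulate = stageSimulate(config),
    preprocess = stagePreprocess(config),
    validate = stageValidate(config),
    train = stageTrain(config),
    crossval = stageCrossval(config),
    explain = stageExplain(config),
    report = stageReport(config))
  writeReproRecord(config, config$outDir, command)
  invisible(out)
}

stageDir <- function(rc, sub) {
  d <- file.path(rc$outDir, sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

stageSimulate <- function(rc) {
  recs <- generatePairedDataset(rcGenConfig(rc))
  man <- writeDataset(recs, stageDir(rc, "raw"))
  list(manifest = file.path(rc$outDir, "raw", "manifest.tsv"),
       n = nrow(man))
}

loadPreprocessed <- function(rc) {
  pp <- rc$preprocess
  rawMan <- file.path(rc$outDir, "raw", "manifest.tsv")
  recs <- if (file.exists(rawMan)) readDataset(rawMan)
          else generatePairedDataset(rcGenConfig(rc))
  lapply(recs, preprocessRecording,
         low = pp$low %||% 1, high = pp$high %||% 40,
         order = pp$order %||% 6, notch = pp$notch %||% 60,
         targetFs = pp$targetFs %||% 125)
}

stagePreprocess <- function(rc) {
  man <- writeDataset(loadPreprocessed(rc), stageDir(rc, "preprocessed"))
  list(manifest = file.path(rc$outDir, "preprocessed", "manifest.tsv"),
       n = nrow(man))
}

loadEpochs <- function(rc) {
  ppMan <- file.path(rc$outDir, "preprocessed", "manifest.tsv")
  recs <- if (file.exists(ppMan)) readDataset(ppMan) else loadPreprocessed(rc)
  extractEpochs(recs, epochS = rc$preprocess$epochS %||%
                  min(60, rc$generator$duration %||% 60))
}

stageValidate <- function(rc) {
  res <- validateParadigm(computeMarkers(loadEpochs(rc)))
  path <- file.path(rc$outDir, "validation.tsv")
  writeValidationReport(res, path)
  list(report = path, nSignificant = sum(res$significant))
}

rcModelConfig <- function(rc) do.call(modelConfig, rc$model)

stageTrain <- function(rc) {
  epochs <- loadEpochs(rc)
  k <- rc$crossval$k %||% 8L
  folds <- makeSubjectFolds(epochSubjects(epochs), k = k, seed = rc$seed)
  variant <- (rc$crossval$variants %||% "full")[1]
  model <- buildVariant(rcModelConfig(rc), variant,
                        seed = subSeed(rc$seed, "init", 1L))
  tr <- trainFold(model, folds[[1]], epochs, rcTrainConfig(rc))
  ev <- evaluateFold(tr$model,
                     subsetEpochs(epochs, which(epochSubjects(epochs) %in%
                                                  folds[[1]]$testSubjects)))
  histPath <- file.path(rc$outDir, "train-history.tsv")
  data.table::fwrite(tr$history, histPath, sep = "\t")
  metPath <- file.path(rc$outDir, "train-metrics.tsv")
  data.table::fwrite(data.frame(variant = variant, fold = 1L,
                                accuracy = ev$accuracy, macroF1 = ev$macroF1,
                                epochsTrained = tr$epochsTrained), metPath,
                     sep = "\t")
  list(history = histPath, metrics = metPath)
}

rcTrainConfig <- function(rc) {
  tc <- rc$train
  tc$seed <- tc$seed %||% rc$seed
  do.call(trainConfig, tc)
}

stageCrossval <- function(rc) {
  epochs <- loadEpochs(rc)
  variants <- rc$crossval$variants %||% "full"
  k <- rc$crossval$k %||% 8L
  rows <- list()
  cvs <- list()
  for (v in variants) {
    cv <- runCrossValidation(epochs, variant = v,
                             modelCfg = rcModelConfig(rc),
                             trainCfg = rcTrainConfig(rc), k = k,
                             seed = rc$seed)
    s <- cv$summary
    rows[[v]] <- data.frame(variant = v, metric = s$metric, mean = s$mean,
                            sd = s$sd)
    cvs[[v]] <- cv
    data.table::fwrite(cv$perFold,
                       file.path(rc$outDir, sprintf("folds-%s.tsv", v)),
                       sep = "\t")
  }
  path <- file.path(rc$outDir, "crossval-summary.tsv")
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  saveRDS(cvs, file.path(rc$outDir, "crossval-models.rds"))
  list(summary = path)
}

stageExplain <- function(rc) {
  modelsPath <- file.path(rc$outDir, "crossval-models.rds")
  if (!file.exists(modelsPath))
    stopTyped("earstress_bad_config",
              "run the crossval stage before explain (missing %s)", modelsPath)
  cvs <- readRDS(modelsPath)
  cv <- cvs[[intersect(c("full", names(cvs)), names(cvs))[1]]]
  ex <- explainCrossValidation(cv, loadEpochs(rc),
                               occlusion = rc$explain$occlusion %||% TRUE,
                               occlusionStepS = rc$explain$stepS %||% 0.1)
  attPath <- file.path(rc$outDir, "explain-attention.tsv")
  data.table::fwrite(ex$attention$perFold, attPath, sep = "\t")
  occPath <- file.path(rc$outDir, "explain-occlusion.tsv")
  data.table::fwrite(ex$occlusion$perFold, occPath, sep = "\t")
  list(attention = attPath, occlusion = occPath)
}

stageReport <- function(rc) {
  collect <- function(path) if (file.exists(path))
    as.data.frame(data.table::fread(path, sep = "\t")) else NULL
  bundle <- list(
    validation = collect(file.path(rc$outDir, "validation.tsv")),
    crossval = collect(file.path(rc$outDir, "crossval-summary.tsv")),
    attention = collect(file.path(rc$outDir, "explain-attention.tsv")),
    occlusion = collect(file.path(rc$outDir, "explain-occlusion.tsv")),
    seed = rc$seed)
  path <- file.path(rc$outDir, "report.json")
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(report = path)
}

#' Run a sequence of pipeline stages
#'
#' @param commands character vector of stage names, executed in order.
#' @param config an `earstress_runconfig`.
#' @return invisibly, a named list of per-stage artifact lists.
#' @export
runPipeline <- function(commands, config = readRunConfig()) {
  out <- lapply(commands, dispatch, config = config)
  names(out) <- commands
  invisible(out)
}
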