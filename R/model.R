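MODEL_VARIANTS <- c("full", "no_cross_attention", "no_pointwise", "no_both",
                    "self_attention", "lightweight_transformer")

#' Model configuration
#'
#' Pinned architecture: four per-stream temporal blocks
#' (1-D convolution -> batch norm -> ELU, average pooling after blocks
#' 1-3) with kernel lengths decreasing 125 -> 20 samples; pooling
#' (5, 6, 7) reduces the 7500-sample input to 35 token positions; a 1x1
#' pointwise convolution compresses each stream to one feature map whose
#' 35 scalar tokens are lifted to `attentionDk`-dimensional queries/keys
#' and `attentionDv`-dimensional values for the two directional
#' cross-attention modules; the attended features are concatenated into
#' the shallow classifier (dense -> batch norm -> ELU -> dropout -> dense).
#'
#' @param kernelLengths conv kernel lengths in samples, strictly
#'   decreasing from 125 to 20.
#' @param filters feature maps per block.
#' @param pool (length, stride) pairs for blocks 1-3 (length = stride,
#'   non-overlapping).
#' @param attentionDk query/key dimension.
#' @param attentionDv value dimension.
#' @param hiddenDim classifier hidden width.
#' @param dropoutP classifier dropout probability.
#' @param shareStreams share encoder weights between the two ear streams.
#' @param variant one of full, no_cross_attention, no_pointwise, no_both,
#'   self_attention, lightweight_transformer.
#' @param inputLength samples per epoch (60 s at 125 Hz).
#' @param selfAttDim embedding width of the self-attention ablation.
#' @param trDim,trHeads,trFfnDim embedding width, head count and
#'   feed-forward width of the lightweight-transformer ablation.
#' @return a list of class `earstress_modelconfig`.
#' @export
modelConfig <- function(kernelLengths = c(125, 63, 31, 20),
                        filters = c(8, 16, 16, 32),
                        pool = list(c(5, 5), c(6, 6), c(7, 7)),
                        attentionDk = 8, attentionDv = 1,
                        hiddenDim = 64, dropoutP = 0.5,
                        shareStreams = FALSE, variant = "full",
                        inputLength = 7500,
                        selfAttDim = 64, trDim = 64, trHeads = 2,
                        trFfnDim = 128) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (length(kernelLengths) != 4L || any(diff(kernelLengths) >= 0) ||
      kernelLengths[1] != 125 || kernelLengths[4] != 20)
    stopTyped("earstress_bad_architecture",
              "kernel lengths must decrease strictly from 125 to 20 samples")
  if (attentionDk < 1 || attentionDv < 1)
    stopTyped("earstress_bad_architecture", "attention dims must be >= 1")
  cfg <- list(kernelLengths = as.integer(kernelLengths),
              filters = as.integer(filters), pool = pool,
              attentionDk = as.integer(attentionDk),
              attentionDv = as.integer(attentionDv),
              hiddenDim = as.integer(hiddenDim), dropoutP = dropoutP,
              shareStreams = isTRUE(shareStreams), variant = variant,
              inputLength = as.integer(inputLength),
              selfAttDim = as.integer(selfAttDim), trDim = as.integer(trDim),
              trHeads = as.integer(trHeads), trFfnDim = as.integer(trFfnDim))
  class(cfg) <- "earstress_modelconfig"
  cfg
}

# token positions after the three pooling stages (floor division)
tokenCount <- function(cfg) {
  T <- cfg$inputLength
  for (p in cfg$pool) T <- T %/% p[2]
  T
}

usesPointwise <- function(variant) variant %in%
  c("full", "no_cross_attention", "self_attention", "lightweight_transformer")

usesCrossAttention <- function(variant) variant %in% c("full", "no_pointwise")

# classifier input width per variant
fusedDim <- function(cfg) {
  Tp <- tokenCount(cfg)
  switch(cfg$variant,
    full = ,
    no_pointwise = 2L * Tp * cfg$attentionDv,
    no_cross_attention = ,
    no_both = 2L * Tp,
    self_attention = 2L * cfg$selfAttDim,
    lightweight_transformer = cfg$trDim)
}

# ordered parameter specification; initialization follows this order so a
# fixed seed yields identical parameters
paramSpec <- function(cfg) {
  spec <- list()
  add <- function(name, dims, fanIn) {
    spec[[length(spec) + 1L]] <<- list(name = name, dims = dims, fanIn = fanIn)
  }
  prefixes <- if (cfg$shareStreams) "enc" else c("encL", "encR")
  for (pfx in prefixes) {
    cin <- 1L
    for (i in 1:4) {
      k <- cfg$kernelLengths[i]; cout <- cfg$filters[i]
      add(sprintf("%s.conv%d.W", pfx, i), c(k * cin, cout), k * cin)
      add(sprintf("%s.conv%d.b", pfx, i), cout, k * cin)
      add(sprintf("%s.bn%d.gamma", pfx, i), cout, NA)
      add(sprintf("%s.bn%d.beta", pfx, i), cout, NA)
      cin <- cout
    }
    if (usesPointwise(cfg$variant)) {
      add(sprintf("%s.pw.W", pfx), c(cfg$filters[4], 1L), cfg$filters[4])
      add(sprintf("%s.pw.b", pfx), 1L, cfg$filters[4])
    }
  }
  if (usesCrossAttention(cfg$variant)) {
    for (d in c("LR", "RL")) {
      add(sprintf("att.%s.Wq", d), c(1L, cfg$attentionDk), 1L)
      add(sprintf("att.%s.bq", d), cfg$attentionDk, 1L)
      add(sprintf("att.%s.Wk", d), c(1L, cfg$attentionDk), 1L)
      add(sprintf("att.%s.bk", d), cfg$attentionDk, 1L)
      add(sprintf("att.%s.Wv", d), c(1L, cfg$attentionDv), 1L)
      add(sprintf("att.%s.bv", d), cfg$attentionDv, 1L)
    }
  }
  if (cfg$variant == "self_attention") {
    D <- cfg$selfAttDim
    add("sa.embed.W", c(1L, D), 1L); add("sa.embed.b", D, 1L)
    for (nm in c("Wq", "Wk", "Wv")) add(paste0("sa.", nm), c(D, D), D)
    for (nm in c("bq", "bk", "bv")) add(paste0("sa.", nm), D, D)
  }
  if (cfg$variant == "lightweight_transformer") {
    D <- cfg$trDim; Tp <- tokenCount(cfg)
    add("tr.embed.W", c(1L, D), 1L); add("tr.embed.b", D, 1L)
    add("tr.pos", c(2L * Tp, D), D)
    add("tr.chan", c(2L, D), D)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) add(paste0("tr.", nm), c(D, D), D)
    for (nm in c("bq", "bk", "bv", "bo")) add(paste0("tr.", nm), D, D)
    add("tr.ln1.gamma", D, NA); add("tr.ln1.beta", D, NA)
    add("tr.ffn.W1", c(D, cfg$trFfnDim), D)
    add("tr.ffn.b1", cfg$trFfnDim, D)
    add("tr.ffn.W2", c(cfg$trFfnDim, D), cfg$trFfnDim)
    add("tr.ffn.b2", D, cfg$trFfnDim)
    add("tr.ln2.gamma", D, NA); add("tr.ln2.beta", D, NA)
  }
  din <- fusedDim(cfg)
  add("clf.W1", c(din, cfg$hiddenDim), din)
  add("clf.b1", cfg$hiddenDim, din)
  add("clf.bn.gamma", cfg$hiddenDim, NA)
  add("clf.bn.beta", cfg$hiddenDim, NA)
  add("clf.W2", c(cfg$hiddenDim, 2L), cfg$hiddenDim)
  add("clf.b2", 2L, cfg$hiddenDim)
  spec
}

#' Build the classifier
#'
#' Initializes all parameters deterministically from `seed` (uniform
#' He-style bounds `1/sqrt(fan_in)`; norm scales 1, shifts 0; the
#' transformer positional/channel embeddings N(0, 0.02)).
#'
#' @param config a [modelConfig()].
#' @param seed integer initialization seed.
#' @return a model object of class `earstressModel`.
#' @export
buildModel <- function(config, seed = 42L) {
  stopifnot(inherits(config, "earstress_modelconfig"))
  Tp <- tokenCount(config)
  if (Tp != 35L)
    stopTyped("earstress_bad_architecture",
              "pooling yields %d token positions; the architecture requires 35",
              Tp)
  spec <- paramSpec(config)
  params <- withSeed(seed, {
    out <- list()
    for (s in spec) {
      nm <- s$name
      if (grepl("gamma$", nm)) {
        v <- rep(1, prod(s$dims))
      } else if (grepl("beta$", nm)) {
        v <- rep(0, prod(s$dims))
      } else if (nm %in% c("tr.pos", "tr.chan")) {
        v <- rnorm(prod(s$dims), 0, 0.02)
      } else {
        bound <- 1 / sqrt(s$fanIn)
        v <- runif(prod(s$dims), -bound, bound)
      }
      out[[nm]] <- if (length(s$dims) > 1L) matrix(v, s$dims[1], s$dims[2])
                   else v
    }
    out
  })
  bnState <- list()
  for (nm in names(params)) {
    if (grepl("\\.bn.*\\.gamma$", nm)) {
      layer <- sub("\\.gamma$", "", nm)
      bnState[[layer]] <- list(mean = rep(0, length(params[[nm]])),
                               var = rep(1, length(params[[nm]])))
    }
  }
  structure(list(config = config, variant = config$variant, params = params,
                 bnState = bnState, tokens = Tp,
                 classes = c("relax", "stress")),
            class = "earstressModel")
}

#' Build a named architecture variant
#'
#' `no_cross_attention` concatenates the two compressed token streams
#' directly; `no_pointwise` replaces the learned 1x1 compression with a
#' parameter-free mean over feature maps at each time bin (token count
#' stays 35); `no_both` combines the two removals; `self_attention`
#' applies shared within-stream single-head self-attention with temporal
#' averaging; `lightweight_transformer` concatenates the token streams,
#' adds positional and channel embeddings, and applies a single two-head
#' transformer encoder layer.
#'
#' @param config a [modelConfig()] (its `variant` field is overridden).
#' @param variant variant name.
#' @param seed initialization seed.
#' @return an `earstressModel`.
#' @export
buildVariant <- function(config, variant, seed = 42L) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  config$variant <- variant
  buildModel(config, seed = seed)
}

#' Total trainable parameter count
#' @param model an `earstressModel`.
#' @return integer number of trainable parameters.
#' @export
parameterCount <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Print a layer/parameter summary
#' @param model an `earstressModel`.
#' @export
describeModel <- function(model) {
  cat(sprintf("earstressModel variant '%s' | %d tokens/stream | %d parameters\n",
              model$variant, model$tokens, parameterCount(model)))
  nm <- names(model$params)
  dims <- vapply(model$params, function(p)
    paste(dim(p) %||% length(p), collapse = "x"), character(1))
  cnt <- vapply(model$params, length, integer(1))
  for (i in seq_along(nm))
    cat(sprintf("  %-18s %10s %8d\n", nm[i], dims[i], cnt[i]))
  invisible(model)
}

#' @export
print.earstressModel <- function(x, ...) {
  cat(sprintf(
    "earstressModel: variant '%s', %d trainable parameters, %d tokens/stream\n",
    x$variant, parameterCount(x), x$tokens))
  invisible(x)
}

# encoder stream prefix for a side ("L"/"R")
encPrefix <- function(model, side) {
  if (model$config$shareStreams) "enc" else paste0("enc", side)
}
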