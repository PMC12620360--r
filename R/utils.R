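#' @useDynLib earstress, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif fft sd var median p.adjust psignrank
#' @importFrom utils head tail packageVersion
NULL

# Typed condition helper: every user-facing failure carries a class that tests
# and callers can match on (e.g. "earstress_missing_channel").
stopTyped <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "earstress_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Deterministic substream seed
#'
#' Maps a root seed plus an arbitrary sequence of string keys to a
#' reproducible integer seed in `[0, 2^31 - 2]`. Used so that every random
#' component of the synthetic generator (subject, condition, signal
#' component) draws from its own independent substream: adding a new
#' component never perturbs the draws of existing ones.
#'
#' @param seed integer root seed.
#' @param ... character or numeric keys identifying the substream.
#' @return a single integer seed.
#' @export
subSeed <- function(seed, ...) {
  keys <- paste(vapply(list(...), as.character, character(1)), collapse = "\x1f")
  bytes <- utf8ToInt(keys)
  # 32-bit-safe polynomial rolling hash in double arithmetic
  h <- (as.numeric(seed) %% 2147483647)
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded from `seed`; the caller's
# RNG state is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# trapezoidal integral over a uniform or non-uniform grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
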