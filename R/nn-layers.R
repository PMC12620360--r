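# Neural-network primitives.
#
# Activations are (N*T) x C matrices in sample-major row blocks (rows 1..T
# belong to sample 1); `T` is carried alongside. Every layer comes as a
# forward returning (out, cache) and a backward mapping (dOut, cache) to
# input/parameter gradients. Convolutions run through the compiled
# im2col/GEMM kernels.

convFw <- function(x, W, b, T, k, padLeft) {
  cpp_conv1d_fw(x, W, b, T, k, padLeft)
}

convBw <- function(x, W, dy, T, k, padLeft) {
  g <- cpp_conv1d_bw(x, W, dy, T, k, padLeft)
  g$db <- as.vector(g$db)
  g
}

# Batch normalization over rows (i.e. across batch and time), per channel.
# Training mode uses batch statistics and updates running estimates
# (momentum 0.1, unbiased running variance); evaluation mode uses the
# running estimates, which makes inference batch-size invariant.
bnFw <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    R <- nrow(x)
    f <- cpp_bn_fw_train(x, gamma, beta, eps)
    state$mean <- (1 - momentum) * state$mean + momentum * as.vector(f$mean)
    state$var <- (1 - momentum) * state$var +
      momentum * as.vector(f$var) * R / max(1, R - 1)
    cache <- list(xhat = f$xhat, invstd = as.vector(f$invstd), gamma = gamma)
    y <- f$y
  } else {
    y <- cpp_bn_fw_eval(x, gamma, beta, state$mean, state$var, eps)
    cache <- NULL
  }
  list(y = y, cache = cache, state = state)
}

bnBw <- function(dy, cache) {
  g <- cpp_bn_bw(dy, cache$xhat, cache$invstd, cache$gamma)
  list(dx = g$dx, dgamma = as.vector(g$dgamma), dbeta = as.vector(g$dbeta))
}

# ELU with alpha = 1; backward uses the cached output (slope is y + 1 on
# the negative branch).
eluFw <- function(x) cpp_elu_fw(x)

eluBw <- function(dy, y) cpp_elu_bw(dy, y)

# Non-overlapping average pooling (length = stride = p) along time; trailing
# samples that do not fill a window are dropped (floor division).
poolFw <- function(x, T, p) cpp_pool_fw(x, T, as.integer(p))

poolBwDims <- function(dy, T, Tp, p) {
  cpp_pool_bw(dy, as.integer(T), as.integer(Tp), as.integer(p))
}

denseFw <- function(x, W, b) sweep(x %*% W, 2, b, `+`)

denseBw <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

dropoutFw <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}

rowSoftmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Scaled dot-product cross-attention
#'
#' `softmax(Q K' / sqrt(dk)) V` with a row-wise softmax, so the returned
#' map is row-stochastic: entry (i, j) is the weight the query at time bin
#' i assigns to the key at time bin j.
#'
#' @param Q queries, `T' x dk`.
#' @param K keys, `T' x dk`.
#' @param V values, `T' x dv`.
#' @return list with `attended` (`T' x dv`) and `map` (`T' x T'`
#'   row-stochastic attention weights).
#' @export
crossAttention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    stopTyped("earstress_shape_error",
              "Q/K must share dk and K/V must share rows")
  A <- rowSoftmax(Q %*% t(K) / sqrt(ncol(Q)))
  list(attended = A %*% V, map = A)
}

# backward through crossAttention; A is the cached map
attnBw <- function(dO, Q, K, V, A) {
  dV <- crossprod(A, dO)
  dA <- dO %*% t(V)
  dS <- A * (dA - rowSums(dA * A))
  scale <- 1 / sqrt(ncol(Q))
  list(dQ = dS %*% K * scale, dK = crossprod(dS, Q) * scale, dV = dV)
}

# row-wise layer normalization (transformer variant)
lnFw <- function(x, gamma, beta, eps = 1e-5) {
  m <- rowMeans(x)
  xc <- x - m
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  list(y = sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

lnBw <- function(dy, cache) {
  D <- ncol(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$invstd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# mean cross-entropy on logits; labels are 0/1 class indices
softmaxCrossEntropy <- function(logits, labels) {
  dimnames(logits) <- NULL
  P <- rowSoftmax(logits)
  idx <- cbind(seq_len(nrow(P)), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / nrow(P))
}

# ---- AdamW ---------------------------------------------------------------

adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay applied to weight matrices only (batch-norm /
# layer-norm scales and biases excluded, the usual convention).
adamwStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weightDecay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (decayedParam(nm)) step <- step + weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, state = state)
}

decayedParam <- function(nm) {
  grepl("\\.W[a-z0-9]*$", nm) && !grepl("(gamma|beta|\\.b[a-z0-9]*$)", nm)
}
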