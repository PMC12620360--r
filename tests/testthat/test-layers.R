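# Layer primitives against numeric-gradient and brute-force oracles

numGrad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("conv1d forward matches a naive double-loop oracle", {
  set.seed(1)
  T <- 20L; k <- 5L; Cin <- 3L; Cout <- 2L; N <- 2L
  pad <- (k - 1L) %/% 2L
  x <- matrix(rnorm(N * T * Cin), N * T, Cin)
  W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
  b <- rnorm(Cout)
  y <- earstress:::convFw(x, W, b, T, k, pad)
  # naive evaluation
  yo <- matrix(0, N * T, Cout)
  for (n in 1:N) for (t in 1:T) for (o in 1:Cout) {
    acc <- b[o]
    for (c in 1:Cin) for (j in 0:(k - 1)) {
      ti <- t + j - pad
      if (ti >= 1 && ti <= T)
        acc <- acc + x[(n - 1) * T + ti, c] * W[(c - 1) * k + j + 1, o]
    }
    yo[(n - 1) * T + t, o] <- acc
  }
  expect_equal(y, yo, tolerance = 1e-12)
})

test_that("conv1d backward matches numeric gradients", {
  set.seed(2)
  T <- 12L; k <- 4L; Cin <- 2L; Cout <- 3L; N <- 2L
  pad <- (k - 1L) %/% 2L
  x <- matrix(rnorm(N * T * Cin), N * T, Cin)
  W <- matrix(rnorm(k * Cin * Cout), k * Cin, Cout)
  b <- rnorm(Cout)
  dy <- matrix(rnorm(N * T * Cout), N * T, Cout)
  g <- earstress:::convBw(x, W, dy, T, k, pad)
  loss <- function(xx, WW, bb) sum(earstress:::convFw(xx, WW, bb, T, k, pad) * dy)
  expect_equal(g$dX, numGrad(function(v) loss(v, W, b), x), tolerance = 1e-6)
  expect_equal(g$dW, numGrad(function(v) loss(x, v, b), W), tolerance = 1e-6)
  expect_equal(g$db, as.vector(numGrad(function(v) loss(x, W, v), b)),
               tolerance = 1e-6)
})

test_that("batch norm, ELU, pooling and layer norm backward match numeric gradients", {
  set.seed(3)
  x <- matrix(rnorm(40), 10, 4)
  gamma <- runif(4, 0.5, 1.5); beta <- rnorm(4)
  dy <- matrix(rnorm(40), 10, 4)
  st <- list(mean = rep(0, 4), var = rep(1, 4))
  fw <- earstress:::bnFw(x, gamma, beta, st, training = TRUE)
  bw <- earstress:::bnBw(dy, fw$cache)
  lossBn <- function(xx) sum(earstress:::bnFw(xx, gamma, beta, st, TRUE)$y * dy)
  expect_equal(bw$dx, numGrad(lossBn, x), tolerance = 1e-5)
  expect_equal(bw$dgamma,
               as.vector(numGrad(function(v)
                 sum(earstress:::bnFw(x, v, beta, st, TRUE)$y * dy), gamma)),
               tolerance = 1e-6)

  y <- earstress:::eluFw(x)
  expect_equal(earstress:::eluBw(dy, y),
               numGrad(function(v) sum(earstress:::eluFw(v) * dy), x),
               tolerance = 1e-6)

  T <- 12L; p <- 5L # deliberately non-divisible: floor(12/5) = 2 windows
  xp <- matrix(rnorm(2 * T * 3), 2 * T, 3)
  Tp <- T %/% p
  dyp <- matrix(rnorm(2 * Tp * 3), 2 * Tp, 3)
  yp <- earstress:::poolFw(xp, T, p)
  expect_equal(nrow(yp), 2L * Tp)
  expect_equal(yp[1, 1], mean(xp[1:5, 1]))
  expect_equal(earstress:::poolBwDims(dyp, T, Tp, p),
               numGrad(function(v) sum(earstress:::poolFw(v, T, p) * dyp), xp),
               tolerance = 1e-6)

  ln <- earstress:::lnFw(x, gamma, beta)
  lb <- earstress:::lnBw(dy, ln$cache)
  expect_equal(lb$dx,
               numGrad(function(v) sum(earstress:::lnFw(v, gamma, beta)$y * dy), x),
               tolerance = 1e-5)
})

test_that("cross-attention matches the brute-force formula and degenerate cases", {
  set.seed(4)
  # T' = 1: softmax of a scalar is 1, attended = V
  r1 <- crossAttention(matrix(2, 1, 3), matrix(1, 1, 3), matrix(5, 1, 2))
  expect_equal(r1$map, matrix(1, 1, 1))
  expect_equal(r1$attended, matrix(5, 1, 2))
  # identical keys -> uniform rows, attended = column means of V
  Q <- matrix(rnorm(15), 5, 3)
  K <- matrix(rep(rnorm(3), each = 5), 5, 3)
  V <- matrix(rnorm(10), 5, 2)
  r2 <- crossAttention(Q, K, V)
  expect_equal(r2$map, matrix(1 / 5, 5, 5))
  expect_equal(r2$attended,
               matrix(rep(colMeans(V), each = 5), 5, 2), tolerance = 1e-12)
  # random shapes vs naive double-loop evaluation
  Q <- matrix(rnorm(15), 5, 3); K <- matrix(rnorm(15), 5, 3)
  V <- matrix(rnorm(10), 5, 2)
  r3 <- crossAttention(Q, K, V)
  S <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(3)
  A <- matrix(0, 5, 5)
  for (i in 1:5) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  expect_equal(r3$map, A, tolerance = 1e-6)
  expect_equal(r3$attended, A %*% V, tolerance = 1e-6)
  expect_error(crossAttention(Q, K[, 1:2], V), class = "earstress_shape_error")
})

test_that("attention rows are stochastic over many random inputs", {
  set.seed(6)
  worst <- 0
  for (i in 1:1000) {
    Tn <- sample(2:8, 1); dk <- sample(1:4, 1)
    r <- crossAttention(matrix(rnorm(Tn * dk, sd = 3), Tn),
                        matrix(rnorm(Tn * dk, sd = 3), Tn),
                        matrix(rnorm(Tn), Tn, 1))
    worst <- max(worst, max(abs(rowSums(r$map) - 1)), -min(r$map))
  }
  expect_lt(worst, 1e-6)
})

test_that("attention backward matches numeric gradients", {
  set.seed(7)
  Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(12), 4, 3)
  V <- matrix(rnorm(8), 4, 2)
  dO <- matrix(rnorm(8), 4, 2)
  A <- crossAttention(Q, K, V)$map
  g <- earstress:::attnBw(dO, Q, K, V, A)
  loss <- function(QQ, KK, VV) sum(crossAttention(QQ, KK, VV)$attended * dO)
  expect_equal(g$dQ, numGrad(function(v) loss(v, K, V), Q), tolerance = 1e-5)
  expect_equal(g$dK, numGrad(function(v) loss(Q, v, V), K), tolerance = 1e-5)
  expect_equal(g$dV, numGrad(function(v) loss(Q, K, v), V), tolerance = 1e-5)
})

test_that("AdamW with zero learning rate leaves parameters unchanged", {
  set.seed(8)
  params <- list(a.W = matrix(rnorm(4), 2), b.b = rnorm(3))
  st <- earstress:::adamwInit(params)
  grads <- list(a.W = matrix(rnorm(4), 2), b.b = rnorm(3))
  upd <- earstress:::adamwStep(params, grads, st, lr = 0)
  expect_equal(upd$params, params)
  # and a positive lr moves against the gradient for a fresh state
  upd2 <- earstress:::adamwStep(params, grads, st, lr = 0.1,
                                weightDecay = 0)
  expect_true(all(sign(unlist(params) - unlist(upd2$params)) ==
                  sign(unlist(grads))))
})
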