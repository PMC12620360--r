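# Forward and backward passes for all architecture variants.
#
# `forwardModel` maps a (N, 2, T0) input batch to (N, 2) logits, optionally
# keeping layer caches for `backwardModel` (manual reverse-mode chain) and
# the per-sample row-stochastic attention maps.

# convert a (N, 2, T0) array into the two per-stream (N*T0) x 1 matrices
batchToStreams <- function(X) {
  N <- dim(X)[1]
  list(L = matrix(as.vector(t(X[, 1, , drop = TRUE])), ncol = 1),
       R = matrix(as.vector(t(X[, 2, , drop = TRUE])), ncol = 1),
       N = N)
}

encodeStream <- function(model, x, side, training) {
  cfg <- model$config
  P <- model$params
  pfx <- encPrefix(model, side)
  bnS <- model$bnState
  T <- cfg$inputLength
  blocks <- vector("list", 4L)
  for (i in 1:4) {
    k <- cfg$kernelLengths[i]
    pad <- (k - 1L) %/% 2L
    Wn <- sprintf("%s.conv%d.W", pfx, i)
    bn <- sprintf("%s.bn%d", pfx, i)
    z <- convFw(x, P[[Wn]], P[[sprintf("%s.conv%d.b", pfx, i)]], T, k, pad)
    bnRes <- bnFw(z, P[[paste0(bn, ".gamma")]], P[[paste0(bn, ".beta")]],
                  bnS[[bn]], training)
    bnS[[bn]] <- bnRes$state
    a <- eluFw(bnRes$y)
    if (i <= 3L) {
      p <- cfg$pool[[i]][2]
      Tp <- T %/% p
      y <- poolFw(a, T, p)
    } else {
      p <- NA_integer_; Tp <- T; y <- a
    }
    blocks[[i]] <- list(xin = x, T = T, k = k, pad = pad,
                        bnCache = bnRes$cache, eluOut = a, p = p, Tp = Tp)
    x <- y
    T <- Tp
  }
  # token compression: learned pointwise conv or parameter-free channel mean
  if (usesPointwise(cfg$variant)) {
    tokens <- denseFw(x, P[[paste0(pfx, ".pw.W")]], P[[paste0(pfx, ".pw.b")]])
  } else {
    tokens <- matrix(rowMeans(x), ncol = 1)
  }
  list(tokens = tokens, blocks = blocks, b4out = x, bnState = bnS, pfx = pfx)
}

backpropStream <- function(model, enc, dTokens, addGrad) {
  cfg <- model$config
  P <- model$params
  pfx <- enc$pfx
  if (usesPointwise(cfg$variant)) {
    g <- denseBw(enc$b4out, P[[paste0(pfx, ".pw.W")]], dTokens)
    addGrad(paste0(pfx, ".pw.W"), g$dW)
    addGrad(paste0(pfx, ".pw.b"), g$db)
    dx <- g$dx
  } else {
    C <- ncol(enc$b4out)
    dx <- matrix(dTokens, nrow(enc$b4out), C) / C
  }
  for (i in 4:1) {
    blk <- enc$blocks[[i]]
    if (i <= 3L) dx <- poolBwDims(dx, blk$T, blk$Tp, blk$p)
    dx <- eluBw(dx, blk$eluOut)
    bn <- sprintf("%s.bn%d", pfx, i)
    bg <- bnBw(dx, blk$bnCache)
    addGrad(paste0(bn, ".gamma"), bg$dgamma)
    addGrad(paste0(bn, ".beta"), bg$dbeta)
    Wn <- sprintf("%s.conv%d.W", pfx, i)
    cg <- convBw(blk$xin, P[[Wn]], bg$dx, blk$T, blk$k, blk$pad)
    addGrad(Wn, cg$dW)
    addGrad(sprintf("%s.conv%d.b", pfx, i), cg$db)
    dx <- cg$dX
  }
  invisible(NULL)
}

# ---- variant fusion ------------------------------------------------------

# lift scalar tokens (Tp x 1) with a 1 x d map
liftTokens <- function(x, W, b) sweep(x %*% W, 2, b, `+`)

fuseForward <- function(model, tokL, tokR, N, capture) {
  cfg <- model$config
  P <- model$params
  Tp <- model$tokens
  ML <- matrix(tokL, Tp, N)
  MR <- matrix(tokR, Tp, N)
  cache <- list(ML = ML, MR = MR, samples = vector("list", N))
  attention <- if (capture) vector("list", N) else NULL
  Fmat <- matrix(0, N, fusedDim(cfg))

  if (cfg$variant %in% c("no_cross_attention", "no_both")) {
    Fmat <- t(rbind(ML, MR))
  } else if (usesCrossAttention(cfg$variant)) {
    for (n in seq_len(N)) {
      xl <- ML[, n, drop = FALSE]; xr <- MR[, n, drop = FALSE]
      sc <- list()
      feats <- list()
      for (d in c("LR", "RL")) {
        qsrc <- if (d == "LR") xl else xr
        ksrc <- if (d == "LR") xr else xl
        Q <- liftTokens(qsrc, P[[paste0("att.", d, ".Wq")]],
                        P[[paste0("att.", d, ".bq")]])
        K <- liftTokens(ksrc, P[[paste0("att.", d, ".Wk")]],
                        P[[paste0("att.", d, ".bk")]])
        V <- liftTokens(ksrc, P[[paste0("att.", d, ".Wv")]],
                        P[[paste0("att.", d, ".bv")]])
        att <- crossAttention(Q, K, V)
        sc[[d]] <- list(Q = Q, K = K, V = V, A = att$map)
        feats[[d]] <- as.vector(att$attended)
      }
      if (capture) attention[[n]] <- list(LR = sc$LR$A, RL = sc$RL$A)
      cache$samples[[n]] <- sc
      Fmat[n, ] <- c(feats$LR, feats$RL)
    }
  } else if (cfg$variant == "self_attention") {
    for (n in seq_len(N)) {
      sc <- list()
      feats <- list()
      for (s in c("L", "R")) {
        x <- (if (s == "L") ML else MR)[, n, drop = FALSE]
        E <- liftTokens(x, P$sa.embed.W, P$sa.embed.b)
        Q <- denseFw(E, P$sa.Wq, P$sa.bq)
        K <- denseFw(E, P$sa.Wk, P$sa.bk)
        V <- denseFw(E, P$sa.Wv, P$sa.bv)
        att <- crossAttention(Q, K, V)
        sc[[s]] <- list(x = x, E = E, Q = Q, K = K, V = V, A = att$map)
        feats[[s]] <- colMeans(att$attended)
      }
      cache$samples[[n]] <- sc
      Fmat[n, ] <- c(feats$L, feats$R)
    }
  } else if (cfg$variant == "lightweight_transformer") {
    D <- cfg$trDim
    nh <- cfg$trHeads
    hs <- D %/% nh
    chanExp <- rbind(matrix(P$tr.chan[1, ], Tp, D, byrow = TRUE),
                     matrix(P$tr.chan[2, ], Tp, D, byrow = TRUE))
    for (n in seq_len(N)) {
      x70 <- rbind(ML[, n, drop = FALSE], MR[, n, drop = FALSE])
      E <- liftTokens(x70, P$tr.embed.W, P$tr.embed.b) + P$tr.pos + chanExp
      Q <- denseFw(E, P$tr.Wq, P$tr.bq)
      K <- denseFw(E, P$tr.Wk, P$tr.bk)
      V <- denseFw(E, P$tr.Wv, P$tr.bv)
      heads <- vector("list", nh)
      Ocat <- matrix(0, nrow(E), D)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * hs + 1L):(h * hs)
        att <- crossAttention(Q[, cols, drop = FALSE],
                              K[, cols, drop = FALSE],
                              V[, cols, drop = FALSE])
        heads[[h]] <- att$map
        Ocat[, cols] <- att$attended
      }
      O <- denseFw(Ocat, P$tr.Wo, P$tr.bo)
      R1 <- E + O
      L1 <- lnFw(R1, P$tr.ln1.gamma, P$tr.ln1.beta)
      Hpre <- denseFw(L1$y, P$tr.ffn.W1, P$tr.ffn.b1)
      H <- eluFw(Hpre)
      F2 <- denseFw(H, P$tr.ffn.W2, P$tr.ffn.b2)
      R2 <- L1$y + F2
      L2 <- lnFw(R2, P$tr.ln2.gamma, P$tr.ln2.beta)
      cache$samples[[n]] <- list(x70 = x70, E = E, Q = Q, K = K, V = V,
                                 heads = heads, Ocat = Ocat,
                                 L1 = L1, H = H, L2 = L2)
      Fmat[n, ] <- colMeans(L2$y)
    }
  }
  list(F = Fmat, cache = cache, attention = attention)
}

fuseBackward <- function(model, cache, dF, addGrad) {
  cfg <- model$config
  P <- model$params
  Tp <- model$tokens
  N <- nrow(dF)
  dML <- matrix(0, Tp, N)
  dMR <- matrix(0, Tp, N)

  if (cfg$variant %in% c("no_cross_attention", "no_both")) {
    dML <- t(dF[, seq_len(Tp), drop = FALSE])
    dMR <- t(dF[, Tp + seq_len(Tp), drop = FALSE])
  } else if (usesCrossAttention(cfg$variant)) {
    dv <- cfg$attentionDv
    for (n in seq_len(N)) {
      sc <- cache$samples[[n]]
      xl <- cache$ML[, n, drop = FALSE]; xr <- cache$MR[, n, drop = FALSE]
      dxl <- matrix(0, Tp, 1); dxr <- matrix(0, Tp, 1)
      for (d in c("LR", "RL")) {
        off <- if (d == "LR") 0L else Tp * dv
        dO <- matrix(dF[n, off + seq_len(Tp * dv)], Tp, dv)
        g <- attnBw(dO, sc[[d]]$Q, sc[[d]]$K, sc[[d]]$V, sc[[d]]$A)
        qsrc <- if (d == "LR") xl else xr
        ksrc <- if (d == "LR") xr else xl
        addGrad(paste0("att.", d, ".Wq"), crossprod(qsrc, g$dQ))
        addGrad(paste0("att.", d, ".bq"), colSums(g$dQ))
        addGrad(paste0("att.", d, ".Wk"), crossprod(ksrc, g$dK))
        addGrad(paste0("att.", d, ".bk"), colSums(g$dK))
        addGrad(paste0("att.", d, ".Wv"), crossprod(ksrc, g$dV))
        addGrad(paste0("att.", d, ".bv"), colSums(g$dV))
        dq <- g$dQ %*% t(P[[paste0("att.", d, ".Wq")]])
        dk <- g$dK %*% t(P[[paste0("att.", d, ".Wk")]]) +
          g$dV %*% t(P[[paste0("att.", d, ".Wv")]])
        if (d == "LR") { dxl <- dxl + dq; dxr <- dxr + dk }
        else { dxr <- dxr + dq; dxl <- dxl + dk }
      }
      dML[, n] <- dxl; dMR[, n] <- dxr
    }
  } else if (cfg$variant == "self_attention") {
    D <- cfg$selfAttDim
    for (n in seq_len(N)) {
      sc <- cache$samples[[n]]
      for (s in c("L", "R")) {
        off <- if (s == "L") 0L else D
        dfeat <- dF[n, off + seq_len(D)]
        dO <- matrix(dfeat, Tp, D, byrow = TRUE) / Tp
        g <- attnBw(dO, sc[[s]]$Q, sc[[s]]$K, sc[[s]]$V, sc[[s]]$A)
        E <- sc[[s]]$E
        addGrad("sa.Wq", crossprod(E, g$dQ)); addGrad("sa.bq", colSums(g$dQ))
        addGrad("sa.Wk", crossprod(E, g$dK)); addGrad("sa.bk", colSums(g$dK))
        addGrad("sa.Wv", crossprod(E, g$dV)); addGrad("sa.bv", colSums(g$dV))
        dE <- g$dQ %*% t(P$sa.Wq) + g$dK %*% t(P$sa.Wk) + g$dV %*% t(P$sa.Wv)
        addGrad("sa.embed.W", crossprod(sc[[s]]$x, dE))
        addGrad("sa.embed.b", colSums(dE))
        dx <- dE %*% t(P$sa.embed.W)
        if (s == "L") dML[, n] <- dx else dMR[, n] <- dx
      }
    }
  } else if (cfg$variant == "lightweight_transformer") {
    D <- cfg$trDim; nh <- cfg$trHeads; hs <- D %/% nh
    for (n in seq_len(N)) {
      sc <- cache$samples[[n]]
      Ttot <- nrow(sc$E)
      dL2y <- matrix(dF[n, ], Ttot, D, byrow = TRUE) / Ttot
      g2 <- lnBw(dL2y, sc$L2$cache)
      addGrad("tr.ln2.gamma", g2$dgamma); addGrad("tr.ln2.beta", g2$dbeta)
      dR2 <- g2$dx
      gF2 <- denseBw(sc$H, P$tr.ffn.W2, dR2)
      addGrad("tr.ffn.W2", gF2$dW); addGrad("tr.ffn.b2", gF2$db)
      dHpre <- eluBw(gF2$dx, sc$H)
      gF1 <- denseBw(sc$L1$y, P$tr.ffn.W1, dHpre)
      addGrad("tr.ffn.W1", gF1$dW); addGrad("tr.ffn.b1", gF1$db)
      dL1y <- dR2 + gF1$dx
      g1 <- lnBw(dL1y, sc$L1$cache)
      addGrad("tr.ln1.gamma", g1$dgamma); addGrad("tr.ln1.beta", g1$dbeta)
      dR1 <- g1$dx
      dE <- dR1
      gO <- denseBw(sc$Ocat, P$tr.Wo, dR1)
      addGrad("tr.Wo", gO$dW); addGrad("tr.bo", gO$db)
      dOcat <- gO$dx
      dQ <- matrix(0, Ttot, D); dK <- dQ; dV <- dQ
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * hs + 1L):(h * hs)
        g <- attnBw(dOcat[, cols, drop = FALSE],
                    sc$Q[, cols, drop = FALSE], sc$K[, cols, drop = FALSE],
                    sc$V[, cols, drop = FALSE], sc$heads[[h]])
        dQ[, cols] <- g$dQ; dK[, cols] <- g$dK; dV[, cols] <- g$dV
      }
      addGrad("tr.Wq", crossprod(sc$E, dQ)); addGrad("tr.bq", colSums(dQ))
      addGrad("tr.Wk", crossprod(sc$E, dK)); addGrad("tr.bk", colSums(dK))
      addGrad("tr.Wv", crossprod(sc$E, dV)); addGrad("tr.bv", colSums(dV))
      dE <- dE + dQ %*% t(P$tr.Wq) + dK %*% t(P$tr.Wk) + dV %*% t(P$tr.Wv)
      addGrad("tr.pos", dE)
      addGrad("tr.chan", rbind(colSums(dE[seq_len(Tp), , drop = FALSE]),
                               colSums(dE[Tp + seq_len(Tp), , drop = FALSE])))
      addGrad("tr.embed.W", crossprod(sc$x70, dE))
      addGrad("tr.embed.b", colSums(dE))
      dx70 <- dE %*% t(P$tr.embed.W)
      dML[, n] <- dx70[seq_len(Tp), 1]
      dMR[, n] <- dx70[Tp + seq_len(Tp), 1]
    }
  }
  list(dTokL = matrix(as.vector(dML), ncol = 1),
       dTokR = matrix(as.vector(dMR), ncol = 1))
}

# ---- full model ----------------------------------------------------------

forwardModel <- function(model, X, training = FALSE, keepCache = FALSE,
                         capture = FALSE) {
  if (capture && !usesCrossAttention(model$variant))
    stopTyped("earstress_unsupported_variant",
              "variant '%s' has no cross-attention maps to capture",
              model$variant)
  st <- batchToStreams(X)
  if (nrow(st$L) / st$N != model$config$inputLength)
    stopTyped("earstress_shape_error",
              "input epochs must have %d samples per channel",
              model$config$inputLength)
  encL <- encodeStream(model, st$L, "L", training)
  model$bnState <- encL$bnState
  encR <- encodeStream(model, st$R, "R", training)
  model$bnState <- encR$bnState
  fus <- fuseForward(model, encL$tokens, encR$tokens, st$N, capture)
  P <- model$params
  h1 <- denseFw(fus$F, P$clf.W1, P$clf.b1)
  bnRes <- bnFw(h1, P$clf.bn.gamma, P$clf.bn.beta, model$bnState$clf.bn,
                training)
  model$bnState$clf.bn <- bnRes$state
  a1 <- eluFw(bnRes$y)
  dp <- dropoutFw(a1, model$config$dropoutP, training)
  logits <- denseFw(dp$y, P$clf.W2, P$clf.b2)
  colnames(logits) <- model$classes
  out <- list(logits = logits, bnState = model$bnState,
              attention = fus$attention)
  if (keepCache) {
    out$cache <- list(F = fus$F, fusion = fus$cache, encL = encL, encR = encR,
                      h1bn = bnRes$cache, a1 = a1, mask = dp$mask,
                      dpY = dp$y)
  }
  out
}

backwardModel <- function(model, cache, dlogits) {
  P <- model$params
  gr <- new.env(parent = emptyenv())
  addGrad <- function(nm, g) {
    cur <- gr[[nm]]
    assign(nm, if (is.null(cur)) g else cur + g, envir = gr)
  }
  g2 <- denseBw(cache$dpY, P$clf.W2, dlogits)
  addGrad("clf.W2", g2$dW); addGrad("clf.b2", g2$db)
  da1 <- g2$dx
  if (!is.null(cache$mask)) da1 <- da1 * cache$mask
  da1 <- eluBw(da1, cache$a1)
  gb <- bnBw(da1, cache$h1bn)
  addGrad("clf.bn.gamma", gb$dgamma); addGrad("clf.bn.beta", gb$dbeta)
  g1 <- denseBw(cache$F, P$clf.W1, gb$dx)
  addGrad("clf.W1", g1$dW); addGrad("clf.b1", g1$db)
  dtok <- fuseBackward(model, cache$fusion, g1$dx, addGrad)
  backpropStream(model, cache$encL, dtok$dTokL, addGrad)
  backpropStream(model, cache$encR, dtok$dTokR, addGrad)
  as.list(gr)
}

#' Classify epochs with a (trained) model
#'
#' Evaluation-mode forward pass (running batch-norm statistics, dropout
#' disabled), deterministic and batch-size invariant.
#'
#' @param model an `earstressModel`.
#' @param x an [EpochSet-class] or a `(N, 2, 7500)` array (a single
#'   `2 x 7500` matrix is also accepted).
#' @param batchSize samples per forward chunk.
#' @return `N x 2` logit matrix with columns (relax, stress).
#' @export
classify <- function(model, x, batchSize = 256L) {
  X <- asInputArray(x)
  N <- dim(X)[1]
  out <- matrix(0, N, 2L)
  for (s in seq(1L, N, by = batchSize)) {
    idx <- s:min(N, s + batchSize - 1L)
    out[idx, ] <- forwardModel(model, X[idx, , , drop = FALSE],
                               training = FALSE)$logits
  }
  colnames(out) <- model$classes
  out
}

#' Predicted class labels (0 = relax, 1 = stress)
#' @inheritParams classify
#' @return integer vector of predicted labels.
#' @export
predictLabels <- function(model, x, batchSize = 256L) {
  lg <- classify(model, x, batchSize)
  as.integer(lg[, "stress"] > lg[, "relax"])
}

asInputArray <- function(x) {
  if (is(x, "EpochSet")) return(earEpochs(x))
  if (is.matrix(x)) {
    X <- array(0, c(1L, nrow(x), ncol(x)))
    X[1, , ] <- x
    return(X)
  }
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopTyped("earstress_shape_error",
            "expected an EpochSet, a 2 x T matrix or an (N, 2, T) array")
}
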