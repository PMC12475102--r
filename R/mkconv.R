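#' Number of temporal tokens produced by the conv front-end
#'
#' `T_c = floor(floor(T / P1) / P2)`: two successive non-overlapping average
#' pooling stages each drop the remainder samples.
#'
#' @param T_in trial length in samples.
#' @param pool1,pool2 the two pooling factors.
#' @return the token count `T_c`.
#' @examples
#' tokenCount(1000, 8, 7)  # 17
#' @export
tokenCount <- function(T_in, pool1 = 8L, pool2 = 7L) {
  if (T_in < pool1 * pool2)
    stop(sprintf("T = %d yields zero tokens; minimal admissible T is P1*P2 = %d",
                 T_in, pool1 * pool2))
  (T_in %/% pool1) %/% pool2
}

# "same" padding split for even/odd kernels: extra tap on the right
padSame <- function(K) {
  pl <- (K - 1L) %/% 2L
  c(pl, K - 1L - pl)
}

#' Grouped squeeze-and-excitation attention
#'
#' Standalone form of the gate used inside the conv front-end, operating on a
#' `channels x time` feature map. Squeeze: global average over time per
#' channel. Excitation: a grouped 1x1 projection to `channels / (reduction *
#' nGroups)` units per group with ReLU, then a grouped 1x1 projection to one
#' scalar per group with sigmoid, giving `nGroups` gates in `[0, 1]`. Each
#' gate is broadcast over its group's channels and the rescaled map is added
#' to the residual input: `out = x + a * x`.
#'
#' @param x numeric matrix `channels x time`; `channels` must be divisible by
#'   `nGroups`.
#' @param weights list with per-group lists `W1` (`C_g x h`), `b1`, `W2`
#'   (`h x 1`), `b2`; see [seInit()].
#' @param nGroups number of channel groups G.
#' @return list with `out` (same shape as `x`) and `gates` (length
#'   `nGroups`).
#' @export
groupedSE <- function(x, weights, nGroups) {
  Cm <- nrow(x)
  if (Cm %% nGroups != 0L)
    stop(sprintf("channels (%d) not divisible by nGroups (%d)", Cm, nGroups))
  cg <- Cm %/% nGroups
  s <- rowMeans(x)
  a <- numeric(nGroups)
  for (g in seq_len(nGroups)) {
    sg <- s[(g - 1L) * cg + seq_len(cg)]
    h1 <- pmax(0, drop(crossprod(weights$W1[[g]], sg)) + weights$b1[[g]])
    z <- drop(crossprod(weights$W2[[g]], h1)) + weights$b2[[g]]
    a[g] <- 1 / (1 + exp(-z))
  }
  gain <- rep(a, each = cg)
  list(out = x + x * gain, gates = a)
}

#' @rdname groupedSE
#' @param channels number of feature channels.
#' @param reduction SE reduction ratio; hidden width is
#'   `max(1, floor(channels / (reduction * nGroups)))` per group.
#' @param init scale of the uniform initialization.
#' @export
seInit <- function(channels, nGroups, reduction, init = NULL) {
  cg <- channels %/% nGroups
  h <- max(1L, channels %/% (reduction * nGroups))
  W1 <- list(); b1 <- list(); W2 <- list(); b2 <- list()
  for (g in seq_len(nGroups)) {
    bnd1 <- 1 / sqrt(cg); bnd2 <- 1 / sqrt(h)
    W1[[g]] <- matrix(stats::runif(cg * h, -bnd1, bnd1), cg, h)
    b1[[g]] <- stats::runif(h, -bnd1, bnd1)
    W2[[g]] <- matrix(stats::runif(h, -bnd2, bnd2), h, 1)
    b2[[g]] <- stats::runif(1, -bnd2, bnd2)
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# ---- weight init for the whole front-end -----------------------------------

mkconvInit <- function(config, C) {
  K <- config@kernels; F1 <- config@f1; D <- config@depthMultiplier
  G <- length(K); M <- G * F1; DM <- D * M
  dm <- dModel(config); dg <- config@dGroup
  u <- function(n, fanin) stats::runif(n, -1 / sqrt(fanin), 1 / sqrt(fanin))
  Wt <- lapply(K, function(k) matrix(u(k * F1, k), k, F1))
  se <- seInit(M, G, config@seReduction)
  Wd <- array(u(C * D * M, C), c(C, D, M))
  reduce <- lapply(seq_len(G), function(g)
    matrix(u(D * F1 * dg, D * F1), D * F1, dg))
  conv2 <- lapply(seq_len(G), function(g)
    array(u(dg * config@kernel2 * dg, dg * config@kernel2),
          c(dg, config@kernel2, dg)))
  list(
    Wt = Wt,
    bn1 = list(gamma = rep(1, M), beta = rep(0, M)),
    se = se,
    Wd = Wd,
    bn2 = list(gamma = rep(1, DM), beta = rep(0, DM)),
    reduce = reduce,
    bn3 = list(gamma = rep(1, dm), beta = rep(0, dm)),
    conv2 = conv2,
    bn4 = list(gamma = rep(1, dm), beta = rep(0, dm))
  )
}

mkconvBuffers <- function(config) {
  G <- length(config@kernels); M <- G * config@f1
  DM <- config@depthMultiplier * M; dm <- dModel(config)
  zb <- function(n) list(mean = rep(0, n), var = rep(1, n))
  list(run1 = zb(M), run2 = zb(DM), run3 = zb(dm), run4 = zb(dm))
}

# ---- stage 1: R double-precision reference ---------------------------------
# Same arithmetic as src/frontend.cpp; used at small sizes as the numerical
# oracle and as the "R" backend.

buildColR <- function(X, T_in, C, B, c, K) {
  pd <- padSame(K)
  xc <- matrix(X[, c + C * (0:(B - 1))], T_in, B)
  xp <- rbind(matrix(0, pd[1], B), xc, matrix(0, pd[2], B))
  col <- matrix(0, T_in * B, K)
  for (k in seq_len(K)) col[, k] <- xp[(k - 1) + seq_len(T_in), ]
  col
}

feForwardR <- function(X, w, buffers, config, C, B, train, momentum = 0.1,
                       eps = 1e-5) {
  T_in <- nrow(X)
  K <- config@kernels; F1 <- config@f1; D <- config@depthMultiplier
  G <- length(K); M <- G * F1
  xbuf <- matrix(0, T_in * B, C * M)
  for (j in seq_len(G)) {
    for (c in seq_len(C)) {
      col <- buildColR(X, T_in, C, B, c, K[j])
      O <- col %*% w$Wt[[j]]
      for (f in seq_len(F1))
        xbuf[, c + C * ((j - 1) * F1 + f - 1)] <- O[, f]
    }
  }
  # per-map batch norm via the (T*B*C, M) view
  xv <- xbuf; dim(xv) <- c(T_in * B * C, M)
  bn <- bnFwd(xv, w$bn1$gamma, w$bn1$beta, buffers$run1, train, momentum, eps)
  buffers$run1 <- bn$run
  y1 <- bn$out
  # squeeze: mean over (t, c) per (map, trial)
  s <- apply(array(y1, c(T_in, B, C, M)), c(4, 2), mean)   # M x B
  gates <- matrix(0, G, B)
  h1 <- vector("list", G)
  for (g in seq_len(G)) {
    sg <- s[(g - 1) * F1 + seq_len(F1), , drop = FALSE]
    hg <- crossprod(w$se$W1[[g]], sg) + w$se$b1[[g]]
    hg[hg < 0] <- 0
    z <- crossprod(w$se$W2[[g]], hg) + w$se$b2[[g]]
    gates[g, ] <- 1 / (1 + exp(-z))
    h1[[g]] <- hg
  }
  seOut <- y1
  for (m in seq_len(M)) {
    g <- (m - 1) %/% F1 + 1
    gv <- rep(rep(1 + gates[g, ], each = T_in), times = C)
    seOut[, m] <- y1[, m] * gv
  }
  seMat <- seOut; dim(seMat) <- c(T_in * B, C * M)
  out <- matrix(0, T_in * B, D * M)
  for (m in seq_len(M)) {
    blk <- seMat[, (m - 1) * C + seq_len(C), drop = FALSE]
    out[, (m - 1) * D + seq_len(D)] <- blk %*% w$Wd[, , m]
  }
  list(out = out, run1 = buffers$run1,
       cache = list(X = X, bn = bn$cache, y1 = y1, s = s, h1 = h1,
                    gates = gates, seMat = seMat, w = w, T_in = T_in, C = C,
                    B = B, M = M, F1 = F1, D = D, G = G))
}

feBackwardR <- function(cache, dOut) {
  with(cache, {
    dse <- matrix(0, T_in * B, C * M)
    dWd <- array(0, dim(w$Wd))
    for (m in seq_len(M)) {
      dom <- dOut[, (m - 1) * D + seq_len(D), drop = FALSE]
      blk <- seMat[, (m - 1) * C + seq_len(C), drop = FALSE]
      dWd[, , m] <- crossprod(blk, dom)
      dse[, (m - 1) * C + seq_len(C)] <- dom %*% t(w$Wd[, , m])
    }
    dsev <- dse; dim(dsev) <- c(T_in * B * C, M)
    # gate gradients
    da <- matrix(0, G, B)
    for (m in seq_len(M)) {
      g <- (m - 1) %/% F1 + 1
      prod <- dsev[, m] * y1[, m]
      da[g, ] <- da[g, ] + colSums(matrix(rowSums(array(prod, c(T_in * B, C))),
                                          T_in))
    }
    dW1 <- list(); db1 <- list(); dW2 <- list(); db2 <- list()
    dsq <- matrix(0, M, B)
    for (g in seq_len(G)) {
      av <- gates[g, ]
      dz <- da[g, ] * av * (1 - av)
      hg <- h1[[g]]
      dW2[[g]] <- matrix(hg %*% dz, ncol = 1)
      db2[[g]] <- sum(dz)
      dh <- w$se$W2[[g]] %*% matrix(dz, 1)      # h x B
      dh[hg <= 0] <- 0
      sg <- s[(g - 1) * F1 + seq_len(F1), , drop = FALSE]
      dW1[[g]] <- sg %*% t(dh)
      db1[[g]] <- rowSums(dh)
      dsq[(g - 1) * F1 + seq_len(F1), ] <- w$se$W1[[g]] %*% dh
    }
    # d y1 = dse * (1 + a) + dsq/(T*C)
    dy1 <- dsev
    for (m in seq_len(M)) {
      g <- (m - 1) %/% F1 + 1
      gv <- rep(rep(1 + gates[g, ], each = T_in), times = C)
      addc <- rep(rep(dsq[m, ] / (T_in * C), each = T_in), times = C)
      dy1[, m] <- dsev[, m] * gv + addc
    }
    bnb <- bnBwd(bn, dy1)
    dx <- bnb$dx; dim(dx) <- c(T_in * B, C * M)
    dWt <- vector("list", G)
    for (j in seq_len(G)) {
      Kj <- nrow(w$Wt[[j]])
      acc <- matrix(0, Kj, ncol(w$Wt[[j]]))
      for (c in seq_len(C)) {
        col <- buildColR(X, T_in, C, B, c, Kj)
        DG <- dx[, c + C * ((j - 1) * F1 + seq_len(F1) - 1), drop = FALSE]
        acc <- acc + crossprod(col, DG)
      }
      dWt[[j]] <- acc
    }
    list(dWt = dWt, dGamma = bnb$dgamma, dBeta = bnb$dbeta,
         dSeW1 = dW1, dSeB1 = db1, dSeW2 = dW2, dSeB2 = db2, dWd = dWd)
  })
}

# ---- front dispatch: stage 1 + BN -> ELU -> pool P1 -------------------------
# The compiled path fuses the whole front half; the R path composes the
# double-precision reference primitives. Both return the pooled activations
# (T1*B x D*M) and mirror-image gradients.

frontForward <- function(X, w, buffers, config, C, B, train) {
  T_in <- nrow(X)
  if (feBackend() == "R") {
    r <- feForwardR(X, w, buffers, config, C, B, train)
    buffers$run1 <- r$run1
    bn2 <- bnFwd(r$out, w$bn2$gamma, w$bn2$beta, buffers$run2, train)
    buffers$run2 <- bn2$run
    e1 <- eluFwd(bn2$out)
    p1 <- poolFwd(e1$out, T_in, B, config@pool1)
    list(out = p1$out, buffers = buffers,
         cache = list(kind = "R", c = r$cache, bn2 = bn2$cache, e1 = e1$cache,
                      p1 = p1$cache))
  } else {
    dims <- c(T_in, C, B, config@f1, config@depthMultiplier, config@pool1)
    r <- .fe_forward_cpp(X, config@kernels, w$Wt,
                         w$bn1$gamma, w$bn1$beta,
                         buffers$run1$mean, buffers$run1$var,
                         w$bn2$gamma, w$bn2$beta,
                         buffers$run2$mean, buffers$run2$var,
                         0.1, train, 1e-5,
                         w$se$W1, w$se$b1, w$se$W2, w$se$b2,
                         as.numeric(w$Wd), as.integer(dims), TRUE)
    buffers$run1 <- list(mean = r$run_mean, var = r$run_var)
    buffers$run2 <- list(mean = r$run_mean2, var = r$run_var2)
    list(out = r$out, buffers = buffers,
         cache = list(kind = "cpp", ptr = r$cache, kernels = config@kernels,
                      wdDim = dim(w$Wd)))
  }
}

frontBackward <- function(cache, dPool) {
  if (cache$kind == "R") {
    d <- poolBwd(cache$p1, dPool)
    d <- eluBwd(cache$e1, d)
    bn2 <- bnBwd(cache$bn2, d)
    g <- feBackwardR(cache$c, bn2$dx)
    g$dGamma2 <- bn2$dgamma
    g$dBeta2 <- bn2$dbeta
    g
  } else {
    g <- .fe_backward_cpp(cache$ptr, dPool, cache$kernels)
    g$dWd <- array(g$dWd, cache$wdDim)
    g
  }
}

# ---- stages 2..4 and the public forward ------------------------------------

# forward through the full front-end; x is (T x C*B), returns tokens
# (T_c*B x d_model) plus caches for backprop
mkconvFwd <- function(x, w, buffers, config, C, B, train) {
  T_in <- nrow(x)
  P1 <- config@pool1; P2 <- config@pool2
  dm <- dModel(config); G <- length(config@kernels)
  caches <- list()

  s1 <- frontForward(x, w, buffers, config, C, B, train)
  buffers <- s1$buffers
  caches$fe <- s1$cache
  T1 <- T_in %/% P1
  d1 <- dropoutFwd(s1$out, config@dropout, train); caches$d1 <- d1$cache

  rd <- groupedLinFwd(d1$out, w$reduce); caches$rd <- rd$cache
  bn3 <- bnFwd(rd$out, w$bn3$gamma, w$bn3$beta, buffers$run3, train)
  buffers$run3 <- bn3$run; caches$bn3 <- bn3$cache
  e2 <- eluFwd(bn3$out); caches$e2 <- e2$cache

  pd <- padSame(config@kernel2)
  c2 <- convRowsFwd(e2$out, T1, B, w$conv2, bias = NULL, dilation = 1L,
                    padL = pd[1], padR = pd[2])
  caches$c2 <- c2$cache
  bn4 <- bnFwd(c2$out, w$bn4$gamma, w$bn4$beta, buffers$run4, train)
  buffers$run4 <- bn4$run; caches$bn4 <- bn4$cache
  e3 <- eluFwd(bn4$out); caches$e3 <- e3$cache
  p2 <- poolFwd(e3$out, T1, B, P2); caches$p2 <- p2$cache
  d2 <- dropoutFwd(p2$out, config@dropout, train); caches$d2 <- d2$cache

  list(out = d2$out, buffers = buffers, caches = caches,
       Tc = tokenCount(T_in, P1, P2))
}

mkconvBwd <- function(caches, dZ) {
  d <- dropoutBwd(caches$d2, dZ)
  d <- poolBwd(caches$p2, d)
  d <- eluBwd(caches$e3, d)
  bn4 <- bnBwd(caches$bn4, d)
  c2 <- convRowsBwd(caches$c2, bn4$dx)
  d <- eluBwd(caches$e2, c2$dx)
  bn3 <- bnBwd(caches$bn3, d)
  rd <- groupedLinBwd(caches$rd, bn3$dx)
  d <- dropoutBwd(caches$d1, rd$dx)
  fe <- frontBackward(caches$fe, d)
  list(
    Wt = fe$dWt,
    bn1 = list(gamma = fe$dGamma, beta = fe$dBeta),
    se = list(W1 = fe$dSeW1, b1 = fe$dSeB1, W2 = fe$dSeW2, b2 = fe$dSeB2),
    Wd = fe$dWd,
    bn2 = list(gamma = fe$dGamma2, beta = fe$dBeta2),
    reduce = rd$dW,
    bn3 = list(gamma = bn3$dgamma, beta = bn3$dbeta),
    conv2 = c2$dW,
    bn4 = list(gamma = bn4$dgamma, beta = bn4$dbeta)
  )
}

# convert [B, C, T] batch array to the internal (T x C*B) matrix
batchToMat <- function(batch) {
  d <- dim(batch)
  matrix(aperm(batch, c(3, 2, 1)), d[3], d[2] * d[1])
}

#' Multi-kernel convolutional front-end forward pass
#'
#' Maps a batch of raw trials to the token sequence consumed by the encoder:
#' per-branch temporal convolutions (same padding, no bias) -> per-map batch
#' norm -> grouped SE attention with residual gating -> depthwise spatial
#' convolution over the EEG-channel axis -> batch norm -> ELU -> average pool
#' P1 -> dropout -> grouped pointwise reduction to `d_model` -> batch norm ->
#' ELU -> grouped temporal convolution (kernel `K_C2`) -> batch norm -> ELU ->
#' average pool P2 -> dropout.
#'
#' @param batch numeric array `[B, C, T]` (a singleton leading map axis is
#'   implicit) or a [TrialSet-class].
#' @param weights,buffers front-end weights and batch-norm running statistics;
#'   defaults are freshly initialized from the current RNG state.
#' @param config an [mkConvConfig()].
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return numeric array `[B, T_c, d_model]`.
#' @export
mkConvForward <- function(batch, config = mkConvConfig(), weights = NULL,
                          buffers = NULL, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is(batch, "TrialSet")) batch <- signals(batch)
  d <- dim(batch)
  if (length(d) == 4L) {            # accept [B, 1, C, T]
    stopifnot(d[2] == 1L)
    batch <- array(batch, d[c(1, 3, 4)])
    d <- dim(batch)
  }
  B <- d[1]; C <- d[2]; T_in <- d[3]
  if (any(config@kernels > T_in))
    stop(sprintf("T = %d too short for kernels; minimal admissible T is %d",
                 T_in, max(config@kernels, config@pool1 * config@pool2)))
  tokenCount(T_in, config@pool1, config@pool2)   # errors if pools too large
  if (is.null(weights)) weights <- mkconvInit(config, C)
  if (is.null(buffers)) buffers <- mkconvBuffers(config)
  r <- mkconvFwd(batchToMat(batch), weights, buffers, config, C, B,
                 train = (mode == "train"))
  # (T_c*B x d_model), rows (t, b) -> [B, T_c, d_model]
  aperm(array(r$out, c(r$Tc, B, dModel(config))), c(2, 1, 3))
}
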