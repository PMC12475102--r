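#' Head-to-group mapping for grouped-query attention
#'
#' `g(h) = 1 + floor((h - 1) * G / H)`. With `G = 1` every head shares one
#' key/value pair (multi-query attention); with `G = H` the mapping is the
#' identity and GQA coincides with standard multi-head attention.
#'
#' @param h head index (1-based, may be a vector).
#' @param H number of query heads.
#' @param G number of key/value groups; must divide `H`.
#' @return group index in `1..G`.
#' @examples
#' headGroup(1:4, 4, 2)  # 1 1 2 2
#' @export
headGroup <- function(h, H, G) {
  if (H %% G != 0L) stop("G must divide H")
  stopifnot(all(h >= 1), all(h <= H))
  1L + ((h - 1L) * G) %/% H
}

#' Stochastic-depth rate schedule
#'
#' Quadratic depth schedule `drop_path_i = (i / (N - 1))^2 * drop_path_max`
#' for 0-based layer index `i`; a single-layer encoder uses rate 0.
#'
#' @param i 0-based layer index.
#' @param N number of layers.
#' @param dropPathMax maximum rate, reached at the last layer.
#' @return the drop-path probability for layer `i`.
#' @export
dropPathRate <- function(i, N, dropPathMax = 0.25) {
  stopifnot(i >= 0, i < N)
  if (N < 2L) return(0)
  (i / (N - 1))^2 * dropPathMax
}

# rotation tables: angles pos * theta_i, theta_i = base^(-2(i-1)/d_k)
ropeTables <- function(Tc, dk, base = 10000) {
  if (dk %% 2L != 0L) stop("rotary embedding requires an even head dimension")
  half <- dk %/% 2L
  theta <- base^(-2 * (seq_len(half) - 1) / dk)
  ang <- outer(0:(Tc - 1), theta)
  list(cos = cos(ang), sin = sin(ang))
}

#' Rotary positional embedding
#'
#' Rotates consecutive dimension pairs `(2i-1, 2i)` of each vector by the
#' angle `pos * theta_i` with `theta_i = base^(-2(i-1)/d_k)`. Rotations are
#' isometries, and the inner product of a rotated query/key pair depends on
#' positions only through their difference (relative-position property).
#'
#' @param x numeric matrix `[T x d_k]`, one vector per sequence position.
#' @param positions integer positions (default `0:(T-1)`); position 0 is the
#'   identity.
#' @param base rotation base (default 10000).
#' @return the rotated matrix, same shape as `x`.
#' @export
ropeApply <- function(x, positions = NULL, base = 10000) {
  dk <- ncol(x)
  if (dk %% 2L != 0L) stop("rotary embedding requires an even head dimension")
  if (is.null(positions)) positions <- 0:(nrow(x) - 1)
  half <- dk %/% 2L
  theta <- base^(-2 * (seq_len(half) - 1) / dk)
  ang <- outer(positions, theta)
  co <- cos(ang); si <- sin(ang)
  out <- x
  i1 <- 2 * seq_len(half) - 1; i2 <- 2 * seq_len(half)
  out[, i1] <- x[, i1] * co - x[, i2] * si
  out[, i2] <- x[, i1] * si + x[, i2] * co
  out
}

# rope on (T*B x d_k) row-major (t fastest) matrices using precomputed tables
ropeRowsFwd <- function(x, rt, Tc, B) {
  half <- ncol(x) %/% 2L
  co <- rt$cos[rep(seq_len(Tc), B), , drop = FALSE]
  si <- rt$sin[rep(seq_len(Tc), B), , drop = FALSE]
  i1 <- 2 * seq_len(half) - 1; i2 <- 2 * seq_len(half)
  out <- x
  out[, i1] <- x[, i1] * co - x[, i2] * si
  out[, i2] <- x[, i1] * si + x[, i2] * co
  list(out = out, cache = list(co = co, si = si, i1 = i1, i2 = i2))
}

ropeRowsBwd <- function(cache, dout) {
  with(cache, {
    dx <- dout
    dx[, i1] <- dout[, i1] * co + dout[, i2] * si
    dx[, i2] <- -dout[, i1] * si + dout[, i2] * co
    dx
  })
}

# per-sample stochastic depth on the residual branch (inverted scaling)
dropPathFwd <- function(branch, rate, Tc, B, train) {
  if (!train || rate <= 0) return(list(out = branch, cache = NULL))
  if (rate >= 1) {
    gain <- rep(0, Tc * B)                  # branch fully dropped
  } else {
    keep <- stats::runif(B) >= rate
    gain <- rep(keep / (1 - rate), each = Tc)
  }
  list(out = branch * gain, cache = gain)
}

dropPathBwd <- function(cache, dout) if (is.null(cache)) dout else dout * cache

# ---- weights ----------------------------------------------------------------

encoderInit <- function(config) {
  d <- config@d; H <- config@nHeads; G <- config@nKvGroups
  dk <- headDim(config); rd <- config@ffnRatio * d
  u <- function(n, fanin) stats::runif(n, -1 / sqrt(fanin), 1 / sqrt(fanin))
  mkLayer <- function() list(
    ln1 = list(gamma = rep(1, d), beta = rep(0, d)),
    Wq = matrix(u(d * d, d), d, d),                 # head h: columns (h-1)*dk+1..h*dk
    Wk = lapply(seq_len(G), function(g) matrix(u(d * dk, d), d, dk)),
    Wv = lapply(seq_len(G), function(g) matrix(u(d * dk, d), d, dk)),
    Wo = matrix(u(d * d, d), d, d),
    ln2 = list(gamma = rep(1, d), beta = rep(0, d)),
    W1 = matrix(u(d * rd, d), d, rd), b1 = u(rd, d),
    W2 = matrix(u(rd * d, rd), rd, d), b2 = u(d, rd))
  list(mix = list(W = matrix(u(d * d, d), d, d), b = u(d, d)),
       layers = lapply(seq_len(config@nLayers), function(i) mkLayer()))
}

# ---- attention sublayer -----------------------------------------------------

attnFwd <- function(Z, lw, config, Tc, B, rt, train) {
  d <- config@d; H <- config@nHeads; G <- config@nKvGroups
  dk <- headDim(config)
  ln <- lnFwd(Z, lw$ln1$gamma, lw$ln1$beta)
  zn <- ln$out
  Ks <- vector("list", G); Vs <- vector("list", G); Kcaches <- vector("list", G)
  for (g in seq_len(G)) {
    kg <- ropeRowsFwd(zn %*% lw$Wk[[g]], rt, Tc, B)
    Ks[[g]] <- kg$out; Kcaches[[g]] <- kg$cache
    Vs[[g]] <- zn %*% lw$Wv[[g]]
  }
  heads <- matrix(0, Tc * B, d)
  A <- array(0, c(Tc, Tc, B, H))
  Qs <- vector("list", H); Qcaches <- vector("list", H)
  for (h in seq_len(H)) {
    qh <- ropeRowsFwd(zn %*% lw$Wq[, (h - 1) * dk + seq_len(dk), drop = FALSE],
                      rt, Tc, B)
    Qs[[h]] <- qh$out; Qcaches[[h]] <- qh$cache
    g <- headGroup(h, H, G)
    for (b in seq_len(B)) {
      rows <- (b - 1) * Tc + seq_len(Tc)
      S <- Qs[[h]][rows, , drop = FALSE] %*% t(Ks[[g]][rows, , drop = FALSE]) / sqrt(dk)
      Ab <- softmaxRows(S)
      A[, , b, h] <- Ab
      heads[rows, (h - 1) * dk + seq_len(dk)] <- Ab %*% Vs[[g]][rows, , drop = FALSE]
    }
  }
  proj <- heads %*% lw$Wo
  dr <- dropoutFwd(proj, config@dropout, train)
  list(out = dr$out, attn = A,
       cache = list(ln = ln$cache, zn = zn, Qs = Qs, Qc = Qcaches, Ks = Ks,
                    Kc = Kcaches, Vs = Vs, A = A, heads = heads, lw = lw,
                    dk = dk, H = H, G = G, Tc = Tc, B = B, drop = dr$cache))
}

attnBwd <- function(cache, dout) {
  with(cache, {
    d <- ncol(zn)
    dproj <- dropoutBwd(drop, dout)
    dheads <- dproj %*% t(lw$Wo)
    dWo <- crossprod(heads, dproj)
    dzn <- matrix(0, nrow(zn), d)
    dWq <- matrix(0, d, d)
    dWk <- lapply(Ks, function(k) matrix(0, d, ncol(k)))
    dWv <- lapply(Vs, function(v) matrix(0, d, ncol(v)))
    dKs <- lapply(Ks, function(k) matrix(0, nrow(k), ncol(k)))
    dVs <- lapply(Vs, function(v) matrix(0, nrow(v), ncol(v)))
    for (h in seq_len(H)) {
      g <- headGroup(h, H, G)
      dQ <- matrix(0, Tc * B, dk)
      for (b in seq_len(B)) {
        rows <- (b - 1) * Tc + seq_len(Tc)
        dOh <- dheads[rows, (h - 1) * dk + seq_len(dk), drop = FALSE]
        Ab <- A[, , b, h]
        dVs[[g]][rows, ] <- dVs[[g]][rows, ] + crossprod(Ab, dOh)
        dA <- dOh %*% t(Vs[[g]][rows, , drop = FALSE])
        dS <- Ab * (dA - rowSums(dA * Ab))            # softmax backward
        dS <- dS / sqrt(dk)
        dQ[rows, ] <- dS %*% Ks[[g]][rows, , drop = FALSE]
        dKs[[g]][rows, ] <- dKs[[g]][rows, ] +
          crossprod(dS, Qs[[h]][rows, , drop = FALSE])
      }
      dQr <- ropeRowsBwd(Qc[[h]], dQ)
      dWq[, (h - 1) * dk + seq_len(dk)] <- crossprod(zn, dQr)
      dzn <- dzn + dQr %*% t(lw$Wq[, (h - 1) * dk + seq_len(dk), drop = FALSE])
    }
    for (g in seq_len(G)) {
      dKr <- ropeRowsBwd(Kc[[g]], dKs[[g]])
      dWk[[g]] <- crossprod(zn, dKr)
      dzn <- dzn + dKr %*% t(lw$Wk[[g]])
      dWv[[g]] <- crossprod(zn, dVs[[g]])
      dzn <- dzn + dVs[[g]] %*% t(lw$Wv[[g]])
    }
    lnb <- lnBwd(ln, dzn)
    list(dZ = lnb$dx,
         grads = list(ln1 = list(gamma = lnb$dgamma, beta = lnb$dbeta),
                      Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
  })
}

ffnFwd <- function(O, lw, config, train) {
  ln <- lnFwd(O, lw$ln2$gamma, lw$ln2$beta)
  l1 <- linFwd(ln$out, lw$W1, lw$b1)
  ge <- geluFwd(l1$out)
  l2 <- linFwd(ge$out, lw$W2, lw$b2)
  dr <- dropoutFwd(l2$out, config@dropout, train)
  list(out = dr$out,
       cache = list(ln = ln$cache, l1 = l1$cache, ge = ge$cache,
                    l2 = l2$cache, drop = dr$cache))
}

ffnBwd <- function(cache, dout) {
  with(cache, {
    d2 <- dropoutBwd(drop, dout)
    b2 <- linBwd(l2, d2)
    dg <- geluBwd(ge, b2$dx)
    b1 <- linBwd(l1, dg)
    lnb <- lnBwd(ln, b1$dx)
    list(dZ = lnb$dx,
         grads = list(ln2 = list(gamma = lnb$dgamma, beta = lnb$dbeta),
                      W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
  })
}

# full encoder on (T_c*B x d) matrices
encFwd <- function(Z, w, config, Tc, B, train) {
  rt <- ropeTables(Tc, headDim(config), config@ropeBase)
  mix <- linFwd(Z, w$mix$W, w$mix$b)
  out <- mix$out
  caches <- list(mix = mix$cache, layers = list())
  N <- config@nLayers
  for (i in seq_len(N)) {
    rate <- dropPathRate(i - 1L, N, config@dropPathMax)
    at <- attnFwd(out, w$layers[[i]], config, Tc, B, rt, train)
    dp1 <- dropPathFwd(at$out, rate, Tc, B, train)
    O <- out + dp1$out
    ff <- ffnFwd(O, w$layers[[i]], config, train)
    dp2 <- dropPathFwd(ff$out, rate, Tc, B, train)
    out2 <- O + dp2$out
    caches$layers[[i]] <- list(at = at$cache, dp1 = dp1$cache,
                               ff = ff$cache, dp2 = dp2$cache)
    out <- out2
  }
  list(out = out, caches = caches)
}

encBwd <- function(caches, w, config, dout) {
  N <- config@nLayers
  grads <- list(layers = vector("list", N))
  d <- dout
  for (i in rev(seq_len(N))) {
    lc <- caches$layers[[i]]
    dff_branch <- dropPathBwd(lc$dp2, d)
    ff <- ffnBwd(lc$ff, dff_branch)
    dO <- d + ff$dZ
    dat_branch <- dropPathBwd(lc$dp1, dO)
    at <- attnBwd(lc$at, dat_branch)
    d <- dO + at$dZ
    grads$layers[[i]] <- c(at$grads, ff$grads)
  }
  mx <- linBwd(caches$mix, d)
  grads$mix <- list(W = mx$dW, b = mx$db)
  grads$dZ <- mx$dx
  grads
}

# ---- public array-in / array-out wrappers -----------------------------------

tokensToMat <- function(z) {
  d <- dim(z)                       # [B, T, d]
  matrix(aperm(z, c(2, 1, 3)), d[2] * d[1], d[3])
}

matToTokens <- function(m, Tc, B) {
  aperm(array(m, c(Tc, B, ncol(m))), c(2, 1, 3))
}

#' Grouped-query attention sublayer
#'
#' Pre-norm GQA with rotary embeddings: layer norm, per-head query and
#' per-group shared key/value projections (all bias-free), RoPE on queries and
#' keys, scaled dot-product attention per head, head concatenation and output
#' projection, dropout, and a residual connection
#' (`O = Z + Dropout(GQA(Q, K, V))`).
#'
#' @param Z token array `[B, T_c, d]` (a single `[T_c, d]` matrix is
#'   promoted).
#' @param weights a layer weight list (see [encoderInit()] internals) with
#'   `ln1`, `Wq`, `Wk`, `Wv`, `Wo`.
#' @param config an [encoderConfig()].
#' @param mode `"eval"` or `"train"` (dropout active).
#' @param returnAttention also return the attention tensor
#'   `[T_c, T_c, B, H]`.
#' @return the output array shaped like `Z` (plus `attention` when requested).
#' @export
gqaAttention <- function(Z, weights, config, mode = c("eval", "train"),
                         returnAttention = FALSE) {
  mode <- match.arg(mode)
  single <- length(dim(Z)) == 2L || is.null(dim(Z))
  if (single) Z <- array(Z, c(1L, nrow(Z), ncol(Z)))
  d <- dim(Z)
  if (d[3] != config@d) stop(sprintf("feature dim %d != configured d %d", d[3], config@d))
  rt <- ropeTables(d[2], headDim(config), config@ropeBase)
  m <- tokensToMat(Z)
  at <- attnFwd(m, weights, config, d[2], d[1], rt, train = (mode == "train"))
  out <- matToTokens(m + at$out, d[2], d[1])
  if (single) out <- array(out, d[2:3])
  if (returnAttention) list(out = out, attention = at$attn) else out
}

#' Feed-forward encoder sublayer
#'
#' Pre-norm position-wise FFN: layer norm, expansion by the ratio `ffnRatio`,
#' exact GELU
#' (`x * pnorm(x)`), projection back to `d`, dropout, residual add.
#'
#' @inheritParams gqaAttention
#' @param O input token array `[B, T_c, d]` or `[T_c, d]`.
#' @param weights layer weights with `ln2`, `W1`, `b1`, `W2`, `b2`.
#' @return output array shaped like `O`.
#' @export
ffnSublayer <- function(O, weights, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  single <- length(dim(O)) == 2L
  if (single) O <- array(O, c(1L, nrow(O), ncol(O)))
  d <- dim(O)
  m <- tokensToMat(O)
  ff <- ffnFwd(m, weights, config, train = (mode == "train"))
  out <- matToTokens(m + ff$out, d[2], d[1])
  if (single) array(out, d[2:3]) else out
}

#' Transformer encoder forward pass
#'
#' A pointwise input-mixing projection (the only biased linear map in the
#' attention stack) followed by `N` pre-norm layers of grouped-query attention
#' and feed-forward sublayers, each residual branch wrapped in per-sample
#' stochastic depth with the quadratic [dropPathRate()] schedule. Output
#' length and width equal the input's.
#'
#' @param Z token array `[B, T_c, d]`.
#' @param weights full encoder weights from [encoderInit()]; freshly
#'   initialized when `NULL`.
#' @param config an [encoderConfig()].
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @return token array `[B, T_c, d]`.
#' @export
encoderForward <- function(Z, config = encoderConfig(), weights = NULL,
                           mode = c("eval", "train")) {
  mode <- match.arg(mode)
  d <- dim(Z)
  if (d[3] != config@d) stop(sprintf("feature dim %d != configured d %d", d[3], config@d))
  if (is.null(weights)) weights <- encoderInit(config)
  r <- encFwd(tokensToMat(Z), weights, config, d[2], d[1],
              train = (mode == "train"))
  matToTokens(r$out, d[2], d[1])
}
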