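# Layer primitives used by the encoder / TCN / conv stages.
#
# Activations travel as matrices of shape (T*B) x channels with row index
# t + T*(b-1) (time fastest, then trial). Every forward returns list(out,
# cache); every backward takes (cache, dout) and returns list(dx, grads...).
# All arithmetic is double precision; these functions are the reference
# semantics that the compiled front-end must match.

linFwd <- function(x, W, b = NULL) {
  out <- x %*% W
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(x = x, W = W, hasb = !is.null(b)))
}

linBwd <- function(cache, dout) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$x, dout),
       db = if (cache$hasb) colSums(dout) else NULL)
}

eluFwd <- function(x) {
  pos <- x > 0
  y <- pmax(x, 0) + (exp(pmin(x, 0)) - 1)
  list(out = y, cache = list(pos = pos, y = y))
}

eluBwd <- function(cache, dout) {
  f <- cache$y + 1
  f[cache$pos] <- 1
  dout * f
}

geluFwd <- function(x) {
  # exact GELU: x * Phi(x)
  list(out = x * stats::pnorm(x), cache = list(x = x))
}

geluBwd <- function(cache, dout) {
  x <- cache$x
  dout * (stats::pnorm(x) + x * stats::dnorm(x))
}

dropoutFwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = mask)
}

dropoutBwd <- function(cache, dout) if (is.null(cache)) dout else dout * cache

# batch norm over columns (one feature per column), population variance for
# normalization, unbiased variance into the running buffer (momentum 0.1)
bnFwd <- function(x, gamma, beta, run, train, momentum = 0.1, eps = 1e-5) {
  n <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = n)
    unb <- if (n > 1) v * n / (n - 1) else v
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * unb
  } else {
    inv <- 1 / sqrt(run$var + eps)
    xhat <- (x - rep(run$mean, each = n)) * rep(inv, each = n)
  }
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = out, run = run,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, n = n, train = train))
}

bnBwd <- function(cache, dout) {
  n <- cache$n
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  if (cache$train) {
    dx <- rep(cache$gamma * cache$inv, each = n) *
      (dout - rep(dbeta / n, each = n) - cache$xhat * rep(dgamma / n, each = n))
  } else {
    dx <- dout * rep(cache$gamma * cache$inv, each = n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# layer norm over each row (token)
lnFwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d))
}

lnBwd <- function(cache, dout) {
  n <- nrow(dout); d <- cache$d
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = n)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# non-overlapping average pooling along t for (T*B) x F matrices; trailing
# samples that do not fill a window are dropped (floor semantics)
poolFwd <- function(x, T_in, B, P) {
  Fc <- ncol(x)
  T_out <- T_in %/% P
  a <- array(x, c(T_in, B, Fc))
  a <- a[seq_len(T_out * P), , , drop = FALSE]
  pooled <- colMeans(matrix(a, P))
  out <- matrix(pooled, T_out * B, Fc)
  list(out = out, cache = list(T_in = T_in, B = B, P = P, Fc = Fc, T_out = T_out))
}

poolBwd <- function(cache, dout) {
  with(cache, {
    # spread each pooled gradient uniformly over its P source samples
    da <- array(rep(as.vector(dout) / P, each = P), c(T_out * P, B, Fc))
    full <- array(0, c(T_in, B, Fc))
    full[seq_len(T_out * P), , ] <- da
    matrix(full, T_in * B, Fc)
  })
}

# grouped, dilated 1-d convolution along t for (T*B) x Cin matrices.
# weights: list per group of array (Cin_g, K, Cout_g); optional bias (Cout).
# padL/padR give "same" or causal padding; output length equals T when
# padL + padR == (K-1)*dilation.
convRowsFwd <- function(x, T_in, B, weights, bias = NULL, dilation = 1L,
                        padL, padR) {
  G <- length(weights)
  cing <- dim(weights[[1]])[1]; K <- dim(weights[[1]])[2]
  coutg <- dim(weights[[1]])[3]
  Cin <- ncol(x)
  stopifnot(Cin == cing * G)
  Tp <- T_in + padL + padR
  xp <- array(0, c(Tp, B, Cin))
  xp[padL + seq_len(T_in), , ] <- array(x, c(T_in, B, Cin))
  T_out <- Tp - (K - 1L) * dilation
  cols <- vector("list", G)
  outs <- vector("list", G)
  for (g in seq_len(G)) {
    chs <- (g - 1L) * cing + seq_len(cing)
    col <- matrix(0, T_out * B, cing * K)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * dilation + seq_len(T_out)
      col[, (k - 1L) * cing + seq_len(cing)] <-
        matrix(xp[rows, , chs, drop = FALSE], T_out * B, cing)
    }
    Wm <- matrix(weights[[g]], cing * K, coutg)
    outs[[g]] <- col %*% Wm
    cols[[g]] <- col
  }
  out <- do.call(cbind, outs)
  if (!is.null(bias)) out <- out + rep(bias, each = nrow(out))
  list(out = out,
       cache = list(cols = cols, weights = weights, T_in = T_in, B = B,
                    Tp = Tp, T_out = T_out, K = K, dilation = dilation,
                    padL = padL, cing = cing, coutg = coutg, G = G,
                    hasb = !is.null(bias)))
}

convRowsBwd <- function(cache, dout) {
  with(cache, {
    Cin <- cing * G
    dxp <- array(0, c(Tp, B, Cin))
    dW <- vector("list", G)
    for (g in seq_len(G)) {
      chs <- (g - 1L) * cing + seq_len(cing)
      dog <- dout[, (g - 1L) * coutg + seq_len(coutg), drop = FALSE]
      Wm <- matrix(weights[[g]], cing * K, coutg)
      dW[[g]] <- array(crossprod(cols[[g]], dog), dim(weights[[g]]))
      dcol <- dog %*% t(Wm)
      for (k in seq_len(K)) {
        rows <- (k - 1L) * dilation + seq_len(T_out)
        cur <- dxp[rows, , chs, drop = FALSE]
        dxp[rows, , chs] <- cur +
          array(dcol[, (k - 1L) * cing + seq_len(cing)], c(T_out, B, cing))
      }
    }
    dx <- matrix(dxp[padL + seq_len(T_in), , , drop = FALSE], T_in * B, Cin)
    list(dx = dx, dW = dW, db = if (hasb) colSums(dout) else NULL)
  })
}

# grouped pointwise linear: per group W (a x b), optional per-group bias list
groupedLinFwd <- function(x, weights, biases = NULL) {
  G <- length(weights)
  a <- nrow(weights[[1]])
  outs <- vector("list", G)
  for (g in seq_len(G)) {
    xg <- x[, (g - 1L) * a + seq_len(a), drop = FALSE]
    outs[[g]] <- xg %*% weights[[g]]
    if (!is.null(biases)) outs[[g]] <- outs[[g]] + rep(biases[[g]], each = nrow(x))
  }
  list(out = do.call(cbind, outs),
       cache = list(x = x, weights = weights, hasb = !is.null(biases), a = a))
}

groupedLinBwd <- function(cache, dout) {
  with(cache, {
    G <- length(weights)
    b <- ncol(weights[[1]])
    dx <- matrix(0, nrow(x), ncol(x))
    dW <- vector("list", G); db <- if (hasb) vector("list", G) else NULL
    for (g in seq_len(G)) {
      cols_in <- (g - 1L) * a + seq_len(a)
      dog <- dout[, (g - 1L) * b + seq_len(b), drop = FALSE]
      dx[, cols_in] <- dog %*% t(weights[[g]])
      dW[[g]] <- crossprod(x[, cols_in, drop = FALSE], dog)
      if (hasb) db[[g]] <- colSums(dog)
    }
    list(dx = dx, dW = dW, db = db)
  })
}

# numerically stable softmax cross-entropy; labels 0-based
softmaxRows <- function(z) {
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

ceLossFwd <- function(logits, labels) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- mean(lse - logits[idx])
  p <- exp(logits - lse)
  list(loss = loss, probs = p, cache = list(p = p, idx = idx, n = n))
}

ceLossBwd <- function(cache) {
  g <- cache$p
  g[cache$idx] <- g[cache$idx] - 1
  g / cache$n
}
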