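encCfg <- function(H = 4L, G = 2L, d = 16L, N = 2L, dropout = 0)
  encoderConfig(nLayers = N, nHeads = H, nKvGroups = G, d = d,
                ffnRatio = 2L, dropout = dropout, dropPathMax = 0.25)

layerWeights <- function(cfg, seed = 1) {
  set.seed(seed)
  tcf$encoderInit(cfg)$layers[[1]]
}

# independent reference: plain multi-head attention with per-head key/value
# projections, rotary embeddings and pre-norm, written directly from the
# defining formulas (no shared code with the package internals)
refAttention <- function(Z, lw, cfg, kvIndex) {
  d <- cfg@d; H <- cfg@nHeads; dk <- d %/% H
  out <- array(0, dim(Z))
  for (b in seq_len(dim(Z)[1])) {
    z <- Z[b, , ]
    zn <- t(apply(z, 1, function(r) {
      v <- mean((r - mean(r))^2)
      (r - mean(r)) / sqrt(v + 1e-5)
    }))
    zn <- zn * rep(lw$ln1$gamma, each = nrow(zn)) +
      rep(lw$ln1$beta, each = nrow(zn))
    heads <- NULL
    for (h in seq_len(H)) {
      q <- ropeApply(zn %*% lw$Wq[, (h - 1) * dk + seq_len(dk)])
      k <- ropeApply(zn %*% lw$Wk[[kvIndex(h)]])
      v <- zn %*% lw$Wv[[kvIndex(h)]]
      s <- q %*% t(k) / sqrt(dk)
      a <- exp(s - apply(s, 1, max))
      a <- a / rowSums(a)
      heads <- cbind(heads, a %*% v)
    }
    out[b, , ] <- z + heads %*% lw$Wo
  }
  out
}

test_that("head-to-group mapping follows the floor formula and its limits", {
  expect_equal(headGroup(1:4, 4, 2), c(1L, 1L, 2L, 2L))
  expect_equal(headGroup(1:4, 4, 1), rep(1L, 4))   # multi-query limit
  expect_equal(headGroup(1:4, 4, 4), 1:4)          # full multi-head limit
  expect_equal(headGroup(1:8, 8, 4), rep(1:4, each = 2))
  expect_error(headGroup(1, 4, 3), "divide")
})

test_that("rotary embedding is the identity at position 0 and preserves norms", {
  set.seed(2)
  x <- matrix(rnorm(6 * 8), 6, 8)
  r <- ropeApply(x)
  expect_equal(r[1, ], x[1, ])                     # position 0 untouched
  expect_equal(sqrt(rowSums(r^2)), sqrt(rowSums(x^2)), tolerance = 1e-6)
  expect_error(ropeApply(matrix(0, 3, 5)), "even")
})

test_that("rotary attention scores depend only on relative position", {
  set.seed(3)
  dk <- 8
  q <- matrix(rnorm(dk), 1); k <- matrix(rnorm(dk), 1)
  for (m in c(0, 3, 7)) for (n in c(1, 4)) for (s in c(1, 5, 11)) {
    d0 <- sum(ropeApply(q, m) * ropeApply(k, n))
    d1 <- sum(ropeApply(q, m + s) * ropeApply(k, n + s))
    expect_equal(d0, d1, tolerance = 1e-5)
  }
})

test_that("GQA with G = H matches an independent multi-head attention oracle", {
  cfg <- encCfg(H = 4L, G = 4L)
  lw <- layerWeights(cfg, seed = 4)
  set.seed(5)
  Z <- array(rnorm(2 * 7 * 16), c(2, 7, 16))
  got <- gqaAttention(Z, lw, cfg)
  want <- refAttention(Z, lw, cfg, kvIndex = identity)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("GQA with G = 1 matches an independent multi-query attention oracle", {
  cfg <- encCfg(H = 4L, G = 1L)
  lw <- layerWeights(cfg, seed = 6)
  set.seed(7)
  Z <- array(rnorm(2 * 5 * 16), c(2, 5, 16))
  got <- gqaAttention(Z, lw, cfg)
  want <- refAttention(Z, lw, cfg, kvIndex = function(h) 1L)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("attention rows are normalized and zero queries give uniform attention", {
  cfg <- encCfg()
  lw <- layerWeights(cfg, seed = 8)
  set.seed(9)
  Z <- array(rnorm(3 * 6 * 16), c(3, 6, 16))
  r <- gqaAttention(Z, lw, cfg, returnAttention = TRUE)
  expect_equal(apply(r$attention, c(1, 3, 4), sum),
               array(1, c(6, 3, 4)), tolerance = 1e-6)
  lw0 <- lw; lw0$Wq <- lw0$Wq * 0
  r0 <- gqaAttention(Z, lw0, cfg, returnAttention = TRUE)
  expect_equal(r0$attention, array(1 / 6, dim(r0$attention)), tolerance = 1e-12)
  # pre-residual head outputs are then the token-means of the group values
  zn <- tcf$lnFwd(tcf$tokensToMat(Z), lw0$ln1$gamma, lw0$ln1$beta)$out
  heads <- do.call(cbind, lapply(1:4, function(h) {
    Vg <- zn %*% lw0$Wv[[headGroup(h, 4, 2)]]            # (6*3) x 4, rows (t,b)
    vm <- apply(array(Vg, c(6, 3, 4)), c(2, 3), mean)    # per-trial token mean
    vm[rep(1:3, each = 6), , drop = FALSE]               # broadcast to tokens
  }))
  expect_equal(r0$out - Z, tcf$matToTokens(heads %*% lw0$Wo, 6, 3),
               tolerance = 1e-10)
})

test_that("a single token attends only to itself", {
  cfg <- encCfg()
  lw <- layerWeights(cfg, seed = 10)
  Z <- array(rnorm(2 * 1 * 16), c(2, 1, 16))
  r <- gqaAttention(Z, lw, cfg, returnAttention = TRUE)
  expect_equal(as.vector(r$attention), rep(1, 2 * 4))
})

test_that("exact GELU and the FFN residual behave as defined", {
  expect_equal(tcf$geluFwd(0)$out, 0)
  expect_equal(tcf$geluFwd(1)$out, pnorm(1), tolerance = 1e-12)  # 0.8413
  cfg <- encCfg()
  lw <- layerWeights(cfg, seed = 11)
  lw$W1 <- lw$W1 * 0; lw$W2 <- lw$W2 * 0
  lw$b1 <- lw$b1 * 0; lw$b2 <- lw$b2 * 0
  O <- array(rnorm(2 * 5 * 16), c(2, 5, 16))
  expect_equal(ffnSublayer(O, lw, cfg), O, tolerance = 1e-12)
})

test_that("the stochastic-depth schedule is quadratic in depth", {
  expect_equal(dropPathRate(0, 2, 0.25), 0)
  expect_equal(dropPathRate(1, 2, 0.25), 0.25)
  expect_equal(dropPathRate(2, 5, 0.25), 0.0625)   # (2/4)^2 * 0.25
  expect_equal(dropPathRate(0, 1, 0.25), 0)        # single layer: no drop
  rates <- vapply(0:4, dropPathRate, numeric(1), N = 5, dropPathMax = 0.25)
  expect_true(all(diff(rates) >= 0))
  expect_error(dropPathRate(5, 5, 0.25))
})

test_that("a fully dropped residual branch contributes nothing in train mode", {
  cfg <- encCfg(N = 2L)
  cfg@dropPathMax <- 1                        # layer 1 rate = (1/1)^2 * 1 = 1
  set.seed(12)
  w <- tcf$encoderInit(cfg)
  Z <- array(rnorm(2 * 5 * 16), c(2, 5, 16))
  set.seed(13)
  full <- encoderForward(Z, cfg, w, mode = "train")
  # layer 2's branches are dropped with probability 1, so the output equals
  # running only the first layer's sublayers
  cfg1 <- encCfg(N = 2L)                      # same schedule, eval comparison
  m <- tcf$tokensToMat(Z)
  rt <- tcf$ropeTables(5, tcf$headDim(cfg), cfg@ropeBase)
  mix <- tcf$linFwd(m, w$mix$W, w$mix$b)$out
  at <- tcf$attnFwd(mix, w$layers[[1]], cfg, 5, 2, rt, train = FALSE)
  O <- mix + at$out
  ff <- tcf$ffnFwd(O, w$layers[[1]], cfg, train = FALSE)
  expect_equal(full, tcf$matToTokens(O + ff$out, 5, 2), tolerance = 1e-10)
})

test_that("encoder output keeps the input shape and eval mode is deterministic", {
  cfg <- encCfg(dropout = 0.4)
  set.seed(14)
  w <- tcf$encoderInit(cfg)
  Z <- array(rnorm(3 * 7 * 16), c(3, 7, 16))
  e1 <- encoderForward(Z, cfg, w)
  expect_equal(dim(e1), dim(Z))
  expect_identical(e1, encoderForward(Z, cfg, w))
  expect_error(encoderForward(array(0, c(1, 4, 8)), cfg, w), "feature dim")
})

test_that("key/value parameter count scales with G, not with H", {
  countKV <- function(G) {
    w <- tcf$encoderInit(encCfg(H = 4L, G = G))
    sum(vapply(w$layers, function(l)
      length(unlist(l$Wk)) + length(unlist(l$Wv)), numeric(1)))
  }
  expect_equal(countKV(2L) / countKV(1L), 2)
  expect_equal(countKV(4L) / countKV(1L), 4)
})
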