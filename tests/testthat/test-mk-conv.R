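test_that("token count follows the double floor-division formula", {
  expect_equal(tokenCount(1000, 8, 7), 17)
  expect_equal(tokenCount(56, 8, 7), 1)
  expect_equal(tokenCount(1125, 8, 7), 20)   # floor(floor(1125/8)/7) = floor(140/7)
  expect_error(tokenCount(55, 8, 7), "minimal admissible")
})

test_that("token-count formula matches the realized sequence length over a T grid", {
  cfg <- tinyMkConfig(dropout = 0)
  for (T_in in c(16, 23, 40, 57, 64)) {
    set.seed(T_in)
    z <- mkConvForward(array(rnorm(2 * 3 * T_in), c(2, 3, T_in)), cfg)
    expect_equal(dim(z)[2], tokenCount(T_in, cfg@pool1, cfg@pool2))
    expect_equal(dim(z)[3], dModel(cfg))
  }
})

test_that("grouped SE emits one gate per group, shared within the group", {
  set.seed(3)
  Cm <- 12L; G <- 3L
  w <- seInit(Cm, G, reduction = 2)
  x <- matrix(rnorm(Cm * 30), Cm, 30)
  r <- groupedSE(x, w, G)
  expect_length(r$gates, G)
  expect_true(all(r$gates >= 0 & r$gates <= 1))
  # all channels of one group are rescaled by the same scalar
  ratio <- r$out / x
  for (g in seq_len(G)) {
    rows <- (g - 1) * 4 + 1:4
    expect_equal(max(ratio[rows, ]) - min(ratio[rows, ]), 0, tolerance = 1e-12)
    expect_equal(unique(as.vector(round(ratio[rows, ], 10))),
                 round(1 + r$gates[g], 10))
  }
  expect_error(groupedSE(x, w, 5L), "divisible")
})

test_that("forcing excitation logits to -Inf makes the SE block an identity", {
  set.seed(4)
  w <- seInit(8L, 2L, reduction = 2)
  w$b2 <- lapply(w$b2, function(b) b - 1e9)  # sigmoid -> 0, residual passes
  x <- matrix(rnorm(8 * 20), 8, 20)
  expect_equal(groupedSE(x, w, 2L)$out, x, tolerance = 1e-12)
})

test_that("the published geometry yields 17 x 48 tokens and eval is deterministic", {
  cfg <- mkConvConfig()
  set.seed(5)
  w <- tcf$mkconvInit(cfg, 22L)
  x <- array(rnorm(2 * 22 * 1000), c(2, 22, 1000))
  z1 <- mkConvForward(x, cfg, weights = w)
  expect_equal(dim(z1), c(2, 17, 48))
  z2 <- mkConvForward(x, cfg, weights = w)
  expect_identical(z1, z2)                   # pure function of input + weights
  z0 <- mkConvForward(array(0, c(1, 22, 1000)), cfg, weights = w)
  expect_true(all(is.finite(z0)))
  expect_identical(z0, mkConvForward(array(0, c(1, 22, 1000)), cfg, weights = w))
})

test_that("a single-branch configuration produces d_group-dimensional tokens", {
  cfg <- mkConvConfig(kernels = 20L, dGroup = 16L)
  set.seed(6)
  z <- mkConvForward(array(rnorm(1 * 4 * 112), c(1, 4, 112)), cfg)
  expect_equal(dim(z)[3], 16)                # d_model = d_group * 1
})

test_that("with the SE gates bypassed, zeroing one branch's filters silences exactly its group", {
  cfg <- tinyMkConfig(dropout = 0)
  set.seed(7)
  w <- tcf$mkconvInit(cfg, 3L)
  w$se$b2 <- lapply(w$se$b2, function(b) b - 1e9)   # bypass the gates
  x <- array(rnorm(2 * 3 * 40), c(2, 3, 40))
  for (g in 1:2) {
    wg <- w
    wg$Wt[[g]] <- wg$Wt[[g]] * 0
    z <- mkConvForward(x, cfg, weights = wg)
    own <- (g - 1) * cfg@dGroup + seq_len(cfg@dGroup)
    expect_true(all(z[, , own] == 0))
    expect_gt(max(abs(z[, , -own])), 0)
  }
})

test_that("compiled and reference front-end paths agree in forward and gradients", {
  cfg <- tinyMkConfig(dropout = 0)
  set.seed(8)
  w <- tcf$mkconvInit(cfg, 3L)
  buf <- tcf$mkconvBuffers(cfg)
  X <- matrix(rnorm(40 * 3 * 2), 40, 6)
  run <- function(backend, train) {
    withr::local_options(tcformer.backend = backend)
    tcf$frontForward(X, w, buf, cfg, 3L, 2L, train = train)
  }
  for (train in c(TRUE, FALSE)) {
    rR <- run("R", train); rC <- run("cpp", train)
    expect_equal(rC$out, rR$out, tolerance = 1e-4)
    expect_equal(rC$buffers, rR$buffers, tolerance = 1e-6)
  }
  rR <- run("R", TRUE); rC <- run("cpp", TRUE)
  dOut <- matrix(rnorm(length(rR$out)), nrow(rR$out))
  gR <- tcf$frontBackward(rR$cache, dOut)
  gC <- tcf$frontBackward(rC$cache, dOut)
  scale <- max(abs(unlist(gR)))
  for (nm in names(gR))
    expect_lt(max(abs(unlist(gR[[nm]]) - unlist(gC[[nm]]))) / scale, 1e-4)
})

test_that("front-end analytic gradients match central finite differences", {
  withr::local_options(tcformer.backend = "R")
  cfg <- tinyMkConfig(dropout = 0)
  set.seed(9)
  w <- tcf$mkconvInit(cfg, 3L)
  buf <- tcf$mkconvBuffers(cfg)
  X <- matrix(rnorm(40 * 3 * 2), 40, 6)
  probe <- matrix(rnorm(20 * 16), 20, 16)    # random linear functional on (T1*B) x D*M
  lossFn <- function(w2) {
    r <- tcf$frontForward(X, w2, buf, cfg, 3L, 2L, train = TRUE)
    sum(r$out * probe)
  }
  g <- tcf$frontBackward(tcf$frontForward(X, w, buf, cfg, 3L, 2L, TRUE)$cache,
                         probe)
  mods <- list(
    list(\(w, e) { w$Wt[[2]][10] <- w$Wt[[2]][10] + e; w }, \(g) g$dWt[[2]][10]),
    list(\(w, e) { w$bn1$gamma[3] <- w$bn1$gamma[3] + e; w }, \(g) g$dGamma[3]),
    list(\(w, e) { w$bn2$beta[5] <- w$bn2$beta[5] + e; w }, \(g) g$dBeta2[5]),
    list(\(w, e) { w$Wd[7] <- w$Wd[7] + e; w }, \(g) g$dWd[7]),
    list(\(w, e) { w$se$W1[[1]][2] <- w$se$W1[[1]][2] + e; w }, \(g) g$dSeW1[[1]][2]),
    list(\(w, e) { w$se$b2[[2]][1] <- w$se$b2[[2]][1] + e; w }, \(g) g$dSeB2[[2]][1]))
  for (m in mods) {
    num <- (lossFn(m[[1]](w, 1e-5)) - lossFn(m[[1]](w, -1e-5))) / 2e-5
    expect_equal(m[[2]](g), num, tolerance = 1e-4)
  }
})

test_that("too-short inputs report the minimal admissible length", {
  cfg <- mkConvConfig()
  expect_error(mkConvForward(array(0, c(1, 22, 40)), cfg), "minimal admissible")
})
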