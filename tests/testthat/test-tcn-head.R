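test_that("receptive field follows 1 + 2(K-1)(2^L - 1)", {
  expect_equal(receptiveField(4, 2), 19)
  expect_equal(receptiveField(1, 5), 1)      # pointwise kernels see one step
  expect_equal(receptiveField(4, 3), 43)
})

test_that("fusion projects the encoder tokens and concatenates after the conv groups", {
  set.seed(1)
  Z <- array(rnorm(2 * 17 * 48), c(2, 17, 48))
  E <- array(rnorm(2 * 17 * 48), c(2, 17, 48))
  W <- matrix(rnorm(48 * 16, sd = 0.1), 48, 16)
  b <- rnorm(16, sd = 0.1)
  F1 <- fuseFeatures(Z, E, W, b)
  expect_equal(dim(F1), c(2, 17, 64))        # d_F = (3 + 1) * 16
  expect_equal(F1[, , 1:48], Z)              # conv tokens pass through first
  F0 <- fuseFeatures(Z, E, W * 0, b * 0)
  expect_true(all(F0[, , 49:64] == 0))
  expect_error(fuseFeatures(Z, array(0, c(2, 16, 48)), W, b), "token-count")
})

test_that("TCN blocks preserve length, causality, and the published receptive field", {
  cfg <- tcnConfig()                         # L = 2, K_T = 4 -> RFS 19
  set.seed(2)
  dF <- 8L; groups <- 2L; Tc <- 30L
  w <- tcf$tcnInit(cfg, dF, groups, nClasses = 2L)
  Fm <- array(rnorm(1 * Tc * dF), c(1, Tc, dF))
  seq0 <- tcnForward(Fm, cfg, groups, w, returnSequence = TRUE)
  expect_equal(dim(seq0), dim(Fm))           # same-length output sequence
  # causality: perturbing token t leaves outputs before t unchanged
  for (t in c(5L, 15L, 25L)) {
    Fp <- Fm; Fp[1, t, ] <- Fp[1, t, ] + 1
    seqp <- tcnForward(Fp, cfg, groups, w, returnSequence = TRUE)
    if (t > 1) expect_equal(seqp[, 1:(t - 1), ], seq0[, 1:(t - 1), ],
                            tolerance = 1e-12)
    expect_gt(max(abs(seqp[, t:Tc, ] - seq0[, t:Tc, ])), 0)
  }
  # with T_c = 30 and RFS = 19, tokens 1..11 lie outside the last step's view
  h0 <- tcnForward(Fm, cfg, groups, w)
  Fout <- Fm; Fout[1, 1:11, ] <- Fout[1, 1:11, ] + 5
  expect_equal(tcnForward(Fout, cfg, groups, w), h0, tolerance = 1e-12)
  Fin <- Fm; Fin[1, 12, ] <- Fin[1, 12, ] + 5
  expect_gt(max(abs(tcnForward(Fin, cfg, groups, w) - h0)), 0)
})

test_that("grouped convolutions keep feature groups separated through the TCN", {
  cfg <- tcnConfig()
  set.seed(3)
  dF <- 12L; groups <- 3L; dg <- 4L
  w <- tcf$tcnInit(cfg, dF, groups, nClasses = 2L)
  Fm <- array(rnorm(2 * 10 * dF), c(2, 10, dF))
  base <- tcnForward(Fm, cfg, groups, w, returnSequence = TRUE)
  for (g in seq_len(groups)) {
    own <- (g - 1) * dg + seq_len(dg)
    Fp <- Fm; Fp[, , own] <- 0
    out <- tcnForward(Fp, cfg, groups, w, returnSequence = TRUE)
    expect_gt(max(abs(out[, , own] - base[, , own])), 0)
    expect_equal(out[, , -own], base[, , -own], tolerance = 1e-12)
  }
})

test_that("zeroed convolutions with neutral batch norm make the TCN an identity", {
  cfg <- tcnConfig(dropout = 0)
  dF <- 8L; groups <- 2L
  set.seed(4)
  w <- tcf$tcnInit(cfg, dF, groups, nClasses = 2L)
  for (bk in seq_along(w$blocks)) {
    for (cv in c("conv1", "conv2")) {
      w$blocks[[bk]][[cv]]$W <- lapply(w$blocks[[bk]][[cv]]$W, function(a) a * 0)
      w$blocks[[bk]][[cv]]$b <- w$blocks[[bk]][[cv]]$b * 0
    }
  }
  # non-negative features: the block's final ELU is exactly the identity there
  Fm <- array(abs(rnorm(2 * 6 * dF)), c(2, 6, dF))
  h <- tcnForward(Fm, cfg, groups, w)
  expect_equal(h, matrix(Fm[, 6, ], 2, dF), tolerance = 1e-12)
})

test_that("per-group classifiers average along the group dimension", {
  w <- list(W = list(matrix(0, 2, 2), matrix(0, 2, 2)),
            b = list(c(1, 3), c(3, 1)))
  h <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(classifyFeatures(h, w), matrix(2, 3, 2))  # mean of [1,3], [3,1]
  # identical groups and weights reduce to a single group's logits
  set.seed(5)
  W1 <- matrix(rnorm(4 * 3), 4, 3); b1 <- rnorm(3)
  wsame <- list(W = list(W1, W1), b = list(b1, b1))
  hg <- matrix(rnorm(2 * 4), 2, 4)
  hh <- cbind(hg, hg)
  expect_equal(classifyFeatures(hh, wsame),
               hg %*% W1 + rep(b1, each = 2), tolerance = 1e-12)
  expect_equal(ncol(classifyFeatures(hh, wsame)), 3)
})

test_that("the default geometry satisfies the full-coverage rule T_c <= RFS", {
  cfg <- modelConfig()
  expect_lte(tokenCount(cfg@nSamples, cfg@mkconv@pool1, cfg@mkconv@pool2),
             receptiveField(cfg@tcn@kernel, cfg@tcn@nBlocks))
  # a too-long token sequence triggers the coverage warning at build time
  longCfg <- modelConfig(nSamples = 2000L)
  expect_warning(buildModel(longCfg, seed = 1), "receptive field")
})
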