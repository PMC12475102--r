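#' Receptive field size of the dilated-causal TCN
#'
#' `RFS = 1 + 2 (K_T - 1)(2^L - 1)`: each of the `L` residual blocks applies
#' two causal convolutions with kernel `K_T` at dilation `2^(b-1)`, so the
#' last output position can see up to `RFS` input steps.
#'
#' @param kernel temporal kernel size K_T.
#' @param nBlocks number of residual blocks L.
#' @return the receptive field size in time steps.
#' @examples
#' receptiveField(4, 2)  # 19
#' @export
receptiveField <- function(kernel, nBlocks) {
  stopifnot(kernel >= 1, nBlocks >= 1)
  1 + 2 * (kernel - 1) * (2^nBlocks - 1)
}

tcnInit <- function(config, dF, groups, nClasses) {
  dg <- dF %/% groups
  K <- config@kernel
  u <- function(n, fanin) stats::runif(n, -1 / sqrt(fanin), 1 / sqrt(fanin))
  mkConv <- function() list(
    W = lapply(seq_len(groups), function(g)
      array(u(dg * K * dg, dg * K), c(dg, K, dg))),
    b = u(dF, dg * K))
  blocks <- lapply(seq_len(config@nBlocks), function(bk) list(
    conv1 = mkConv(), bn1 = list(gamma = rep(1, dF), beta = rep(0, dF)),
    conv2 = mkConv(), bn2 = list(gamma = rep(1, dF), beta = rep(0, dF))))
  cls <- list(
    W = lapply(seq_len(groups), function(g)
      matrix(u(dg * nClasses, dg), dg, nClasses)),
    b = lapply(seq_len(groups), function(g) u(nClasses, dg)))
  list(blocks = blocks, classifier = cls)
}

tcnBuffers <- function(config, dF) {
  lapply(seq_len(config@nBlocks), function(b) list(
    run1 = list(mean = rep(0, dF), var = rep(1, dF)),
    run2 = list(mean = rep(0, dF), var = rep(1, dF))))
}

# TCN trunk on (T_c*B x dF) matrices; returns the full output sequence
tcnTrunkFwd <- function(x, w, buffers, config, Tc, B, groups, train) {
  dF <- ncol(x)
  caches <- list()
  for (bk in seq_len(config@nBlocks)) {
    dil <- 2L^(bk - 1L)
    pad <- (config@kernel - 1L) * dil          # causal: all padding on the left
    bw <- w$blocks[[bk]]
    res <- x
    c1 <- convRowsFwd(x, Tc, B, bw$conv1$W, bias = bw$conv1$b,
                      dilation = dil, padL = pad, padR = 0L)
    bn1 <- bnFwd(c1$out, bw$bn1$gamma, bw$bn1$beta, buffers[[bk]]$run1, train)
    buffers[[bk]]$run1 <- bn1$run
    e1 <- eluFwd(bn1$out)
    d1 <- dropoutFwd(e1$out, config@dropout, train)
    c2 <- convRowsFwd(d1$out, Tc, B, bw$conv2$W, bias = bw$conv2$b,
                      dilation = dil, padL = pad, padR = 0L)
    bn2 <- bnFwd(c2$out, bw$bn2$gamma, bw$bn2$beta, buffers[[bk]]$run2, train)
    buffers[[bk]]$run2 <- bn2$run
    e2 <- eluFwd(bn2$out)
    d2 <- dropoutFwd(e2$out, config@dropout, train)
    summed <- res + d2$out
    e3 <- eluFwd(summed)                       # residual add before a final ELU
    caches[[bk]] <- list(c1 = c1$cache, bn1 = bn1$cache, e1 = e1$cache,
                         d1 = d1$cache, c2 = c2$cache, bn2 = bn2$cache,
                         e2 = e2$cache, d2 = d2$cache, e3 = e3$cache)
    x <- e3$out
  }
  list(out = x, buffers = buffers, caches = caches)
}

tcnTrunkBwd <- function(caches, config, dout) {
  grads <- vector("list", config@nBlocks)
  d <- dout
  for (bk in rev(seq_len(config@nBlocks))) {
    cc <- caches[[bk]]
    d <- eluBwd(cc$e3, d)
    dres <- d                                   # identity residual path
    db <- dropoutBwd(cc$d2, d)
    db <- eluBwd(cc$e2, db)
    bn2 <- bnBwd(cc$bn2, db)
    c2 <- convRowsBwd(cc$c2, bn2$dx)
    db <- dropoutBwd(cc$d1, c2$dx)
    db <- eluBwd(cc$e1, db)
    bn1 <- bnBwd(cc$bn1, db)
    c1 <- convRowsBwd(cc$c1, bn1$dx)
    grads[[bk]] <- list(
      conv1 = list(W = c1$dW, b = c1$db),
      bn1 = list(gamma = bn1$dgamma, beta = bn1$dbeta),
      conv2 = list(W = c2$dW, b = c2$db),
      bn2 = list(gamma = bn2$dgamma, beta = bn2$dbeta))
    d <- dres + c1$dx
  }
  list(grads = grads, dx = d)
}

# last-token rows of a (T_c*B x dF) matrix
lastTokenRows <- function(Tc, B) Tc * seq_len(B)

#' Fuse conv-front-end and encoder token sequences
#'
#' Projects the encoder output from `d` to `d_group` with a biased pointwise
#' map and concatenates it after the `n_groups` kernel groups of the MK-CNN
#' tokens, giving the fused width `d_F = (n_groups + 1) * d_group`.
#'
#' @param Z MK-CNN token array `[B, T_c, d_model]`.
#' @param E encoder token array `[B, T_c, d]` with the same token count.
#' @param W,b projection weights `d x d_group` and bias.
#' @return fused array `[B, T_c, d_F]`.
#' @export
fuseFeatures <- function(Z, E, W, b) {
  dz <- dim(Z); de <- dim(E)
  if (dz[2] != de[2]) stop(sprintf("token-count mismatch: %d vs %d", dz[2], de[2]))
  zm <- tokensToMat(Z); em <- tokensToMat(E)
  proj <- em %*% W + rep(b, each = nrow(em))
  matToTokens(cbind(zm, proj), dz[2], dz[1])
}

#' TCN head forward pass
#'
#' Runs `L` residual blocks of two grouped dilated causal convolutions
#' (left-padded by `(K_T - 1) * dilation`, dilation `2^(b-1)` in block `b`,
#' filter count equal to the input width so the residual is an identity), each
#' convolution followed by batch norm, ELU and dropout, with a final ELU after
#' the residual add, and returns the features of the last time step.
#'
#' @param F_in fused token array `[B, T_c, d_F]`.
#' @param config a [tcnConfig()].
#' @param groups number of convolution groups (d_F must be divisible).
#' @param weights,buffers weights from the internal initializer and batch-norm
#'   running statistics; freshly initialized when `NULL`.
#' @param mode `"eval"` or `"train"`.
#' @param returnSequence return the full `[B, T_c, d_F]` output sequence
#'   instead of the last step.
#' @return matrix `[B, d_F]` of last-step features (or the full sequence).
#' @export
tcnForward <- function(F_in, config = tcnConfig(), groups, weights = NULL,
                       buffers = NULL, mode = c("eval", "train"),
                       returnSequence = FALSE) {
  mode <- match.arg(mode)
  d <- dim(F_in)
  dF <- d[3]
  if (dF %% groups != 0L) stop("d_F must be divisible by the group count")
  if (is.null(weights)) weights <- tcnInit(config, dF, groups, nClasses = 2L)
  if (is.null(buffers)) buffers <- tcnBuffers(config, dF)
  r <- tcnTrunkFwd(tokensToMat(F_in), weights, buffers, config, d[2], d[1],
                   groups, train = (mode == "train"))
  if (returnSequence) return(matToTokens(r$out, d[2], d[1]))
  r$out[lastTokenRows(d[2], d[1]), , drop = FALSE]
}

#' Per-group classification of last-step TCN features
#'
#' Applies one pointwise projection `d_group -> n_classes` (with bias) per
#' feature group and averages the per-group logits along the group dimension.
#'
#' @param h matrix `[B, d_F]` of last-step features.
#' @param weights classifier weights: lists `W` (per group `d_group x
#'   n_classes`) and `b`.
#' @return logits matrix `[B, n_classes]`.
#' @export
classifyFeatures <- function(h, weights) {
  G <- length(weights$W)
  dg <- nrow(weights$W[[1]])
  acc <- 0
  for (g in seq_len(G)) {
    hg <- h[, (g - 1) * dg + seq_len(dg), drop = FALSE]
    acc <- acc + hg %*% weights$W[[g]] + rep(weights$b[[g]], each = nrow(h))
  }
  acc / G
}

classifierFwd <- function(h, weights) {
  out <- classifyFeatures(h, weights)
  list(out = out, cache = list(h = h, weights = weights))
}

classifierBwd <- function(cache, dout) {
  with(cache, {
    G <- length(weights$W); dg <- nrow(weights$W[[1]])
    dh <- matrix(0, nrow(h), ncol(h))
    dW <- vector("list", G); db <- vector("list", G)
    for (g in seq_len(G)) {
      cols <- (g - 1) * dg + seq_len(dg)
      dW[[g]] <- crossprod(h[, cols, drop = FALSE], dout) / G
      db[[g]] <- colSums(dout) / G
      dh[, cols] <- (dout %*% t(weights$W[[g]])) / G
    }
    list(dh = dh, dW = dW, db = db)
  })
}
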