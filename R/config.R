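#' Multi-kernel convolutional front-end configuration
#'
#' Defaults follow the published configuration: parallel temporal kernels
#' `K_c = {20, 32, 64}` (80/128/256 ms at 250 Hz, tuned to beta, mu and
#' theta/low-alpha rhythms), `F1 = 32` filters each, depthwise spatial
#' expansion `D = 2`, pooling `P1 = 8` then `P2 = 7`, a grouped pointwise
#' reduction to `d_model = d_group * n_groups` (16 x 3 = 48), a second grouped
#' temporal convolution with kernel 16, grouped squeeze-and-excitation
#' attention over the kernel groups (reduction 16), and dropout `p_c = 0.4`
#' after each pooling stage.
#'
#' @param kernels temporal kernel lengths, one branch per entry.
#' @param f1 temporal filters per kernel branch.
#' @param depthMultiplier depthwise spatial expansion D.
#' @param pool1,pool2 average-pooling factors P1, P2.
#' @param kernel2 second temporal kernel length K_C2.
#' @param dGroup per-group token dimension d_group.
#' @param seReduction squeeze-and-excitation reduction ratio.
#' @param dropout conv-stack dropout rate p_c.
#' @return an `MKConvConfig`; `d_model = dGroup * length(kernels)`.
#' @aliases MKConvConfig-class
#' @exportClass MKConvConfig
#' @export
mkConvConfig <- function(kernels = c(20L, 32L, 64L), f1 = 32L,
                         depthMultiplier = 2L, pool1 = 8L, pool2 = 7L,
                         kernel2 = 16L, dGroup = 16L, seReduction = 16L,
                         dropout = 0.4) {
  new("MKConvConfig", kernels = as.integer(kernels), f1 = as.integer(f1),
      depthMultiplier = as.integer(depthMultiplier), pool1 = as.integer(pool1),
      pool2 = as.integer(pool2), kernel2 = as.integer(kernel2),
      dGroup = as.integer(dGroup), seReduction = as.integer(seReduction),
      dropout = dropout)
}

setClass("MKConvConfig", representation(
  kernels = "integer", f1 = "integer", depthMultiplier = "integer",
  pool1 = "integer", pool2 = "integer", kernel2 = "integer",
  dGroup = "integer", seReduction = "integer", dropout = "numeric"))

setValidity("MKConvConfig", function(object) {
  if (length(object@kernels) < 1L) return("at least one kernel branch required")
  if (any(object@kernels < 1L)) return("kernel lengths must be >= 1")
  if (object@pool1 < 1L || object@pool2 < 1L) return("pooling factors must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  TRUE
})

#' @rdname mkConvConfig
#' @param config an `MKConvConfig`.
#' @export
dModel <- function(config) config@dGroup * length(config@kernels)

#' @rdname mkConvConfig
#' @export
nGroups <- function(config) length(config@kernels)

#' Transformer encoder configuration (grouped-query attention)
#'
#' Defaults: `N = 2` layers, `H = 4` query heads, `G = 2` key/value groups
#' (`G = H/2`), model width equal to the conv front-end's `d_model`, head
#' width `d_k = d/H`, FFN expansion ratio 2, dropout `p_e = 0.4`, quadratic
#' stochastic-depth schedule with `drop_path_max = 0.25`, rotary embedding
#' base 10000.
#'
#' @param nLayers encoder depth N.
#' @param nHeads query heads H.
#' @param nKvGroups key/value groups G (must divide H).
#' @param d model width (token feature dimension).
#' @param ffnRatio feed-forward expansion ratio r.
#' @param dropout residual dropout p_e.
#' @param dropPathMax maximum stochastic-depth rate.
#' @param ropeBase rotary positional embedding base.
#' @return an `EncoderConfig`.
#' @aliases EncoderConfig-class
#' @exportClass EncoderConfig
#' @export
encoderConfig <- function(nLayers = 2L, nHeads = 4L, nKvGroups = 2L, d = 48L,
                          ffnRatio = 2L, dropout = 0.4, dropPathMax = 0.25,
                          ropeBase = 10000) {
  new("EncoderConfig", nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
      nKvGroups = as.integer(nKvGroups), d = as.integer(d),
      ffnRatio = as.integer(ffnRatio), dropout = dropout,
      dropPathMax = dropPathMax, ropeBase = as.numeric(ropeBase))
}

setClass("EncoderConfig", representation(
  nLayers = "integer", nHeads = "integer", nKvGroups = "integer", d = "integer",
  ffnRatio = "integer", dropout = "numeric", dropPathMax = "numeric",
  ropeBase = "numeric"))

setValidity("EncoderConfig", function(object) {
  if (object@nHeads %% object@nKvGroups != 0L)
    return("nKvGroups must divide nHeads")
  if (object@d %% object@nHeads != 0L)
    return("model width d must be divisible by nHeads")
  if ((object@d %/% object@nHeads) %% 2L != 0L)
    return("head width d/H must be even (rotary embedding pairs dimensions)")
  TRUE
})

#' @rdname encoderConfig
#' @param config an `EncoderConfig`.
#' @export
headDim <- function(config) config@d %/% config@nHeads

#' TCN classification-head configuration
#'
#' Defaults: `L = 2` residual blocks of two grouped dilated causal
#' convolutions each (kernel `K_T = 4`, dilation `2^b` in block `b`,
#' filters equal to the input width d_F so the residual is an identity),
#' dropout `p_t = 0.3`. The convolution groups keep the kernel-group and
#' Transformer features separated all the way to the per-group classifiers.
#'
#' @param nBlocks residual blocks L.
#' @param kernel temporal kernel K_T.
#' @param dropout dropout rate p_t.
#' @return a `TCNConfig`.
#' @aliases TCNConfig-class
#' @exportClass TCNConfig
#' @export
tcnConfig <- function(nBlocks = 2L, kernel = 4L, dropout = 0.3) {
  new("TCNConfig", nBlocks = as.integer(nBlocks), kernel = as.integer(kernel),
      dropout = dropout)
}

setClass("TCNConfig", representation(
  nBlocks = "integer", kernel = "integer", dropout = "numeric"))

setValidity("TCNConfig", function(object) {
  if (object@nBlocks < 1L) return("nBlocks must be >= 1")
  if (object@kernel < 1L) return("kernel must be >= 1")
  TRUE
})

#' Full model configuration
#'
#' Combines the three component configurations with the input geometry and
#' the ablation variant: `"A"` = conv front-end + dense classifier, `"B"` =
#' conv front-end + TCN head (groups = n_groups), `"C"` = the full decoder
#' with Transformer encoder and feature fusion (groups = n_groups + 1).
#'
#' @param nChannels,nSamples input geometry (C, T).
#' @param nClasses number of output classes.
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param mkconv,encoder,tcn component configurations.
#' @return a `ModelConfig`.
#' @aliases ModelConfig-class
#' @exportClass ModelConfig
#' @export
modelConfig <- function(nChannels = 22L, nSamples = 1000L, nClasses = 4L,
                        variant = c("C", "A", "B"),
                        mkconv = mkConvConfig(), encoder = NULL,
                        tcn = tcnConfig()) {
  variant <- match.arg(variant)
  if (is.null(encoder)) encoder <- encoderConfig(d = dModel(mkconv))
  new("ModelConfig", nChannels = as.integer(nChannels),
      nSamples = as.integer(nSamples), nClasses = as.integer(nClasses),
      variant = variant, mkconv = mkconv, encoder = encoder, tcn = tcn)
}

setClass("ModelConfig", representation(
  nChannels = "integer", nSamples = "integer", nClasses = "integer",
  variant = "character", mkconv = "MKConvConfig", encoder = "EncoderConfig",
  tcn = "TCNConfig"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (!object@variant %in% c("A", "B", "C")) msgs <- c(msgs, "variant must be A, B or C")
  if (object@variant == "C" && object@encoder@d != dModel(object@mkconv))
    msgs <- c(msgs, sprintf("encoder width d (%d) must equal mkconv d_model (%d)",
                            object@encoder@d, dModel(object@mkconv)))
  if (any(object@mkconv@kernels > object@nSamples))
    msgs <- c(msgs, sprintf("temporal kernels must not exceed T = %d samples", object@nSamples))
  if (object@nSamples < object@mkconv@pool1 * object@mkconv@pool2)
    msgs <- c(msgs, sprintf("T = %d yields zero tokens; need T >= P1*P2 = %d",
                            object@nSamples, object@mkconv@pool1 * object@mkconv@pool2))
  if (length(msgs)) msgs else TRUE
})

#' @rdname modelConfig
#' @param config a `ModelConfig`.
#' @export
fusedDim <- function(config) {
  g <- nGroups(config@mkconv)
  switch(config@variant,
         A = dModel(config@mkconv),
         B = g * config@mkconv@dGroup,
         C = (g + 1L) * config@mkconv@dGroup)
}

#' @rdname modelConfig
#' @export
tcnGroups <- function(config) {
  g <- nGroups(config@mkconv)
  if (config@variant == "C") g + 1L else g
}

#' Load a model configuration from a YAML file
#'
#' Recognised keys mirror the published hyperparameter table: `K_C`, `F1`,
#' `D`, `P1`, `P2`, `K_C2`, `d_group`, `p_c`, `r_se` (conv front-end); `N`,
#' `H`, `G`, `p_e`, `drop_path_max`, `r_ffn`, `rope_base` (encoder); `L`,
#' `K_T`, `p_t` (TCN); plus `n_channels`, `n_samples`, `n_classes`,
#' `variant`.
#'
#' @param path YAML file.
#' @return a [modelConfig()] object.
#' @export
modelConfigFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  mk <- mkConvConfig(
    kernels = as.integer(pick("K_C", c(20, 32, 64))),
    f1 = pick("F1", 32L), depthMultiplier = pick("D", 2L),
    pool1 = pick("P1", 8L), pool2 = pick("P2", 7L),
    kernel2 = pick("K_C2", 16L), dGroup = pick("d_group", 16L),
    seReduction = pick("r_se", 16L), dropout = pick("p_c", 0.4))
  enc <- encoderConfig(
    nLayers = pick("N", 2L), nHeads = pick("H", 4L), nKvGroups = pick("G", 2L),
    d = dModel(mk), ffnRatio = pick("r_ffn", 2L), dropout = pick("p_e", 0.4),
    dropPathMax = pick("drop_path_max", 0.25), ropeBase = pick("rope_base", 10000))
  tc <- tcnConfig(nBlocks = pick("L", 2L), kernel = pick("K_T", 4L),
                  dropout = pick("p_t", 0.3))
  modelConfig(nChannels = pick("n_channels", 22L), nSamples = pick("n_samples", 1000L),
              nClasses = pick("n_classes", 4L),
              variant = pick("variant", "C"), mkconv = mk, encoder = enc, tcn = tc)
}
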