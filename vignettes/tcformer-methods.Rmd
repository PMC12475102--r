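---
title: "TCFormer: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCFormer: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcformer)
```

## The decoding problem

Motor-imagery brain-computer interfaces ask a classifier to map a single EEG
trial $X \in \mathbb{R}^{C \times T}$ ($C$ electrodes, $T$ samples) to one of
$n$ imagined movements. The discriminative signal is weak and oscillatory:
event-related (de)synchronization of the sensorimotor $\mu$ (~8-12 Hz) and
$\beta$ (~13-30 Hz) rhythms over lateralized motor cortex, buried in $1/f$
background activity with strong trial-to-trial and subject-to-subject
variability. `tcformer` implements TCFormer, a compact three-stage decoder for
this problem, together with everything needed to train and evaluate it.

## Architecture

**Multi-kernel convolutional front-end (MK-CNN).** Parallel temporal
convolutions with kernel lengths $K_c = \{20, 32, 64\}$ samples (80/128/256 ms
at 250 Hz; roughly $\beta$, $\mu$ and $\theta$/low-$\alpha$ selective, so that
one to two oscillatory cycles fall inside a kernel), $F_1 = 32$ filters each,
same-padding and no bias. Each branch is batch-normalized; the $3 F_1 = 96$
maps are concatenated and gated by a grouped squeeze-and-excitation block (one
sigmoid gate $a_j \in [0,1]$ per kernel group, reduction ratio 16, residual
form $\hat{X} = X + a \odot X$), letting the network emphasize the most
informative temporal scale. A depthwise spatial convolution with a $C \times
1$ kernel and multiplier $D = 2$ collapses the electrode axis (learning
spatial filters per time-frequency map), followed by batch norm, ELU, average
pooling by $P_1 = 8$, dropout, a grouped pointwise reduction to $d_{model} =
d_{group} \cdot n_{groups} = 48$, a second grouped temporal convolution
($K_{C2} = 16$), batch norm, ELU, pooling by $P_2 = 7$ and dropout. The token
count is

$$T_c = \lfloor \lfloor T / P_1 \rfloor / P_2 \rfloor,$$

17 tokens of width 48 for the canonical 4 s trial at 250 Hz
(`tokenCount(1000, 8, 7)`).

**Grouped-query attention encoder.** A pointwise input-mixing projection
(the one biased linear map in the attention stack) feeds $N = 2$ pre-norm
layers. Each layer computes $H = 4$ query heads that share key/value
projections across $G = 2$ groups via $g(h) = 1 + \lfloor (h-1)G/H \rfloor$;
$G = 1$ recovers multi-query attention, $G = H$ recovers full multi-head
attention (both equivalences are asserted against independent oracle
implementations in the test suite). Rotary positional embeddings rotate
consecutive dimension pairs of queries and keys by $\mathrm{pos} \cdot
\theta_i$, $\theta_i = 10000^{-2i/d_k}$, so attention scores depend on
positions only through their difference. The feed-forward sublayer expands by
the ratio $r = 2$ with exact GELU ($x \Phi(x)$ via the normal CDF). Residual
dropout is $p_e = 0.4$; stochastic depth follows the quadratic schedule
$\mathrm{drop\_path}_i = (i/(N-1))^2 \cdot 0.25$ over 0-based layer indices,
applied per sample and independently to the attention and FFN branches.

**Fusion and TCN head.** The encoder output is projected from $d$ to
$d_{group}$ and concatenated after the conv tokens, giving $d_F = (n_{groups}
+ 1) d_{group} = 64$ fused features. Two residual blocks of two grouped
dilated causal convolutions (kernel $K_T = 4$, dilation $2^{b-1}$ in block
$b$, groups $= n_{groups}+1$ so kernel-group and Transformer features never
mix, filters $= d_F$ so the residual is an identity) decode temporal
structure; each conv is followed by batch norm, ELU and dropout $p_t = 0.3$,
with a final ELU after the residual add. The receptive field is

$$\mathrm{RFS} = 1 + 2 (K_T - 1)(2^L - 1) = 19 \ge T_c = 17,$$

so the retained last-step feature vector sees the whole trial. Per-group
pointwise classifiers map $d_{group} \to n$ and the group logits are averaged.
Training minimizes softmax cross-entropy.

Ablation variants: `A` (front-end + dense classifier on the flattened
tokens), `B` (front-end + TCN with groups $= n_{groups}$), `C` (full model).
`countParameters()` audits every variant; with the defaults on the 22-channel
4-class geometry the budgets round to 27.5k / 37.3k / 77.8k trainable
parameters, which the acceptance tests assert.

### Parameter-accounting conventions

The printed budgets pin down several choices the architecture description
leaves open; the package adopts the unique convention set consistent with all
of them simultaneously, and prints a per-stage breakdown so any residual
discrepancy is localizable:

* convolutions followed by batch norm carry no bias (their shift is redundant
  with the BN offset) — except the TCN convolutions, which do carry biases
  (required to land variant B on 37.3k, and the default in the temporal-block
  design the TCN follows);
* the SE block sits on the 96-map concatenation *before* the depthwise
  convolution with reduction 16, costing 207 parameters (the documented
  "~0.2k"); placing it after the depthwise stage would cost ~0.8k;
* attention projections $W^Q, W^K, W^V, W^O$ are bias-free (the standard
  construction for grouped-query attention with rotary embeddings; biased
  projections would overshoot 77.8k), while the FFN linears, the input-mixing
  projection, the fusion projection and all classifiers are biased;
* the FFN expansion ratio is never printed; $r = 2$ is the value that brings
  the encoder + TCN remainder to the documented ~50.3k.

## Data handling

Per-channel standardization $x' = (x - \mu)/\sigma$ uses statistics pooled
over all training trials and time points (population $1/N$ convention),
computed from the training split only and applied unchanged to held-out data.
Channels with $\sigma < 10^{-8}$ are flagged degenerate and standardized to
zero rather than amplified. Windows are half-open sample intervals with
0-based indexing, so a 4 s window at 250 Hz is exactly 1000 samples.

Segmentation-and-reconstruction augmentation cuts each trial into $N_s = 8$
equal fragments and builds synthetic trials by drawing, independently per
fragment slot, a uniform same-class donor trial with replacement, keeping the
original slot order. With $m_A = m$ the training set doubles. The total is
allocated to classes proportionally to their counts; trial lengths not
divisible by $N_s$ are a hard error (bit-exact reproducibility beats silent
truncation). Donor indices are recorded in the output metadata, and the
training loop refuses donors from outside its training split.

The neutral trial store is a single-file binary container (magic header, JSON
metadata block, little-endian float64 payload) that round-trips `TrialSet`s
bit-exactly; the optional GDF benchmark adapter delegates parsing to Python
`mne` and emits the same container. All core operations consume and produce
`TrialSet`s only.

## Training and evaluation protocol

Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, no weight decay) with peak learning
rate $9 \times 10^{-4}$, a linear warm-up $(e+1)/\mathrm{warmup} \cdot
\mathrm{peak}$ reaching the peak at the last warm-up epoch (20 within-subject,
3 for cross-subject runs), then cosine decay to zero at the final epoch.
Training runs a fixed number of epochs (published protocol: 1000 within
subject for the 4-class sets, 500 for the 2-class set, 125/77 for the
cross-subject settings) with no early stopping and no model selection; the
final checkpoint is evaluated. Batch size is not printed in the protocol; the
default is 64, common in the comparable EEG literature and exposed in
`trainConfig()`.

Metrics: macro-averaged accuracy $\mathrm{ACC} = \frac{1}{n} \sum_i
TP_i/I_i$ (equal to plain accuracy on balanced test sets, a property the
suite asserts) and Cohen's kappa. The published kappa formula averages
per-class chance-corrected agreements with an undefined per-class observed
agreement; the package implements standard multi-class Cohen's kappa from the
pooled confusion matrix — the field convention consistent with the reported
$[-1, 1]$ values — and cross-checks it against `e1071::classAgreement`.
Model comparisons use a two-tailed paired t-test on subject-level accuracy
means, with the conventions $p = 1$ for all-zero differences and $p = 0$
(flagged) for zero-variance nonzero differences.

`runWithinSubject()` trains one model per (subject, seed) on the training
session and evaluates the held-out session; `runLOSO()` trains on the pooled
training sessions of all other subjects. Both recompute standardization
statistics from their own training portion, and both enforce — via unique
trial ids — that no held-out trial ever reaches the statistics, the
augmentation donor pool or a gradient step. Aggregation is per-subject mean
over seeds, then mean ± SD across subjects, and is invariant to result
ordering.

## Synthetic fixture: what it emulates and what it does not

`generateSynthEEG()` produces class-conditioned oscillatory EEG: $1/f^\alpha$
background noise (spectrally shaped white noise, $\alpha = 1$, unit variance)
on every channel plus, per class, an amplitude-modulated sinusoidal burst on a
class-specific channel subset under a raised-cosine envelope covering a random
60-100% of the trial with random onset and phase. The defaults define the
study conditions used throughout the tests: 4 classes, 22 channels, 1000
samples at 250 Hz, 16 trials per class and session, disjoint channel subsets
spanning the montage (5 channels per class), carriers alternating between 10
and 20 Hz, modulation depth 0.8, and burst amplitude `snr * depth` with `snr
= 3` (a clean, well-responsive-subject regime). These defaults define the fixture by its
contracts: the band-power oracle separates the default configuration at
$\ge 0.9$ accuracy, depth 0 collapses everything to chance, and the full
decoder reaches $\ge 0.9$ held-out accuracy within the 60-epoch smoke
protocol. Sixty-four training trials is a deliberately few-shot regime, so
the class signal is made broad (five channels) and strong (`snr = 3`) rather
than the narrow, weak modulations of difficult real subjects — learnability
from few trials and short training is the property the fixture must supply.

The generator is deliberately not a forward model: no volume conduction or
electrode mixing (class subsets are disjoint, unlike real topographies), no
EOG/EMG artifacts, no non-stationary drifts, no inter-subject amplitude
variability beyond independent noise, and stationary carriers instead of
broadband rhythms. Passing the smoke criteria therefore demonstrates that the
pipeline can learn spatio-spectral class structure end to end — wiring,
gradients, optimization and evaluation are sound — not that benchmark
accuracies on real EEG are reproduced; those require the external datasets
and full-length training.

The band-power oracle (`bandpowerOracle()`) is the architecture-independent
separability check: nearest class centroid on per-channel log band power
($\mu$ and $\beta$ bands by default) from raw periodograms. It is used to
validate the generator, never as part of the decoder.

## Numerical choices

* **Precision split.** The first conv stage (temporal convs through the first
  pooling) touches $T \cdot C \cdot 3F_1$ activations per trial and runs in
  compiled single-precision Armadillo/BLAS kernels; batch norm and SE gating
  are per-(map, trial) affine maps, so the normalized tensor is folded into
  the depthwise contraction instead of being materialized. Everything
  downstream ($T_c \le 20$ tokens) runs in R doubles. A pure-R
  double-precision path (`options(tcformer.backend = "R")`) implements
  identical arithmetic; the test suite asserts forward and gradient agreement
  between the two and checks the R path against central finite differences.
  Gradient reductions accumulate in double even in the compiled path.
* **Batch norm** normalizes with population (biased) batch variance,
  maintains running statistics with momentum 0.1 (unbiased variance, the
  usual deep-learning convention) and uses them in eval mode; $\epsilon =
  10^{-5}$ inside the square root.
* **Padding.** Same-padding splits $K - 1$ as $\lfloor (K-1)/2 \rfloor$ left,
  remainder right; the TCN pads $(K_T - 1) \cdot \mathrm{dilation}$ zeros on
  the left only (causality). Average pooling drops remainder samples (floor
  semantics), matching the token-count formula.
* **Initialization.** Fan-in uniform $U(\pm 1/\sqrt{\mathrm{fan_in}})$ for
  all weights and biases, batch-norm scale 1 / shift 0, fixed by the build
  seed; not printed in the protocol, so the common convention is used and
  recorded here.
* **Determinism.** All randomness (initialization, shuffling, dropout,
  stochastic depth, augmentation, generators) derives from explicit seeds;
  two runs with the same seed produce bit-identical weights. Eval-mode
  forward passes are pure functions of input and weights. Prediction breaks
  logit ties toward the lowest class index and refuses train-mode calls.
* **Degenerate inputs.** Flat channels standardize to zero; trials shorter
  than $P_1 P_2$ samples (zero tokens) or shorter than the largest kernel are
  rejected with the minimal admissible length; $P_e = 1$ kappa returns 0;
  stochastic-depth rate 1 zeroes the branch exactly.

## Scaled-down problem sizes in the tests

Unit and property tests run a miniature geometry (3 channels, 40 samples,
kernels {5, 8}, $d_{group} = 4$) where finite-difference gradient checks are
exact and fast. The end-to-end smoke checks run the published geometry
(22 x 1000, full 77.8k-parameter model) on the default synthetic fixture with
a 60-epoch, batch-16 protocol: with 64 training trials this gives 240 Adam
updates, a few-shot regime where smaller batches are standard practice (batch
64 would allow only 60 updates); the `trainConfig()` default remains 64. The
protocol-accounting tests (9 subjects x 5 seeds, LOSO folds) use 2-epoch
runs on the miniature geometry — they verify bookkeeping and leakage guards,
not learning.

## Known limitations

* The GDF adapter requires a Python with `mne` on the `PATH` and is exercised
  only on its error paths offline; benchmark recordings are never downloaded.
* The high-gamma dataset's 44-channel motor-cortex subset is not enumerated
  in the protocol description; the adapter exposes the channel list as
  configuration. Likewise the 2-class benchmark's 4.5 s-imagery sessions are
  cropped to the common 4 s window so every trial has $T = 1000$.
* The SE parameter count (207) refers to the default $F_1 = 32$; the audit
  scales it with $F_1$, whereas the published ablation table implies a count
  that does not, so non-default $F_1$ budgets can differ by a few tens of
  parameters (localizable in the per-stage breakdown).
* Training is single-threaded CPU code tuned for desk-scale experiments;
  reproducing published benchmark accuracies (45 runs of 500-1000 epochs on
  288-880 trials) is out of scope for the bundled protocols, though nothing
  in the implementation caps them.
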