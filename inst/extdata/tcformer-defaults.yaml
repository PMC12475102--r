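# Published default configuration (hyperparameter-table names)
# MK-CNN front-end
K_C: [20, 32, 64]     # temporal kernel lengths (80/128/256 ms at 250 Hz)
F1: 32                # temporal filters per kernel
D: 2                  # depthwise spatial expansion
P1: 8                 # first average-pooling size
P2: 7                 # second average-pooling size
K_C2: 16              # second temporal kernel
d_group: 16           # per-group token dimension (d_model = 48)
r_se: 16              # squeeze-and-excitation reduction
p_c: 0.4              # conv-stack dropout
# Transformer encoder (grouped-query attention)
N: 2                  # layers
H: 4                  # query heads
G: 2                  # key/value groups
p_e: 0.4              # residual dropout
drop_path_max: 0.25   # stochastic-depth ceiling (quadratic schedule)
r_ffn: 2              # feed-forward expansion
rope_base: 10000      # rotary embedding base
# TCN head
L: 2                  # residual blocks
K_T: 4                # kernel size (receptive field 19)
p_t: 0.3              # TCN dropout
# input geometry (4-class, 22-channel, 4 s at 250 Hz)
n_channels: 22
n_samples: 1000
n_classes: 4
variant: C
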