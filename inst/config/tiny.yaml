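# CPU test profile: same optimizer recipe, quarter-width single-layer
# backbone, 32 px inputs.
preset: tiny
image_size: 32
batch_size: 12
lr: 0.05
momentum: 0.9
weight_decay: 0.0001
epochs: 30
seed: 1
class_weights: auto
backbone:
  preset: tiny
ism:
  heads: 4
  mix_mode: sum_others
  alpha_init: 0.5
  placement: interleaved
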