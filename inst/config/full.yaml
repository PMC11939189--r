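# Full-size training recipe.
preset: full
image_size: 384
batch_size: 32
lr: 0.05
momentum: 0.9
weight_decay: 0.0001
epochs: 150
seed: 1
class_weights: auto
backbone:
  preset: full
ism:
  heads: 4
  mix_mode: sum_others
  alpha_init: 0.5
  placement: interleaved
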