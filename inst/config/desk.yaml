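# Desk-scale experiment: tiny backbone, 64-pixel inputs, 3-fold CV.
# This is the documented CPU test entry point:
#   bcrformer run --config desk.yaml --seed 1 --out runs/desk
seed: 1
variants: [ITR, PTR, PPR, Combined, Clinical, Integrated]
simulate:
  n_patients: 60
  prevalence: 0.2
preprocess:
  n_slices: 8
  input_size: 64
  margin_mm: 5
  bbox_pad_fraction: 0.1
model:
  backbone: tiny
  d_emb: 8
  transformer:
    layers: 2
    heads: 4
    model_dim: 64
    dropout: 0.1
    ffn_mult: 2
  freeze_prefix: 0
train:
  lr0: 0.002
  batch_size: 16
  max_epochs: 15
  patience: 10
  weight_decay: 0.01
  k: 3
  repeats: 2
  rotation_deg: 0
  flip_prob: 0.5
  brightness: 0.1
  contrast: 0.1
write_cohort: false
strict_determinism: true
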