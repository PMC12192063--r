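# Desk-scale profile: tiny widths and short schedules for CPU runs.
data:
  image_size: 64
model:
  base_channels: 8
optim:
  lr: 0.1
  batch_size: 8
  epochs: 40
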