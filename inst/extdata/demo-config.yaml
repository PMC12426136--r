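# Demo pipeline configuration: two-group quantitative comparison at reduced
# scale. See ?pipeline_config for the schema.
timing:
  iti: 0.5
  fdt: 0.5
  et: 1.0
sampler:
  n_iter: 600
  burn_in: 200
  seed: 1
model: difference
delta_c_prior: normal
block_window: [11, 20]
scale: reduced
seed: 1
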