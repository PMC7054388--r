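# Tiny configuration for fast checks; not a biological scenario
model:
  n: 3
  sigma_c_ratio: 0.5
solver:
  t_max: 30
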