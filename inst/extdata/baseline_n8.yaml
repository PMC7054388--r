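# Baseline few-stage germinal center: n = 8, sigma_c = 0.5 sigma, equal seeding
model:
  n: 8
  sigma_c_ratio: 0.5
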