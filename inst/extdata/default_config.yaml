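# Default end-to-end pipeline configuration.
# Concentrations in ug/mL, wavelengths in nm, absorbances in AU.
design:
  center: 9
  step: 4
split: odd_even
wavelengths:
  min: 220
  max: 400
  step: 1
mask:
  - [220, 400]
components: default
noise:
  noise_sd: 0.002
  seed: 101
methods: [cls, pcr, pls]
cv:
  max_latent: 8
  rule: one_se_like_fratio
plasma:
  enabled: true
  interferent_level: 1.0
  interferent_jitter: 0.15
ecoscale: example
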