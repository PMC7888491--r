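# Example pipeline configuration: simulate the bundled rapeseed-meal study
# conditions, then run balance, ingredient and prediction stages.
input:
  simulate:
    seed: 42
    noise_scale: 1
    n_pigs_per_diet: 6
output:
  dir: neval-out
units: MJ
fhp_policy: per-pig
dm_policy: as-fed
stepwise:
  alpha_enter: 0.15
  alpha_stay: 0.15
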