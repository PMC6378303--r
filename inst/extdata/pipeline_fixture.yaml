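# small synthetic fixture configuration for end-to-end runs
simulate:
  nSpecialist: 40
  nGeneralist: 40
  nNeutral: 120
depth: 2000
filter_threshold: 2.0e-5
low: 1.5
high: 8.7
n_perm: 99
n_null: 49
seed: 7
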