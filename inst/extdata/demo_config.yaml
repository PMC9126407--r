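# Demo study: two discordant-mediated genes, one independent-signal gene,
# three null regions. Used by the examples and the determinism tests.
alpha: 0.05
r2_max: 0.1
pp_threshold: 0.75
instrument_p: 5.0e-8
discordance_threshold: 0.75
sim:
  n_samples: 1500
  n_variants_per_region: 15
  n_regions: 6
  n_tissues: 2
  architecture: [shared, shared, independent, "null", "null", "null"]
  sign_pattern: discordant
  ge_pe_coupling: -0.5
  h2_ge: 0.15
  h2_pe: 0.15
  theta_total: 0.4
  seed: 2024
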