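# Desk-scale demonstration configuration for run_all(): three simulated
# two-group studies with a planted 40-gene shared signature, plus the
# four-condition validation study. Completes in well under a minute.
seed: 5
simulation:
  genes_master: 600
  signature_size: 40
  private_de_per_study: 50
  n_per_group: 5
sam:
  n_permutations: 100
pathways:
  n_pathways: 20
  size_max: 60
consensus:
  reps: 100
  n_random: 30
  reps_per_signature: 15
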