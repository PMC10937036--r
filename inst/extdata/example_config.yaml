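# Example pipeline configuration: two simulated two-group experiments with
# eight shared consistently responding genes, per-experiment QL tests, and
# cumulative-rank aggregation of the two analyses.
seed: 42
stages: [simulate, dge, rank, report]
simulate:
  shared_consistent_genes: 8
  min_consistent_lfc: 1.5
  experiments:
    - name: exp1
      n_genes: 1000
      groups:
        - {stress: control, 'n': 6}
        - {stress: stress, 'n': 6}
      lib_size: {median: 2000000, sdlog: 0.15}
      frac_stress_de: 0.05
    - name: exp2
      n_genes: 1000
      groups:
        - {stress: control, 'n': 6}
        - {stress: stress, 'n': 6}
      lib_size: {median: 2000000, sdlog: 0.15}
      frac_stress_de: 0.05
dge:
  analyses:
    - name: exp1_stress
      experiment: exp1
      test: ql
      design: stress
      coef: stressstress
    - name: exp2_stress
      experiment: exp2
      test: ql
      design: stress
      coef: stressstress
rank:
  analyses: [exp1_stress, exp2_stress]
report:
  volcano: [exp1_stress, exp2_stress]
  top_n: 10
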