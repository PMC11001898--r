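# Demo pipeline configuration: simulate a small dataset, QC+normalize,
# then run noise estimation, time-course modules and T5-vs-T4 DEG.
output_dir: lungspan_demo
simulate:
  n_genes: 600
  cells_per_group: {T1: 60, T2: 60, T3: 60, T4: 60, T5: 60}
  seed: 11
qc:
  min_features: 50
  max_percent_mt: 20
  min_gene_umi: 5
noise:
  n_bins: 10
  invariant_fraction: 0.1
tca:
  k: 6
  seed: 11
  restarts: 10
deg:
  group_a: T5
  group_b: T4
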