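# Demo run: three simulated conditions (permissive baseline, splicing
# defect at the restrictive temperature, complemented rescue), I/E
# comparisons against baseline, cycle-class strata, restoration tally.
out_dir: results/demo
seed: 7
metric: ie
simulate:
  n_genes: 300
  single_exon_fraction: 0.25
  exons_per_gene: [2, 8]
  exon_length_bp: [100, 2000]
  intron_length_bp: [200, 2000]
  expression_log_mean: 0.0
  expression_log_sd: 1.5
  conditions:
    perm34: 0.02
    mut40: 0.40
    comp40: 0.02
  total_reads_per_condition: 100000
  read_length_bp: 50
design:
  - {"x": perm34, "y": mut40, test: one_sample}
  - {"x": perm34, "y": comp40, test: one_sample}
strata: [G1, SM]
thresholds:
  fold_threshold: 2
  pseudocount: 0.01
  count_pseudocount: 1
restoration: {ref: perm34, defect: mut40, rescued: comp40}
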