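# Example pipeline configuration for a simulated benchmark run.
# For real data, replace the simulate block with a `data` block of paths:
#   data:
#     mrna_counts: mrna_counts.tsv
#     lncrna_counts: lncrna_counts.tsv
#     mirna_counts: mirna_counts.tsv
#     mrna_lengths: mrna_lengths.tsv
#     lncrna_lengths: lncrna_lengths.tsv
#     mrna_fasta: mrna.fa
#     lncrna_fasta: lncrna.fa
#     mirna_fasta: mirna.fa
#     groups: {CC_1: CC, CC_2: CC, CC_3: CC, GC_1: GC, GC_2: GC, GC_3: GC}
simulate:
  n_mrna: 200
  n_lncrna: 60
  n_mirna: 40
  n_planted_triples: 10
fc_min: 2
fdr_max: 0.05
p_max: 0.05
min_site_type: 8mer
regimes: [lenient, strict]
seed: 1
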