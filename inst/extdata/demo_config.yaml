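# Demo configuration: small two-chromosome genome, apple-like methylation,
# planted CG DMRs in a moderately methylated intergenic background.
seed: 42
chrom_lengths:
  chr1: 150000
  chr2: 100000
gene_count: 60
te_fraction: 0.30
coverage_mean: 10
nonconversion_rate: 0.0012
spike_in_length: 48502
n_dmrs: 10
dmr_length_range: [1000, 2000]
dmr_effect: 0.4
dmr_context: CG
dmr_compartment: intergenic
dmr_direction: both
replicates_per_condition: 2
context_levels:
  intergenic:
    CG: [1.0, 0.35, 20]
    CHG: [0.36, 0.65, 10]
    CHH: [0.07, 0.38, 8]
expression_model:
  nonexpressed_fraction: 0.15
  de_fraction: 0.10
  coupling: true
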