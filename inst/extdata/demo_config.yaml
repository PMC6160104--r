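# Demo pipeline configuration: three synthetic cattle-like breeds.
# Probes, signal, truth calls and the manifest are generated; the
# annotation tracks are small synthetic fixtures shipped with the
# package (resolved against the installed extdata directory).
#
# The CNV templates cover ~3% of the 15 Mb toy genome, in line with
# the few-percent CNVR coverage of real cattle assemblies, so that a
# carried deletion does not dominate a sample's genome-wide LRR SD.
seed: 42
simulate:
  populations: {VRP: 25, IBS: 25, HOL: 25}
  n_chrom: 3
  chrom_length_bp: 5000000
  n_probes_per_chrom: 500
  lrr_sd: 0.15
  wave_amplitude: 0.0
  call_rate_range: [0.975, 1.0]
  templates:
    - {chrom: "1", start: 500001, end: 540000, tcn: 1,
       freq: {VRP: 0.8, IBS: 0.7, HOL: 0.1}}
    - {chrom: "1", start: 1500001, end: 1540000, tcn: 3,
       freq: {VRP: 0.5, IBS: 0.5, HOL: 0.5}}
    - {chrom: "1", start: 3000001, end: 3012000, tcn: 0,
       freq: {VRP: 0.3, IBS: 0.3, HOL: 0.3}}
    - {chrom: "1", start: 4100001, end: 4160000, tcn: 3,
       freq: {VRP: 0.35, IBS: 0.35, HOL: 0.35}}
    - {chrom: "2", start: 500001, end: 550000, tcn: 3,
       freq: {VRP: 0.95, IBS: 0.4, HOL: 0.4}}
    - {chrom: "2", start: 2000001, end: 2030000, tcn: 1,
       freq: {VRP: 0.3, IBS: 0.3, HOL: 0.3}}
    - {chrom: "2", start: 3500001, end: 3560000, tcn: 4,
       freq: {VRP: 0.4, IBS: 0.4, HOL: 0.95}}
    - {chrom: "2", start: 4500001, end: 4530000, tcn: 1,
       freq: {VRP: 0.0, IBS: 0.0, HOL: 0.4}}
    - {chrom: "3", start: 750001, end: 800000, tcn: 1,
       freq: {VRP: 0.6, IBS: 0.6, HOL: 0.6}}
    - {chrom: "3", start: 2500001, end: 2540000, tcn: 3,
       freq: {VRP: 0.4, IBS: 0.95, HOL: 0.4}}
    - {chrom: "3", start: 4000001, end: 4060000, tcn: 1,
       freq: {VRP: 0.4, IBS: 0.4, HOL: 0.4}}
    - {chrom: "3", start: 4600001, end: 4640000, tcn: 3,
       freq: {VRP: 0.4, IBS: 0.0, HOL: 0.0}}
qc:
  call_rate_min: 0.98
  lrr_sd_max: 0.30
  wave_max: 0.10
  dlrs_nsd: 3
matrix:
  encoding: copy_number
  min_carriers: 5
  per_population: true
tree:
  n_boot: 100
  distance: euclidean
vst:
  min_carriers: 5
  rule: mean2sd
annotate:
  genes: extdata/demo_genes.tsv
  qtl: extdata/demo_qtl.tsv
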