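# Demo pipeline configuration: small simulated inputs, every stage enabled.
seed: 1

simulate:
  family_matrix:
    n_assemblies: 15
    targets: {core: 47, softcore: 18, dispensable: 69, cloud: 66}
  snp_cohort:
    groups: {LG: 12, MG: 12}
    fst: 0.2
    n_sites: 1500
    chrom_lengths: {chr01: 4.0e6}
  sv_cohort:
    groups: {LG: 12, MG1: 12, MG2: 12}
    n_sv: 400
    favored_frac: 0.1
    focal: LG
    chrom_lengths: {chr01: 4.0e6}
  rga_geneset:
    chrom_lengths: {chr01: 1.0e7, chr02: 1.0e7}
    n_clusters: 5
    n_pairs: 4
    n_decoys: 2
    n_singletons: 15

partition:
  softcore_frac: 0.85

popgen:
  pair: [LG, MG]
  window: 20000
  step: 20000
  hdr_percentile: 95
  thin_gap: 2000

sv:
  window: 100000
  step: 20000
  hotspot_percentile: 95
  focal: LG
  favored_hi: 0.5
  favored_lo: 0.05
  max_missing: 0.5
  maf: 0.05

tree: {}

rga:
  cluster_gap: 200000
  pair_gap: 20000
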