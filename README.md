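# pankiwi

Desk-scale pan-genome analytics for multi-assembly plant cohorts, modeled on
the *Actinidia* (kiwifruit) super pan-genome study design. The package is for
plant population genomicists who have the *tabular* products of a pan-genome
project — an orthogroup membership table, SNP and structural-variant (SV)
VCFs with per-sample genotypes, gene models in GFF3, a sample-to-group map —
and want the bespoke downstream analytics as tested, reusable functions
rather than one-off scripts.

## What it computes

* **Pan-genome partitioning.** Gene families are classified by assembly
  occupancy *f* over *N* assemblies: **core** (*f = N*), **softcore**
  (⌈0.85 N⌉ ≤ *f* < *N*), **dispensable** (2 ≤ *f* < ⌈0.85 N⌉), **cloud**
  (*f* = 1), with composition summaries, group-specific family detection
  (present in *every* focal assembly, absent from *all* others), and a
  hypergeometric/Benjamini–Hochberg term-enrichment test.
* **Windowed differentiation.** Weir–Cockerham (1984) variance components
  *a*, *b*, *c* per site; the weighted window estimate
  FST = Σa / Σ(a+b+c) in 20-kb tiles; highly differentiated regions (HDRs)
  as merged windows strictly above the 95th percentile. Distance-based SNP
  thinning (≥ 2 kb) for tree building.
* **SV landscape.** Genic-context annotation (exon > intron > upstream >
  downstream > intergenic), SV counts in 100-kb/20-kb sliding windows with
  percentile-threshold hotspot calling, per-group allele frequencies, the
  group-favored screen (frequency > 0.5 in the focal group, < 0.05 in every
  other), hotspot gene classing, and PLINK-style `--geno 0.5 --maf 0.05`
  genotype filters.
* **Distance phylogenetics.** p-distance matrices from diploid dosages
  (site distance |d_i − d_j| / 2 over co-genotyped sites) and Saitou–Nei
  neighbor joining with deterministic tie-breaking — consistent (exact
  recovery) on additive matrices.
* **Pan-RGA.** Physical clustering of resistance gene analogs (same family
  within 200 kb, single linkage), head-to-head paired-NLR detection
  (adjacent NBS genes, strands −/+ in coordinate order), per-class
  clustered fractions, and occupancy partitioning of the RGA family matrix.
* **Synthetic data with ground truth.** Balding–Nichols SNP cohorts with a
  target FST, group-structured SV cohorts with planted favored SVs, family
  matrices with planted categories, and gene sets with planted clusters and
  NLR pairs — so every caller is testable by parameter recovery.

Everything is data-frame-first: functions take tibbles and return tibbles,
fitted objects have `tidy()`/`glance()` methods and `autoplot()` displays.

## Worked example

```r
library(pankiwi)

# a 15-assembly family matrix with planted categories, then re-classified
sim  <- simulate_family_matrix(seed = 1)
part <- classify_families(sim$matrix)
partition_summary(part)
#>   category    n_families pct_families n_genes pct_genes
#> 1 core               236         23.6    4644     47.0
#> 2 softcore            87          8.7    1532     15.5
#> 3 dispensable        347         34.7    3260     33.0
#> 4 cloud              330         33       448      4.53
#> 5 total             1000        100      9884    100

# windowed FST between two groups simulated at F = 0.2
snp   <- simulate_snp_cohort(groups = c(LG = 28, MG = 86), fst = 0.2,
                             n_sites = 4000, seed = 1)
track <- windowed_fst(snp$cohort, snp$groups, c("LG", "MG"))
hdr   <- call_hdr(track)                      # > 95th percentile, merged
genome_fst(snp$cohort, snp$groups, c("LG", "MG"))
#> [1] 0.2040659   # weighted FST across all sites; HDRs: 47 regions, 0.98 Mb

# group-favored SVs in a three-group cohort with 10% planted LG-favored
sv  <- simulate_sv_cohort(seed = 1)
fr  <- group_sv_frequencies(sv$cohort, sv$groups)
fav <- favored_svs(fr, "LG")                  # 150 of 2000 SVs
tree <- cohort_nj_tree(sv$cohort)             # p-distance NJ, 60 tips

# paired NLRs among NBS genes
rga <- simulate_rga_geneset(seed = 1)
paired_nlr_summary(rga$genes, paired_nlr(rga$genes))
#>   n_nbs n_pairs pct_genes_in_pairs pct_pairs_per_nbs
#> 1    52       6               23.1              11.5
```

The partition table says: at seed 1 the generator planted 236/87/347/330
families per category and classification recovers them exactly; core
families hold 47% of genes even though dispensable + cloud are 67.7% of
families. The FST run shows the Balding–Nichols cohort calibrating to its
F = 0.2 target and the HDR caller returning the top-5% merged windows.

A full end-to-end run (simulate → partition → FST/HDR → SV landscape →
tree → RGA) is one call:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "pankiwi"),
             out_dir = "demo_out")
```

which writes every result in its standard format (VCF, GFF3, BED, Newick,
TSV) plus a `manifest.json` of parameters and output hashes; reruns with
the same seed are byte-identical.

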