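---
title: "Methods: pan-genome partitioning, windowed differentiation and the SV landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome partitioning, windowed differentiation and the SV landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pankiwi)
```

pankiwi packages the downstream analytics of a multi-assembly plant
pan-genome project — the kiwifruit (*Actinidia*) study design of 15
assemblies and a resequencing panel split into a Leiocarpae group (LG) and
two Maculatae subclades (MG1, MG2) — as tested, desk-scale functions. This
vignette explains the statistical procedures, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate,
and the numerical and design choices that were genuinely open.

## Occupancy partitioning

A gene family's *frequency* is the number of assemblies containing at least
one member; copy number is deliberately ignored, since presence/absence is
what the pan-genome compartments describe. With $N$ assemblies and softcore
fraction $s$ (default $0.85$), the bands are

* core: $f = N$,
* softcore: $\lceil sN \rceil \le f \le N-1$,
* dispensable: $2 \le f < \lceil sN \rceil$,
* cloud: $f = 1$.

For $N = 15$ the softcore band is 13–14 assemblies, the usual "≥ 85% but
not all" convention. The bands tile $1..N$, so classification is total and
monotone in frequency; `partition_thresholds()` refuses $N$ small enough
for the bands to collide ($\lceil sN\rceil \le 2$). Percentages in
summaries are rounded half-up to two decimals; combined shares (e.g.
dispensable + cloud) are computed from raw counts by `composition_share()`
and rounded once, because a sum of independently rounded percentages can
differ in the last digit.

Group-specific families require presence in *every* focal assembly and
absence (count zero) from *every* non-focal assembly — a strict
intersection/difference rule, with sex-specific detection as the same rule
under male/female labels. Term enrichment is a one-sided hypergeometric
upper-tail test (over-representation; the conventional sidedness for
enrichment) with Benjamini–Hochberg correction across tested terms; terms
with fewer than `min_hits = 2` hits are reported `NA` and excluded from
the correction. Gene-level percentages count all member genes of a family
in all assemblies (not only where present); this is configurable upstream
by restricting the matrix.

## Weir–Cockerham FST and HDRs

Per biallelic site, the two-population diploid Weir & Cockerham (1984)
variance components $a$ (among populations), $b$ (among individuals
within) and $c$ (within individuals) are computed from observed allele
frequencies and heterozygote proportions; missing genotypes drop out of
that site's denominators. The windowed estimate is the *weighted* ratio
$\sum a / \sum(a+b+c)$ over the usable sites of each window (the VCFtools
convention), not a mean of ratios. Windows are 20 kb, tiled from position
1 (window anchoring is not dictated by the data, so tiling from 1 is fixed
and documented; both size and step are arguments). Monomorphic sites and
sites with fewer than two genotyped individuals in either group are
unusable and leave an `NA` window when nothing else falls there.

Two numerical properties worth knowing: the estimator admits small
negative values (its finite-sample correction makes two groups with
*identical* genotype vectors come out slightly negative, shrinking
roughly as $1/n$ — the test suite asserts this rather than pretending the
estimate is exactly zero), and a site fixed for opposite alleles gives
exactly 1.

HDR calling takes the stated percentile (default 95) of the non-`NA`
window values using linear interpolation between order statistics
(`quantile()` type 7 — the percentile method is a choice, documented
here), selects windows *strictly above* the threshold, and merges
overlapping or bookended selections. Strict exceedance means a constant
track yields no regions and threshold ties are excluded. The same
machinery (shared code path) drives SV hotspot calling.

Pairs of groups are whatever the group map says; pooling MG1 + MG2 into
"MG" is done by relabeling the map, not by a special pooling mode.

## SV landscape

Genic context uses the precedence exon > intron > upstream > downstream >
intergenic. Deletions and inversions occupy their full span
$[pos, pos + length - 1]$; insertions use the single breakpoint position.
Upstream/downstream windows are 1 kb by default (ANNOVAR's convention) and
strand-aware; hotspot-*upstream* gene classing uses 2 kb, because that is
the window the study design states in that context — the two flanks are
independent parameters on purpose. A gene set without exon features
collapses exon/intron into `genic` with a warning.

Hotspot scanning counts SVs per 100-kb window advancing by 20 kb, counting
an SV in a window when its *start position* lies inside — counting by
span would weight long SVs by their length, and the windowed count is
meant to measure where variants accumulate, not how much sequence they
cover. Group frequencies are alternate-allele counts over non-missing
alleles (a carrier-frequency mode exists). The favored screen uses strict
inequalities (> 0.5 focal, < 0.05 every other group) and, by default,
excludes an SV whose frequency is `NA` in any non-focal group — the
conservative reading; an ignore-`NA` mode is available. The genotype
filter mirrors PLINK `--geno 0.5 --maf 0.05`: missing rate strictly above
0.5 drops, minor allele frequency strictly below 0.05 drops, boundary
values are kept.

## Distances and neighbor joining

The p-distance between two samples is the mean over co-genotyped sites of
$|d_i - d_j|/2$, where $d$ is the alternate dosage — zero shared sites is
an error naming the pair, not a silent `NA`. The exact formula behind
VCF-based distance tools is not published, so this definition is the
package's own documented contract; a shared-allele variant (identical
genotypes 0, one shared allele 0.5, none 1) is offered, differing only for
opposite-homozygote vs heterozygote comparisons.

Trees are plain Saitou–Nei neighbor joining with the Studier–Keppler
Q-criterion. NJ rather than balanced minimum evolution: the tree's role in
this design is grouping samples, NJ is the canonical distance method, and
its consistency on additive matrices gives a sharp test (exact topology
and branch-length recovery, asserted to 1e-9 on random 5–8-taxon trees).
Whether FastME-style NNI/SPR refinement would alter any grouping on real
data cannot be checked without that data, and no equivalence is claimed.
Exact ties in the Q-criterion are broken by the lexicographic order of the
joined subtrees' smallest leaf labels, which makes the algorithm
deterministic and invariant to taxon-order permutations. Negative branch
lengths (possible on non-additive input) are clamped to zero with the
total deficit recorded on the tree.

## RGA atlas

Clustering chains same-family genes along a chromosome while the gap to
the previous gene is at most 200 kb (single linkage — the convention of
the NLR literature the study design follows); chained members can end up
more than 200 kb apart, which is intended. The all-pairs ("diameter")
reading is available behind `method = "diameter"`. Paired NLRs are two
NBS-class genes adjacent *among NBS genes* (an intervening gene of another
class does not break adjacency), strands −/+ in coordinate order
(divergent, promoters facing), intergenic gap at most 20 kb — the study
design states no gap, so 20 kb is the package's default, chosen as a
typical shared-promoter scale and reported with every pair so users can
re-filter. Pairing is greedy left-to-right, which resolves −,+,+ triples
deterministically. Because "percent paired NLRs of NBS genes" is ambiguous
between genes and pairs, `paired_nlr_summary()` reports both denominators.
The pan-RGA partition simply reuses the occupancy classifier on the
RGA-restricted family matrix, plus per-class composition tables.

## Synthetic data: what it emulates, what it does not

The generators produce inputs with the statistical structure the analyses
assume, plus ground truth:

* `simulate_family_matrix()` draws each family's frequency uniformly
  within its planted category band, so re-classification must recover the
  truth exactly — the classifier is the oracle by construction. Default
  composition scales the published 61,465-family pan-genome down to 1,000
  families (236/87/347/330).
* `simulate_snp_cohort()` uses the Balding–Nichols model: ancestral
  frequency $p \sim U(0.05, 0.95)$, group frequency
  $\sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F}, (1-p)\tfrac{1-F}{F}\big)$,
  dosages $\mathrm{Binomial}(2, p_g)$. Balding–Nichols was chosen because
  it has a known expected FST equal to $F$, giving the windowed estimator
  a calibration target (at $F = 0.2$, 2 × 50 samples and 10,000 sites the
  genome-wide weighted FST lands within ±0.03 of target). Default cohort
  28 + 86 mirrors the study's LG/MG resequencing panel sizes.
* `simulate_sv_cohort()` plants a fraction (default 10%) of SVs as
  focal-group-favored: focal frequency $U(0.6, 1)$, other groups
  $U(0, 0.03)$; the rest share one frequency across groups. Genotypes are
  realized by binomial sampling by default — deliberately noisy, to
  exercise missing-data and threshold handling — with an exact-frequency
  mode for threshold unit tests. SV lengths are log-uniform 50 bp–10 kb
  (no length distribution is published; this spans the common short-read
  SV range) and types default to 45/45/10% INS/DEL/INV.
* `simulate_rga_geneset()` separates planted elements by > 200 kb and
  keeps intra-cluster gaps < 200 kb, so cluster recovery is exact; it also
  plants tail-to-tail decoy pairs that the head-to-head rule must reject.

One consequence of the binomial realization is worth stating precisely:
with 20 samples (40 alleles) per group, a planted non-focal frequency
$p \sim U(0, 0.03)$ realizes at $\ge 2/40 = 0.05$ — failing the strict
< 0.05 screen — with probability $\mathbb{E}_p[P(\mathrm{Bin}(40, p)
\ge 2)] \approx 0.13$ per group, so the screen's expected sensitivity
against planted truth is about $0.98 \times 0.87^2 \approx 0.75$ at this
cohort size, for any seed, rising toward 1 as groups grow (the threshold
count scales with $n$ while the planted mean stays below it). The
acceptance suite measures exactly this (~0.75 at seed 1), with zero false
positives among SVs planted common everywhere; the exact-frequency mode
recovers planted truth perfectly. Passing recovery tests on these
generators shows the callers implement their rules correctly — it does
not validate SV discovery, genotyping error models, linkage structure, or
any sequence-level process, none of which are simulated.

## Problem sizes and determinism

The shipped demo pipeline and the test suite run at deliberately small
sizes (1,000–2,000 variants or families, tens of samples, megabase
chromosomes) — large enough for the calibration bands above, small enough
to run in seconds on one core. All generators are deterministic given
`seed`; `run_pipeline()` threads one seed through every stage and writes a
manifest of output MD5 hashes, so a rerun with the same config is
byte-identical. Degenerate inputs have defined behavior throughout: empty
tracks give empty region sets, monomorphic sites give `NA` FST and zero
diversity, families absent everywhere and genotype-free pairs are errors,
and unknown pipeline-config keys fail before any computation.
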