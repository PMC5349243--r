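---
title: "Read-depth CNV and HNRT calling from capture panels: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV and HNRT calling from capture panels: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcnv)
```

## The read-depth model

Read-depth CNV detection rests on one assumption: conditional on library
size and capture efficiency, sequencing reads distribute proportionally
over the captured space, so the expected read count of a region scales with
its copy number. After hybridisation capture the raw counts are distorted
by two nuisance factors — per-genotype library size and per-region capture
efficiency — and the analysis removes them in two steps.

**Normalisation** scales each count by the genotype's library and the
region's length:

$$\mathrm{cov}_{norm}(g, r) =
  \frac{\mathrm{reads}(g,r)\;L_{genome}}{\mathrm{total\ reads}(g)\;L_{region}(r)}$$

This is the region's read density relative to the genotype's genome-average
density: 1 means "drew reads at the genome-wide rate", enriched targets sit
in the hundreds. $L_{genome}$ is the reference assembly length, a
configuration value (default $8.5\times10^8$ bp, the scale of the
*B. napus* Darmor-Bzh assembly). It cancels in the calling ratio below, so
its exact value only shifts QC-report numbers, never calls.

**Panel-relative calling** removes capture efficiency, which is a property
of the region (bait performance, GC, mappability) and hence shared across
genotypes. The coverage ratio

$$\rho(g, r) = \frac{\mathrm{cov}_{norm}(g, r)}
  {\frac{1}{n}\sum_{g'} \mathrm{cov}_{norm}(g', r)}$$

compares each genotype to the panel mean of the same region; a region is
called a deletion when $\rho < 0.5$ and a duplication when $\rho > 1.5$,
otherwise normal. For inbred (effectively homozygous) material the expected
ratios are 0 for a homozygous deletion and 2 for one extra copy pair, so
the 0.5/1.5 thresholds sit halfway between the normal and altered states.

Three consequences of this rule are deliberate and documented rather than
"fixed":

* **The panel mean includes the focal genotype.** A CNV carried by much of
  the panel shifts its own reference and can mask itself; with carrier
  frequencies mostly below 10% the shift is small, but the calls are
  panel-relative states, not absolute copy numbers.
* **Boundary ratios of exactly 0.5 or 1.5 are normal** (strict
  inequalities).
* **Regions with a zero panel mean give `no_call` for every genotype.**
  The ratio is undefined there, and a deletion cannot be distinguished from
  failed enrichment — matching the treatment of target copies that fail
  capture in every genotype but stay on the target list.

## HNRT classification

In an allopolyploid, a homeologous non-reciprocal translocation (HNRT)
replaces a region of one subgenome with its homeologous counterpart from
the other; in read depth it appears as a *coupled* duplication (donor copy)
and deletion (acceptor copy) in the same genotype. `classify_events()`
pairs, within each genotype and homeolog group, duplicated A-subgenome
copies with deleted C-subgenome copies (direction `A_to_C`) and vice versa;
each call is consumed at most once and unmatched calls remain simple
events. Design choices:

* **Greedy pairing in lexicographic `region_id` order**, A-to-C formed
  before C-to-A. For the common two-copy group this is exact; for larger
  groups a published pairing rule does not exist, and the greedy order
  makes the result deterministic and independent of input row order.
* **Cross-subgenome pairing only.** Coupled events within one subgenome
  stay simple events, because homeologous exchange is by definition
  inter-subgenomic.
* **Copies on `*_random` scaffolds are excluded from pairing** (default):
  unanchored bins cannot be placed relative to their homeologs, so a
  "direction" would be meaningless. Their calls still yield simple events.
* An HNRT is *putative*: an independent co-occurring duplication and
  deletion is observationally identical, and the classifier makes no
  attempt to distinguish the two.

The direction semantics — `A_to_C` means the A copy is duplicated and the C
copy deleted — encode "the A copy replaced the C copy", consistent with the
joint observation of A-gene duplication excess and C-gene deletion excess
among selected target genes.

## The synthetic panel generator

`sim_config()` describes the emulated experiment; its defaults are the
study conditions of the motivating design: 280 inbred genotypes, 1184
captured regions of which 231 are targets (186 target genes, 33 promoter
hits, 12 pseudogenes — scaled proportionally for other sizes), 670x mean
target depth, 100 bp single-end reads, an on-target read fraction of 68%,
and two capture-dropout targets. Counts are drawn as

$$\mathrm{reads}(g,r) \sim \mathrm{Poisson}\!\left(
  d \cdot \tfrac{L_r}{L_{read}} \cdot o_r \cdot e_r \cdot \ell_g \cdot
  c_{gr}\right)$$

with target depth $d$, off-target multiplier $o_r$ (1 for targets, default
0.05 otherwise — the off-target coverage level is a free parameter of the
generator, not an observed value), gamma capture efficiency $e_r$ (shape
20, mean 1), lognormal library factor $\ell_g$ (sigma 0.3), and planted
copy ratio $c_{gr}$. The gamma-Poisson mixture gives overdispersion across
regions while counts stay Poisson within a region, which is the dominant
noise structure of capture data without modelling GC bias or mapping error
(deliberately out of scope, as is FASTQ-level simulation).

Simple deletions and duplications are planted independently per
(genotype, region) at prevalence 0.02 per type, HNRTs per
(genotype, homeolog pair) at prevalence 0.01 with an A-to-C direction bias
of 0.82; at most one event occupies a cell. Morphotype labels (winter /
spring / other at 137:94:49) can scale prevalences per group to emulate
morphotype-enriched CNVs. Because the lines are inbred, deletions are
homozygous (ratio 0) and duplications single-extra-copy (ratio 2);
heterozygous intermediates (0.5/1.5) are available for
threshold-sensitivity studies.

One identifiability rule: when independent simple events would place a
duplication on one copy of a homeolog pair and a deletion on the other copy
in the same genotype, the generator suppresses the deletion. Such a
coincidence is *definitionally* indistinguishable from an HNRT, so leaving
it in would make the truth table unrecoverable by any classifier; real
data, of course, contains exactly such coincidences — which is why called
HNRTs are always "putative". This is the main respect in which a passing
recovery test overstates performance on real data; the others are the
absence of mapping artefacts, GC-correlated coverage waves, and
reference-assembly errors.

Depth profiles for base-resolution QC place each counted read uniformly at
random among the start positions where it fits inside the region; regions
shorter than the read are covered end-to-end by truncated reads. Total
depth therefore equals `count × read_length` minus edge truncation, the
identity the tests exercise.

## QC metrics

`qc_report()` assembles the standard enrichment table: mean genome-wide
coverage (`total_reads × read_length / genome_length`), mean target
coverage (on-target bases over target length), their ratio (enrichment
factor), the mean normalised target coverage (mean of
$\mathrm{cov}_{norm}$ over target regions — the natural reading of a
"normalized mean target coverage"), target specificity and, from depth
profiles, target sensitivity at a depth threshold. Two readings were
genuinely open:

* **Specificity on reads, not bases.** The per-region count model attributes
  each counted read wholly to its region; for reads falling inside captured
  regions the two readings coincide, and the read-level one is computable
  from the core data model.
* **"Covered by more than 10 reads" = depth ≥ 11** (strict reading).

## Validation stage

CNV calls are recoded to biallelic presence/absence markers (one marker per
(region, event type) with ≥ 1 carrier; `no_call` → missing) so they can
join SNP/InDel matrices in marker-level analyses. Filtering keeps markers
with non-missing fraction > 0.9 and MAF > 0.01, then individuals with
non-missing fraction > 0.8 — markers first, individuals recomputed on the
survivors, the common convention where no order is prescribed; all
inequalities strict as stated. Concordance between two platforms pools
matches over individuals non-missing in both, ranks pairs worst-first, and
supports removal either of the k worst pairs or below a concordance
threshold — both exposed because low-concordance markers are in practice
removed by inspection.

The deletion-duplication correlation (Pearson, two-sided, via
`stats::cor.test`) is computed over target-gene copies of one subgenome by
default; the per-genotype aggregation is exposed as `unit = "genotype"`
since the counting unit of such summaries is often left implicit.

## Numerical and reproducibility choices

* All pipeline TSV outputs are written with 6 significant digits so that
  manifest MD5 checksums are platform-stable; full precision is kept in
  memory and in the returned objects.
* Every random draw in a `run_analysis()` call derives from the single
  config seed; two runs with the same config produce byte-identical
  outputs (checked by checksum in the test suite).
* Degenerate inputs fail loudly and early: empty intervals and duplicate
  region ids at parse time with line numbers, counts exceeding library
  totals at panel construction, single-genotype panels at `panel_mean()`,
  zero-variance correlation inputs, empty marker pairings. The one
  deliberate warning (not error) is a filter that removes everything —
  an extreme threshold choice, not a malformed input.

## Problem sizes in the test suite

Unit and property tests run on panels between 4×2 and 280×1184; the
recovery properties are exercised at the full default scale (280
genotypes × 1184 regions) noiselessly and over ten Poisson seeds, and the
determinism check runs the complete pipeline twice at 120×400. The
acceptance script repeats the full-scale runs from scratch at a
caller-supplied seed.

## Known limitations

Calls are per-region states, not integer copy numbers; no segmentation or
HMM smoothing across adjacent regions; no distinction between a true HNRT
and coincident independent events; heterozygous intermediate states are
simulated but sit exactly on the call boundaries by construction; and the
generator does not model GC bias, mappability, duplicates or mapping error,
so recovery rates on synthetic panels are upper bounds for real data.
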