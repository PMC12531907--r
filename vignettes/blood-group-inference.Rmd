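---
title: "Inferring red-cell antigen phenotypes from genomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring red-cell antigen phenotypes from genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodgroupr)
```

## The problem

Serological typing measures whether a red cell expresses an antigen;
genome sequencing measures the variants that determine expression.
`bloodgroupr` converts phased small-variant genotypes plus read-depth
evidence into predicted phenotypes for 24 antigens across nine blood group
systems (ABO, Rh, Kell, Kidd, Duffy, Lewis, Lutheran, MNS, P1), compares
the predictions with a serology grade table, and triages each discordance
by scanning for rare private variants with a plausible functional effect.

Three classes of evidence are combined:

* **Phased genotypes at panel sites.** Most antigens are determined by one
  or a few SNVs/indels whose per-haplotype configuration matters: ABO
  needs to know whether the inactivating frameshift sits in cis or in
  trans to the B-defining missense variants; Duffy expression is abolished
  only when the GATA-box promoter variant is in cis with the allele it
  silences; FUT3 (Lewis) haplotypes are null only for specific cis
  combinations of missense variants.
* **Depth ratios at RHD/RHCE.** The RHD deletion and the RHCE exon-2
  gene-conversion (C antigen) leave no clean genotype signal in short-read
  data; both are read from MAPQ-filtered coverage ratios.
* **Windowed copy-number segmentation over the glycophorins.** The GYPB
  deletion and the Dantu GYPB-GYPA hybrid are called from a five-state
  HMM over normalized 1600-bp window coverage.

## Rh depth model

Let $d$ be the mean MAPQ-filtered depth of a region and note that RHCE is
present at two copies in everyone. RHD zygosity uses

$$ r_\mathrm{zyg} = \frac{d(\mathrm{RHD})}{d(\mathrm{RHCE})/2}, $$

whose ideal values are 0, 1 and 2 for zero, one and two RHD copies.  The
classification bands are configuration (`rh_thresholds()`): null
$[0, 0.5]$, hemizygous $[0.6, 1.5]$, homozygous $[1.6, 2.5]$.  Values in
the gaps are reported as an explicit no-call rather than rounded into the
nearest band: the bands are disjoint by construction, and a ratio between
them is a QC signal, not a genotype.

The C-carrying RHCE haplotype has RHD-like sequence across exon 2, so its
exon-2 reads align to RHD exon 2.  The **paralog-aware (modified)** method
therefore compares RHCE exon-2 depth with per-copy RHD exon-2 depth,

$$ r_\mathrm{Cc} = \frac{d(\mathrm{RHCE\ ex2})}{d(\mathrm{RHD\ ex2}) / n_\mathrm{RHD}}, $$

with ideal values 2, 2/3 and 0 for c/c, C/c and C/C at $n_\mathrm{RHD}=2$
(2, 0.5, 0 at one copy).  Band sets are zygosity-specific: $\ge 1.5$ /
$[0.5, 1.4]$ / $<0.5$ for two-copy RHD and $>0.67$ / $[0.1, 0.66]$ /
$<0.1$ for hemizygotes, again with gap no-calls (the hemizygous boundary
pair leaves $[0.66, 0.67]$ as a gap, which we keep as printed rather than
closing it by fiat).  The **whole-gene (legacy)** method compares RHCE
exon-2 depth with the rest of the RHCE locus and is the only route for
RHD-null samples; its bands $\ge 0.75$ / $[0.25, 0.74]$ / $<0.25$ follow
the expected depletion from zero, one or two converted haplotypes.

Two numerical choices matter here:

* **The "exon 2" interval is a tract, not the 187-bp exon.**  The
  conversion that creates the C allele extends into the flanking introns,
  and a depth estimate over a ~8 kb paralog-divergent tract has a
  coefficient of variation ~5% at 16x, against ~20% for the bare exon.
  The tract coordinates live in the panel's region table and can be
  replaced.
* **Locus means exclude the exon-2 tract.**  The tract's depth moves with
  the sample's C genotype (reads leave RHCE exon 2 and pile onto RHD exon
  2), so leaving it inside the locus means would leak C-genotype signal
  into the zygosity denominator.  "The rest of the gene" is the correct
  denominator for both ratios.

## Glycophorin HMM

Window coverage is normalized to copy units against a copy-number-stable
flank (expected value 2 at diploid windows), low-mappability windows are
masked (a shipped BED; replaceable), and the Viterbi path is decoded under:

* states $\{0, 1, 2, 3, 4\}$ copies; higher coverage ends up as
  `"complex"` rather than extending the state space;
* Gaussian emissions centred on the state copy number.  1600-bp window
  means at 16x average ~170 reads, so the Gaussian is an adequate
  approximation; the standard deviation is estimated per sample from the
  flank windows (MAD about 2) with a floor of 0.1 so that noise-free
  input remains decodable;
* a uniform switch probability of $10^{-4}$ per window between any two
  states.  The prior work this windowing follows does not print its
  transition values; $10^{-4}$ makes a single-window state flip cost
  about as much as a 9-sigma emission residual, which suppresses
  speckle while leaving multi-window events (the ~9-window GYPB
  deletion) essentially free to open and close.

Classification is template-based: a heterozygous GYPB deletion requires
one-copy states over at least 80% of the GYPB windows; Dantu requires a
three-or-more-copy segment covering at least 60% of the shipped
GYPB-GYPA hybrid template interval.  Short-read depth cannot place exact
hybrid breakpoints, so Dantu recognition is deliberately a pattern match,
not a breakpoint call.  With the switch probability driven toward zero on
noise-free input, Viterbi reduces to per-window rounding to the nearest
state mean -- this is the oracle the decoder is tested against.

## The phenotyping rules

Each system is a small rule set over per-haplotype states; provenance
(the named allele that fired) is attached to every call.  Conventions
that were genuinely open and had to be fixed:

* **The reference genome is O at ABO.**  VCF "0" at the c.261 site is the
  inactivating frameshift; the alternate allele is the functional G.  A
  haplotype is O first (frameshift), then B if both B-defining variants
  are in cis, else A.
* **M/N orientation** is fixed by the printed genotype-to-phenotype
  pairs (all-hom-ref is M-N+), not by amino-acid convention, because
  ref/alt labelling at the three GYPA sites is ambiguous in the source
  tables.
* **Weak expression**: the weak-E allele (c.602G>C), the weak-Fyb allele
  (rs34599082 in cis with an expressed Fyb), and the Dantu haplotype's s
  antigen are reported as `weak-positive`, which counts as positive for
  concordance.  Serology-side weak-D resolution is a serology convention;
  the genotype side never outputs "weak D".
* **FUT3 null haplotypes** are the two cis combinations
  (c.202T>C + c.314C>T) and (c.59T>G + c.1067T>A); the definition is
  configurable in the allele table.
* **No-calls are conservative**: they propagate to the antigen call and
  count as incorrect in every accuracy statistic.  The published cohort
  had no no-calls, but a policy is still required; counting them correct
  would let a degenerate caller look accurate.
* **Unphased heterozygotes** at multi-variant systems are resolved to the
  most frequent known configuration (B-defining variants in cis opposite
  the O frameshift; FUT3 202/314 in trans; GATA in cis with Fyb) and
  flagged with a warning.  Phase is consumed, never computed: the input
  VCF is expected to be statistically phased upstream.

## What the synthetic cohorts emulate

`sample_cohort()` draws haplotype classes per system under Hardy-Weinberg
at configured frequencies (defaults match the study cohort's allele
frequencies), encodes cis-linkage in the class definitions, and derives
genotypes, depth and serology from one truth.  The depth model gives each
haplotype half the diploid mean (default 16x), reassigns RHCE*C
exon-2-tract reads to RHD exon 2 at `mismap` (default 1: the conversion
is sequence-identical to RHD, so confident alignments land there), and
adds negative-binomial read-count noise with size 60, i.e. CV ~0.15 for a
1600-bp window at 16x.  Serology grades are 0 for negative, 1 for weak
reactions, 2-4 for positive.

A second mismap parameter, `cross_mismap` (default 0), sends a fraction
of RHD-origin exon-2 reads onto RHCE exon 2, emulating background
bidirectional paralog cross-mapping.  This is the regime in which the
whole-gene C/c method degrades while the zygosity-aware method holds: the
contamination of RHCE exon 2 scales with RHD copy number, which the
whole-gene ratio cannot see.  On the idealized one-way model both methods
classify perfectly -- the published deficit of the whole-gene method
arises from real-data mapping artifacts, and `cross_mismap` is our
explicit, labelled stand-in for them, exercised in the property tests at
0.25 on an RHD-homozygous cohort.

`published_fixture()` is not sampled: it is a hand-constructed,
argument-free 100-donor cohort whose serology positivity counts equal the
published antigen-frequency column, whose twelve discordance events carry
their printed genotypes, and whose panel allele counts are exact wherever
the published frequency is integral over 200 haplotypes (7 K alleles, 2
Kpa, 3 Lua, 3 weak-E, 3 GYPB-deletion, 2 Henshaw, 1 Dantu...).  Where a
published allele frequency is arithmetically incompatible with the
serology counts under the no-null-allele assumption (the C haplotype,
the GYPA M triple, GYPB c.143C>T), the serology counts win and the
realized haplotype counts differ from the printed frequency by a few
copies.  The pseudogene-insertion frequency 0.0376 is not integral over
200 haplotypes (it derives from a larger jointly-called dataset); the
fixture carries 8 copies.  Fixture depth is noise-free and serology
grades follow a deterministic cycle, so every byte of the fixture is
reproducible without a seed.

What passing tests on these cohorts does **not** show: robustness to
alignment artifacts other than the modelled exon-2 mismapping, to GC or
batch effects in coverage (no GC correction is applied anywhere), to
genotyping error outside the injected miscall mechanism, or to serology
grading variation.  The generator emulates the statistical structure the
method assumes, not the failure modes of a sequencing pipeline.

## Discordance accounting and triage

Accuracies follow the two published definitions: per antigen (fraction of
donors with that antigen's expression correctly predicted) and per system
(every tested antigen of the system must match).  The headline average is
the unweighted mean of the nine system accuracies, reported to one
decimal.  Discordances are enumerated one per donor-subsystem, with M/N
and S/s counted separately inside MNS -- so one donor can contribute two
events, and the fixture's twelve events come from eleven donors.

Triage searches the cohort VCF for variants carried by the discordant
donor, with cohort allele count at most 2, inside the implicated system's
gene bodies or inside supplied regulatory intervals (transcription-factor
binding-site BEDs).  Consequence classes are rule-based from the shipped
transcript annotation (frameshift / missense / splice-region /
regulatory-overlap); gene-body variants with none of these predicted
effects are not candidates.  Panel sites are excluded -- they are the
predictors whose failure is being investigated.

## Problem sizes

The analysis scripts and tests run the full pipeline on the 100-donor
fixture (3200 depth windows and 34 VCF sites per donor), 100-donor
sampled cohorts for the depth-method comparisons, 50 seeded replicates
for deletion recovery, and a 10000-donor genotype-only cohort for
allele-frequency recovery.  All of it completes in well under a minute
per script on one CPU.

## Known limitations

* Coordinates for panel rsIDs were compiled by hand; positions inside
  loci are internally consistent with the shipped generator but should be
  re-verified against dbSNP before use on real VCFs, and ref/alt are
  stored in coding-strand orientation for minus-strand genes.
* One source table prints the B-defining change as c.803G>A where the
  allele registry lists c.803G>C; the panel stores the printed label and
  matches by position, so the discrepancy is flagged, not silently
  corrected.
* The P1 alternative predictor (rs66781836) is wired in as a selectable
  mode but ships with genotypes mirroring the three-SNV consensus in the
  fixture; its published accuracy difference is not reproducible from
  printed data.
* ABO subtype alleles, Rh variant alleles beyond the panel, U/Mia/Dantu
  antigen typing, CRAM input and re-phasing are out of scope.
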