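---
title: "Detecting allele-specific expression and imprinting in reciprocal crosses"
author: "crossASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific expression and imprinting in reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In a diploid organism the two alleles of an autosomal gene are expected to
be expressed at a 1:1 ratio. Genes that deviate — through genomic
imprinting (parent-of-origin-dependent silencing), cis-regulatory variation
or random monoallelic expression — show allele-specific expression (ASE).
In inbred model organisms ASE is detected by crossing two strains
reciprocally and tracking strain-diagnostic SNPs in the F1 transcriptome.
Outbred livestock make this harder: most heterozygous SNPs are
uninformative about parental origin, so ASE discovery must be restricted to
sites that are homozygous within each parent but different between the two
parents (breeds). `crossASE` implements that complete discovery procedure
for a two-breed reciprocal cross — in the motivating design, Korean native
pig (KNP) and Landrace parents, with the neocortex transcriptome of pooled
F1 littermates — together with a generative simulator of the whole design,
so that every stage can be exercised and calibrated at desk scale.

## The procedure

The pipeline inverts a simple generative model, stage by stage:

1. **Site filtration** (`filter_sites`). Called variant sites are removed
   for strong strand bias (FS > 30), low quality by depth (QD < 2),
   SNP clusters (3 or more SNPs within a 35 bp window), and low read depth
   (any parent below DP 3 under individual mapping, any per-breed joint
   sample below DP 6). Inequalities are strict: FS = 30, QD = 2 and DP = 3
   all pass. A site failing several rules is attributed to the first
   failing rule in the order FS, QD, cluster, DP, making the removal report
   reproducible. The cluster rule is evaluated per chromosome on the set
   surviving the quality filters, with an inclusive window span
   (`pos_last - pos_first <= 34` for a 35 bp window); the window arithmetic
   of the GATK-style rule is not fully standardized, so this convention is
   documented and oracle-tested against brute-force window enumeration.
2. **Exon assignment** (`read_bed`, `assign_exonic`). Only exonic SNPs are
   usable in RNA data. Exon intervals are unioned per gene
   (via `GenomicRanges`); a SNP inside the exons of two overlapping genes
   contributes to both genes, a choice that is logged so users can exclude
   such sites.
3. **Informative-SNP selection** (`select_informative`). A SNP is
   informative when every parent (strategy I) or per-breed joint sample
   (strategy II) is homozygous and the two breeds carry different alleles;
   then every F1 is heterozygous with known parental origin of each allele.
   Strategy I by default additionally requires the two same-breed parents
   to agree — the reciprocal design needs a consistent breed-to-allele map.
   Whether the original procedure demanded this agreement or only a
   per-cross dam/sire difference is ambiguous, so the weaker reading is
   available as `require_breed_agreement = FALSE`, in which case the extra
   sites carry per-sample allele columns and are oriented per cross via the
   design's sire sample.
4. **Orientation and the paternal read ratio** (`orient_counts`,
   `paternal_read_ratio`). In each pool the sire breed's allele is
   paternal; the paternal read ratio is `paternal / (paternal + maternal)`,
   0.5 under balanced expression, undefined when a pool has no reads.
5. **Candidate flag** (`flag_candidate`). A gene is a candidate when any
   per-pool ratio lies at or outside the 0.3/0.7 band. The boundaries are
   inclusive: the published worked example lists a gene with a ratio cell
   of exactly 0.3 among its candidates, which a strict reading would
   exclude.
6. **Significance** (`g_test`, `evaluate_gene`). Deviation from 1:1 is
   tested with the G-test of goodness-of-fit,
   `G = 2 * sum(O * ln(O/E))`, `E = total/2`, compared to a chi-square
   distribution. The unit of testing was genuinely open: testing the
   paternal-vs-maternal totals pooled over all four pools would cancel for
   allele-dominant genes (ratios near 1,1,0,0), yet such genes are reported
   significant in the motivating study. The default therefore sums per-pool
   G statistics (G is additive over independent pools) with degrees of
   freedom equal to the number of pools with reads, which detects deviation
   in any direction per pool; a per-(SNP, pool) mode is available as
   `per_snp = TRUE`. The Williams small-sample correction
   (`G / (1 + 1/(2n))`) is off by default, matching the plain-G convention.
   No multiple-testing correction is applied by default (raw `p < 0.05`);
   Benjamini–Hochberg is available as `bh = TRUE`.
7. **Pattern classification** (`evaluate_gene`). Per-cross mean ratios
   `r1`, `r2` (the male and female pools of a cross are biological
   replicates; sex-specific imprinting is out of scope) are compared to the
   band: both high = paternally biased, both low = maternally biased
   (the "flipped" patterns diagnostic of imprinting), one high and one
   low = allele-dominant expression of one breed allele irrespective of
   parental origin, both inside the band = biallelic, anything else
   inconsistent, and a gene (or cross) without reads has insufficient
   data.

## The simulator

`sim_config` + `generate_dataset` produce a complete dataset: a
four-parent VCF, a per-breed joint VCF, an exon BED, four per-pool allele
count tables and a truth table. Its defaults are the study conditions of
the motivating design, chosen once:

| parameter | default | rationale |
|---|---|---|
| `dna_depth_individual` | 4 | the parents were sequenced at ~4.1–4.3x; joint per-breed samples at ~8.2x (the simulator pools the same reads, so joint DP is exactly the sum) |
| `rna_depth` | 15 | exonic RNA depth of the pooled libraries was ~12–15x |
| `pool_size` | 3 | each RNA library pooled equal RNA of three same-sex littermates |
| `snps_per_gene` | 3 | few informative SNPs per gene is the regime the design operates in |
| `breed_divergence` | 0.03 | fixed inter-breed differences are a small minority of segregating sites in diverged but conspecific pig breeds |
| `within_breed_het` | 0.15 | moderate within-breed heterozygosity at segregating sites |
| `ase_mode_fractions` | 0.85 / 0.05 / 0.05 / 0.05 | ASE genes are a small minority of testable genes (the motivating study found 9 among 336) |
| `dominant_share` | 0.85 | keeps allele-dominant genes near the 0.7 decision boundary instead of a degenerate 1.0 |
| `qc_violation_rate` | 0.02 | a small fraction of sites carries filter-violating FS/QD annotations |

Genotype observation uses a naive consensus caller: depth is Poisson (or
fixed, for controlled experiments), each read samples one of the parent's
two alleles, a site is called missing at depth 0, hom when all reads agree,
het otherwise. This is deliberately not a likelihood caller: it reproduces
exactly the phenomenon that matters downstream — at depth `d` a true het is
mis-called hom with probability `2^(1-d)` (25% at 3x), which both destroys
true informative sites and fabricates false ones, and which the DP filters
guard against. RNA counts use Poisson totals with binomial read allocation
(beta-binomial via `overdispersion > 0`, default off — pooled RNA may be
overdispersed but the magnitude is unknown, so the knob exists and the
default does not pretend to know it). For allele-dominant genes the favored
share attaches to the favored *breed's* haplotype, not to a parent, which
is what makes the pattern flip with the cross.

The simulator does **not** model read-level sequencing error, alignment or
reference bias, library-preparation effects, RNA editing, splicing
variation, or sex chromosomes. Passing recovery tests on simulated data
therefore demonstrates that the inference machinery is correct under the
stated generative assumptions, not that real data meet those assumptions.

Cross labels follow the dam-first convention (`"KxL"` = KNP dam x Landrace
sire) because the motivating study never states its own; the convention is
configurable (`default_cross_design(dam_first = FALSE)`) and every
classification is symmetric under it (swapping dam and sire breeds maps
each ratio `r` to `1 - r` and leaves G unchanged — a tested invariant).

## Numerical and degenerate-input choices

* Ratios are computed in full precision and rounded to three decimals only
  in output tables.
* A pool with zero reads has an undefined ratio and contributes no degrees
  of freedom; a gene whose every pool (or either cross) lacks reads is
  labeled `insufficient_data` rather than an error.
* Zero cells contribute 0 to G; G is clamped at 0 against floating-point
  rounding at exact 1:1.
* Multi-allelic records and indels are dropped on read, never decomposed:
  the informative-SNP rule and the ratio are defined for two alleles.
* Missing FS/QD annotations parse as 0 (not filtered on that criterion)
  with a warning, so partially annotated files remain usable.
* All randomness flows through explicit seeds; identical configuration
  gives byte-identical datasets.

## Problem sizes used in the test suite

The validation suite runs the worked nine-gene example (instantaneous),
Monte-Carlo property checks (100,000 genotype draws for the het-mis-call
law; 100 seeds for the strategy comparison), and parameter recovery at
1,200 genes with a 2,000-gene type-I-error calibration — chosen as the
smallest sizes at which the binomial Monte-Carlo error is well inside the
asserted tolerances. At these sizes the whole suite runs in well under a
minute on one CPU. Larger simulations only shrink the Monte-Carlo error.

## Known limitations

* The G-test is asymptotic; at very low counts (a handful of reads per
  pool) it is slightly anticonservative. The Williams correction is
  available, and the type-I calibration test documents the achieved level
  (~0.05 at the default depths).
* With ~4x parents, strategy I loses most truly informative sites to the
  DP filter and het mis-calls; strategy II roughly doubles the yield. This
  is the expected behaviour of the design, not a defect of the
  implementation, and is asserted qualitatively (II >= I in >= 95% of
  seeds), not as absolute counts.
* Genes are tested independently; linkage between SNPs of a gene is
  modeled only through shared haplotypes, not through read-level phasing.
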