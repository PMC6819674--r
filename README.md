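# crossASE

Discovery of allele-specific expression (ASE) and candidate genomic
imprinting from **reciprocal crosses in outbred animals** — for geneticists
who have whole-genome sequence of the parents of a two-breed reciprocal
cross (e.g. Korean native pig × Landrace) and RNA-seq of pooled F1
offspring, and want to know which genes preferentially express one
parental allele.

## The method

Because outbred parents are not identical by descent, only *informative*
SNPs — homozygous within each parent but different between the two breeds —
reveal the parental origin of an expressed allele: at such a site every F1
is heterozygous and each allele's origin is known. The pipeline:

1. filters called variant sites (Fisher strand FS > 30, quality-by-depth
   QD < 2, clusters of ≥ 3 SNPs in 35 bp, read depth DP < 3 per parent
   under individual mapping — *strategy I* — or DP < 6 per same-breed joint
   sample — *strategy II*, which doubles effective depth);
2. keeps exonic SNPs (BED annotation, exons unioned per gene) and selects
   informative SNPs under either mapping strategy, with an overlap report
   between the two;
3. orients each pool's RNA allele counts by parental origin (the sire
   breed's allele is paternal) and computes the **paternal read ratio**

   ```
   paternal read ratio = paternal reads / (paternal + maternal reads)
   ```

   per gene and pool (maternal ratio = 1 − paternal ratio);
4. flags genes with any pool ratio ≤ 0.3 or ≥ 0.7 as ASE candidates, and
   tests deviation from the 1:1 expectation with the **G-test of
   goodness-of-fit**, `G = 2·Σ O·ln(O/E)` with `E = total/2`, summing
   per-pool G statistics (df = pools with reads) against a chi-square
   distribution;
5. classifies each gene's cross pattern from the per-cross mean ratios:
   high in both crosses = paternally biased, low in both = maternally
   biased (the "flipped" allele pattern diagnostic of imprinting), high in
   one cross and low in the reciprocal = allele-dominant expression of one
   breed allele, inside the band = biallelic.

A synthetic-data generator (`sim_config`, `generate_dataset`) emulates the
whole design — Mendelian transmission, ~4× parental genome coverage with
naive consensus calling (so true hets are mis-called hom with probability
`2^(1−d)`), same-breed joint samples at summed depth, pooled RNA counts at
~15 reads/SNP/pool under configurable ASE modes — with a per-gene truth
table, so the pipeline's operating characteristics can be measured.
See `vignettes/reciprocal-cross-ase.Rmd` for the model, parameter
rationale and limitations.

## Worked example

```r
library(crossASE)
cfg <- sim_config(n_genes = 300, breed_divergence = 0.3, seed = 42,
                  ase_mode_fractions = c(biallelic = 0.7,
                                         paternal_imprinted = 0.1,
                                         maternal_imprinted = 0.1,
                                         allele_dominant = 0.1))
r <- run_pipeline(cfg, "demo", strategy = "both")
r$selection$report
#>    strategy raw snp removed_fs removed_qd removed_cluster removed_dp filtered exonic informative
#> I         I 900 900         10         14               0        571      305    305         109
#> II       II 900 900         10         14               0        301      575    575         210
unlist(r$selection$overlap)
#>   count_i  count_ii    shared  unique_i unique_ii
#>       109       210       109         0       101
r$ase$summary$n_genes       # 99 genes had informative SNPs with reads
r$ase$summary$n_significant # 27 at raw p < 0.05
r$ase$confusion             # called pattern vs simulated truth
```

Reading the numbers: of 900 simulated sites, the low 4× parental depth
costs strategy I 571 sites to the DP < 3 filter where the ~8× joint
samples lose only 301 to DP < 6 — joint mapping roughly doubles the
informative yield (109 vs 210), the qualitative behaviour the reciprocal
design shows on real low-coverage data. The confusion matrix shows every
fully imprinted gene recovered with the correct parent-of-origin label and
dominant genes separated from imprinted ones by the reciprocal flip.

Per-gene output (`r$ase$results`) carries the four per-pool paternal
ratios, G, df, p, the candidate flag and the pattern label; e.g. a
maternally imprinted gene appears as ratios `0 0 0 0` with
`pattern = "maternal_biased"`, `p ≈ 1e-18` at ~45 reads/pool.

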