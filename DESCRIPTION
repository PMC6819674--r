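Package: crossASE
Title: Allele-Specific Expression and Imprinting Discovery from Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE) and candidate genomic
    imprinting from reciprocal-cross designs in outbred animals. From parental
    whole-genome genotype calls and pooled offspring RNA allele counts, the
    package filters variant sites, selects breed-informative exonic SNPs under
    an individual or same-breed joint mapping strategy, computes the paternal
    read ratio per gene and pool, tests deviation from the 1:1 allelic
    expectation with a G-test of goodness-of-fit, and classifies genes as
    paternally biased, maternally biased, allele-dominant or biallelic. A
    synthetic-data generator emulates the two-breed reciprocal cross with
    low-coverage parental genotyping and pooled RNA sequencing so the whole
    pipeline can be exercised and calibrated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
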