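#' Configure the reciprocal-cross simulator
#'
#' Defines the study conditions the synthetic data emulate: a two-breed
#' reciprocal cross with low-coverage parental whole-genome genotyping
#' (~4x per parent, ~8x for a same-breed joint sample) and pooled offspring
#' RNA sequencing (~15 reads per exonic SNP per pool, pools of three
#' same-sex littermates).
#'
#' @param n_genes number of simulated genes.
#' @param snps_per_gene exonic SNP sites per gene.
#' @param breed_divergence probability that a segregating site is fixed for
#'   different alleles in the two breeds (a breed-informative site).
#' @param within_breed_het per-site probability that a parent is
#'   heterozygous at a non-divergent site.
#' @param dna_depth_individual mean genome read depth per parent; the
#'   same-breed joint sample has twice this depth.
#' @param rna_depth mean RNA read count per SNP per offspring pool.
#' @param pool_size offspring per pool.
#' @param ase_mode_fractions named proportions of genes in each ASE mode
#'   (`biallelic`, `paternal_imprinted`, `maternal_imprinted`,
#'   `allele_dominant`); must sum to 1.
#' @param dominant_share expression share of the favored breed allele in
#'   `allele_dominant` genes. The default 0.85 keeps simulated dominant
#'   genes near the 0.7 decision boundary rather than at a degenerate 1.0.
#' @param imprint_leakage residual expression share of the silenced allele
#'   in imprinted genes (0 = complete imprinting).
#' @param overdispersion beta-binomial overdispersion rho for read
#'   allocation within a SNP; 0 (default) gives pure binomial thinning.
#' @param qc_violation_rate fraction of sites given an FS or QD annotation
#'   that violates the quality filters (FS > 30 or QD < 2).
#' @param seed RNG seed; every derived dataset is a deterministic function
#'   of the configuration including the seed.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_genes = 200,
                       snps_per_gene = 3,
                       breed_divergence = 0.03,
                       within_breed_het = 0.15,
                       dna_depth_individual = 4,
                       rna_depth = 15,
                       pool_size = 3,
                       ase_mode_fractions = c(biallelic = 0.85,
                                              paternal_imprinted = 0.05,
                                              maternal_imprinted = 0.05,
                                              allele_dominant = 0.05),
                       dominant_share = 0.85,
                       imprint_leakage = 0,
                       overdispersion = 0,
                       qc_violation_rate = 0.02,
                       seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be >= 1")
  if (!is_count(snps_per_gene) || snps_per_gene < 1)
    stopf("snps_per_gene must be >= 1")
  if (!is_count(pool_size) || pool_size < 1) stopf("pool_size must be >= 1")
  for (p in c(breed_divergence = breed_divergence,
              within_breed_het = within_breed_het,
              imprint_leakage = imprint_leakage,
              overdispersion = overdispersion,
              qc_violation_rate = qc_violation_rate)) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
      stopf("probabilities must lie in [0, 1]")
  }
  if (dna_depth_individual <= 0 || rna_depth <= 0)
    stopf("depths must be > 0")
  if (dominant_share <= 0.5 || dominant_share > 1)
    stopf("dominant_share must lie in (0.5, 1]")
  f <- ase_mode_fractions
  if (!all(ASE_MODES %in% names(f)))
    stopf("ase_mode_fractions must name all of: %s",
          paste(ASE_MODES, collapse = ", "))
  f <- f[ASE_MODES]
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stopf("ase_mode_fractions must be non-negative and sum to 1")
  structure(list(n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 breed_divergence = breed_divergence,
                 within_breed_het = within_breed_het,
                 dna_depth_individual = dna_depth_individual,
                 rna_depth = rna_depth,
                 pool_size = as.integer(pool_size),
                 ase_mode_fractions = f,
                 dominant_share = dominant_share,
                 imprint_leakage = imprint_leakage,
                 overdispersion = overdispersion,
                 qc_violation_rate = qc_violation_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d genes x %d SNPs; divergence %.3g, het %.3g\n",
    "  DNA depth %.3g (joint %.3g), RNA depth %.3g, pool size %d, seed %d\n",
    "  modes: %s\n"),
    x$n_genes, x$snps_per_gene, x$breed_divergence, x$within_breed_het,
    x$dna_depth_individual, 2 * x$dna_depth_individual, x$rna_depth,
    x$pool_size, x$seed,
    paste(names(x$ase_mode_fractions), x$ase_mode_fractions,
          sep = "=", collapse = ", ")))
  invisible(x)
}
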