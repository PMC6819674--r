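#' Simulate pooled offspring RNA allele counts
#'
#' Transmits parental haplotypes to pooled F1 offspring (each offspring
#' inherits one uniformly chosen allele from its dam and one from its sire
#' at every site — Mendelian transmission) and generates RNA read counts per
#' SNP and pool. Reads per (pool, SNP) are Poisson with mean `rna_depth`;
#' each read picks a pool member uniformly and then the paternal or maternal
#' haplotype of that member according to the gene's ASE mode: the expected
#' paternal share for imprinted and biallelic genes, or — for
#' allele-dominant genes — the favored *breed's* haplotype with the favored
#' share, irrespective of which parent transmitted it. The read reports the
#' base carried by the chosen haplotype, and counts are tallied per observed
#' ref/alt base.
#'
#' @param tg a `true_genotypes` object (carries the per-gene truth table).
#' @param design a [cross_design]; its dam/sire samples must exist in `tg`.
#' @param rna_depth mean reads per SNP per pool.
#' @param pool_size offspring per pool.
#' @param overdispersion beta-binomial rho (0 = binomial).
#' @param seed RNG seed.
#' @return A data.frame of allele count records (`chrom, pos, pool_id,
#'   count_ref, count_alt`), one row per site and pool. The simulated
#'   offspring haplotypes are attached as attribute `"offspring"` (a list
#'   per pool with `pat`/`mat` allele matrices, sites x members) so
#'   transmission can be audited.
#' @export
simulate_offspring_counts <- function(tg, design = default_cross_design(),
                                      rna_depth = 15, pool_size = 3,
                                      overdispersion = 0, seed = 1L) {
  stopifnot(inherits(tg, "true_genotypes"), inherits(design, "cross_design"))
  unknown <- setdiff(c(design$crosses$dam, design$crosses$sire), tg$parents)
  if (length(unknown) > 0)
    stopf("cross design references unknown parent '%s'", unknown[1])
  n <- nrow(tg$sites)
  truth <- tg$truth
  ti <- match(tg$sites$gene_id, truth$gene_id)
  mode <- truth$true_mode[ti]
  tpf <- truth$true_paternal_fraction[ti]
  favored <- truth$favored_breed[ti]

  with_seed(seed, {
    out <- vector("list", nrow(design$pools))
    offspring <- list()
    for (k in seq_len(nrow(design$pools))) {
      pool <- design$pools$pool_id[k]
      cid <- design$pools$cross_id[k]
      ci <- match(cid, design$crosses$cross_id)
      sire <- design$crosses$sire[ci]
      dam <- design$crosses$dam[ci]
      sb <- design$breeds[[sire]]

      # Mendelian transmission: one allele from each parent per member
      pat <- matrix(0L, n, pool_size)
      mat <- matrix(0L, n, pool_size)
      for (j in seq_len(pool_size)) {
        pick_s <- stats::runif(n) < 0.5
        pat[, j] <- ifelse(pick_s, tg$hap1[, sire], tg$hap2[, sire])
        pick_d <- stats::runif(n) < 0.5
        mat[, j] <- ifelse(pick_d, tg$hap1[, dam], tg$hap2[, dam])
      }
      offspring[[pool]] <- list(pat = pat, mat = mat, sire = sire, dam = dam)

      # per-site probability a read picks the paternal haplotype
      p_pat <- ifelse(mode == "allele_dominant",
                      ifelse(sb == favored, tpf, 1 - tpf),
                      tpf)
      # probability the reported base is REF, averaged over pool members
      p_ref <- rowMeans(p_pat * (1L - pat) + (1 - p_pat) * (1L - mat))
      n_reads <- stats::rpois(n, rna_depth)
      if (overdispersion > 0) {
        nu <- 1 / overdispersion - 1
        mid <- p_ref > 0 & p_ref < 1
        p_ref[mid] <- stats::rbeta(sum(mid), p_ref[mid] * nu,
                                   (1 - p_ref[mid]) * nu)
      }
      count_ref <- stats::rbinom(n, n_reads, p_ref)
      out[[k]] <- data.frame(
        chrom = tg$sites$chrom, pos = tg$sites$pos, pool_id = pool,
        count_ref = count_ref, count_alt = n_reads - count_ref,
        stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, out)
    rownames(counts) <- NULL
    attr(counts, "offspring") <- offspring
    counts
  })
}

#' Generate a complete synthetic reciprocal-cross dataset on disk
#'
#' Runs the full generative model and writes every file the analysis
#' pipeline consumes: `parents.vcf` (four individually sequenced parents at
#' `dna_depth_individual`), `joint.vcf` (two per-breed samples built by
#' pooling the *same* read draws of the two same-breed parents, so the joint
#' depth at each site is exactly the sum of the individual depths),
#' `exons.bed`, one `counts_<pool>.tsv` per offspring pool, and
#' `truth.tsv`. Identical configurations (including the seed) produce
#' byte-identical directories.
#'
#' @param config a [sim_config].
#' @param outdir output directory (created if needed).
#' @param design a [cross_design].
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
generate_dataset <- function(config, outdir,
                             design = default_cross_design()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s0 <- config$seed
  tg <- simulate_true_genotypes(config, design, seed = derive_seed(s0, 1))
  reads <- sim_reads(tg, config$dna_depth_individual, derive_seed(s0, 2))
  qc <- sim_site_qc(nrow(tg$sites), config$qc_violation_rate,
                    derive_seed(s0, 3))
  parents_vt <- obs_from_reads(tg, reads$dp, reads$ref_reads, qc, tg$parents)
  merged <- merge_reads_by_breed(tg, reads)
  joint_vt <- obs_from_reads(tg, merged$dp, merged$ref_reads, qc,
                             colnames(merged$dp))
  counts <- simulate_offspring_counts(
    tg, design, rna_depth = config$rna_depth, pool_size = config$pool_size,
    overdispersion = config$overdispersion, seed = derive_seed(s0, 4))

  paths <- list(
    parents_vcf = file.path(outdir, "parents.vcf"),
    joint_vcf = file.path(outdir, "joint.vcf"),
    exons_bed = file.path(outdir, "exons.bed"),
    truth_tsv = file.path(outdir, "truth.tsv"))
  write_vcf(parents_vt, paths$parents_vcf)
  write_vcf(joint_vt, paths$joint_vcf)
  write_bed(tg$exons, paths$exons_bed)
  write_truth(tg$truth, paths$truth_tsv)
  paths$counts_tsv <- character(0)
  for (pool in design_pools(design)) {
    p <- file.path(outdir, paste0("counts_", pool, ".tsv"))
    write_counts(counts[counts$pool_id == pool, ], p)
    paths$counts_tsv <- c(paths$counts_tsv, p)
  }
  invisible(list(truth_genotypes = tg, parents = parents_vt,
                 joint = joint_vt, counts = counts, design = design,
                 paths = paths))
}
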