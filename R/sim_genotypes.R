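#' Simulate true parental genotypes for a reciprocal cross
#'
#' Lays `n_genes` genes out over 18 autosomes, places `snps_per_gene`
#' exonic SNP sites per gene, and draws the four parents' true diploid
#' genotypes. With probability `breed_divergence` a site is fixed hom-ref in
#' one breed and hom-alt in the other (a truly breed-informative site);
#' otherwise each parent is independently heterozygous with probability
#' `within_breed_het` or homozygous for a random allele. Each gene is also
#' assigned a ground-truth ASE mode and expected paternal expression share.
#'
#' @param config a [sim_config].
#' @param design a [cross_design] naming the parent samples and breeds.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A `true_genotypes` object: site table (with the true
#'   informativeness flag), two haplotype matrices (0 = ref, 1 = alt;
#'   sites x parents), the exon layout, and the per-gene truth table
#'   (`gene_id`, `true_mode`, `true_paternal_fraction`, `favored_breed`,
#'   `snp_positions`).
#' @export
simulate_true_genotypes <- function(config, design = default_cross_design(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "cross_design"))
  parents <- names(design$breeds)
  breeds <- design$breeds
  ng <- config$n_genes
  s <- config$snps_per_gene
  with_seed(seed, {
    gidx <- seq_len(ng)
    chrom <- as.character(((gidx - 1) %% 18) + 1)
    slot <- (gidx - 1) %/% 18
    span <- 400 + 150 * s
    gstart <- 100000 + slot * (span + 3000)  # 1-based gene start
    gene_id <- sprintf("G%04d", gidx)

    # SNP sites, 150 bp apart (never forms a 35 bp cluster by layout)
    site_gene <- rep(gidx, each = s)
    pos <- gstart[site_gene] + 200 + 150 * (rep(seq_len(s), ng) - 1)
    n <- ng * s
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")

    # two overlapping exon intervals per gene; unioned on load
    half <- floor(span / 2)
    exons <- data.frame(
      chrom = rep(chrom, each = 2),
      start0 = as.integer(c(rbind(gstart - 1, gstart + half - 51))),
      end0 = as.integer(c(rbind(gstart + half + 49, gstart + span - 1))),
      gene_id = rep(gene_id, each = 2))

    np <- length(parents)
    hap1 <- matrix(0L, n, np, dimnames = list(NULL, parents))
    hap2 <- matrix(0L, n, np, dimnames = list(NULL, parents))
    informative <- stats::runif(n) < config$breed_divergence
    knp_is_alt <- stats::runif(n) < 0.5
    for (j in seq_len(np)) {
      own <- if (breeds[[parents[j]]] == "KNP") knp_is_alt else !knp_is_alt
      fixed <- as.integer(own)
      het <- !informative & stats::runif(n) < config$within_breed_het
      hom_allele <- as.integer(stats::runif(n) < 0.5)
      h1 <- ifelse(informative, fixed, ifelse(het, 0L, hom_allele))
      h2 <- ifelse(informative, fixed, ifelse(het, 1L, hom_allele))
      hap1[, j] <- h1
      hap2[, j] <- h2
    }

    mode <- sample(ASE_MODES, ng, replace = TRUE,
                   prob = config$ase_mode_fractions)
    favored <- ifelse(mode == "allele_dominant",
                      ifelse(stats::runif(ng) < 0.5, "KNP", "Landrace"),
                      NA_character_)
    tpf <- ifelse(mode == "paternal_imprinted", 1 - config$imprint_leakage,
           ifelse(mode == "maternal_imprinted", config$imprint_leakage,
           ifelse(mode == "allele_dominant", config$dominant_share, 0.5)))
    truth <- data.frame(
      gene_id = gene_id, true_mode = mode, true_paternal_fraction = tpf,
      favored_breed = favored, chrom = chrom,
      snp_positions = vapply(gidx, function(g)
        paste(pos[site_gene == g], collapse = ";"), ""),
      stringsAsFactors = FALSE)

    sites <- data.frame(chrom = chrom[site_gene], pos = as.integer(pos),
                        gene_id = gene_id[site_gene], ref = ref, alt = alt,
                        informative = informative, stringsAsFactors = FALSE)
    # store sites in genomic order (chromosomes numeric here)
    ord <- order(as.integer(sites$chrom), sites$pos)
    sites <- sites[ord, ]
    rownames(sites) <- NULL
    hap1 <- hap1[ord, , drop = FALSE]
    hap2 <- hap2[ord, , drop = FALSE]
    eord <- order(as.integer(exons$chrom), exons$start0)
    exons <- exons[eord, ]
    rownames(exons) <- NULL
    structure(list(sites = sites, hap1 = hap1, hap2 = hap2,
                   parents = parents, breeds = breeds, exons = exons,
                   truth = truth, config = config),
              class = "true_genotypes")
  })
}

#' @export
print.true_genotypes <- function(x, ...) {
  cat(sprintf(
    "true_genotypes: %d sites, %d genes, %d parents; %d truly informative\n",
    nrow(x$sites), nrow(x$truth), length(x$parents),
    sum(x$sites$informative)))
  invisible(x)
}

# Draw sequencing reads per site x parent: depth and the number of reads
# carrying the REF allele (each read samples one of the two true alleles).
sim_reads <- function(tg, mean_depth, seed,
                      depth_dist = c("poisson", "fixed")) {
  depth_dist <- match.arg(depth_dist)
  n <- nrow(tg$sites)
  np <- length(tg$parents)
  with_seed(seed, {
    dp <- if (depth_dist == "poisson")
      matrix(stats::rpois(n * np, mean_depth), n, np)
    else matrix(as.integer(round(mean_depth)), n, np)
    p_ref <- ((1L - tg$hap1) + (1L - tg$hap2)) / 2
    ref_reads <- matrix(stats::rbinom(n * np, dp, as.vector(p_ref)), n, np)
    dimnames(dp) <- dimnames(ref_reads) <- list(NULL, tg$parents)
    list(dp = dp, ref_reads = ref_reads)
  })
}

# Naive consensus caller: missing at depth 0, hom when all reads agree,
# het otherwise. At low depth this converts true hets into spurious homs
# with probability 2^(1 - depth), the artefact the DP filters guard against.
call_genotypes <- function(dp, ref_reads) {
  gt <- matrix("het", nrow(dp), ncol(dp), dimnames = dimnames(dp))
  gt[ref_reads == dp] <- "hom_ref"
  gt[ref_reads == 0L] <- "hom_alt"
  gt[dp == 0L] <- "missing"
  gt
}

# Site-level FS/QD annotations; a `rate` fraction of sites violates one of
# the quality filters (FS > 30 or QD < 2), split evenly between the two.
sim_site_qc <- function(n, rate, seed) {
  with_seed(seed, {
    viol <- stats::runif(n) < rate
    fs_viol <- viol & stats::runif(n) < 0.5
    qd_viol <- viol & !fs_viol
    fs <- round(ifelse(fs_viol, stats::runif(n, 31, 120),
                       stats::runif(n, 0, 25)), 2)
    qd <- round(ifelse(qd_viol, stats::runif(n, 0, 1.9),
                       stats::runif(n, 2.5, 35)), 2)
    data.frame(fs = fs, qd = qd)
  })
}

# Assemble a variant_table from read draws + QC annotations.
obs_from_reads <- function(tg, dp, ref_reads, qc, samples) {
  gt <- call_genotypes(dp, ref_reads)
  variant_table(
    data.frame(chrom = tg$sites$chrom, pos = tg$sites$pos,
               ref = tg$sites$ref, alt = tg$sites$alt,
               fs = qc$fs, qd = qc$qd, stringsAsFactors = FALSE),
    gt[, samples, drop = FALSE], dp[, samples, drop = FALSE], samples)
}

#' Simulate genotype observation at finite sequencing depth
#'
#' Observes true parental genotypes through low-coverage sequencing: per
#' site and parent the depth is Poisson with the given mean (or fixed, for
#' controlled experiments), each read samples one of the parent's two true
#' alleles uniformly, and the genotype is called missing at depth 0, hom
#' when all reads agree and het otherwise. With `joint = TRUE` the reads of
#' the two same-breed parents are pooled into one sample per breed, doubling
#' the effective depth (the joint mapping strategy). Site-level FS/QD
#' annotations are drawn so that a small fraction of sites violates the
#' quality filters.
#'
#' @param tg a `true_genotypes` object.
#' @param mean_depth mean reads per site per parent.
#' @param seed RNG seed.
#' @param depth_dist `"poisson"` (default) or `"fixed"` (every site at
#'   exactly `round(mean_depth)` reads).
#' @param qc_violation_rate fraction of sites with filter-violating FS/QD.
#' @param joint pool same-breed parents into per-breed samples.
#' @return A [variant_table] whose samples are the parents, or the breeds
#'   when `joint = TRUE`.
#' @export
simulate_genotype_observation <- function(tg, mean_depth = 4, seed = 1L,
                                          depth_dist = c("poisson", "fixed"),
                                          qc_violation_rate = 0.02,
                                          joint = FALSE) {
  stopifnot(inherits(tg, "true_genotypes"))
  reads <- sim_reads(tg, mean_depth, seed, depth_dist)
  qc <- sim_site_qc(nrow(tg$sites), qc_violation_rate,
                    derive_seed(seed, 101))
  if (joint) {
    merged <- merge_reads_by_breed(tg, reads)
    obs_from_reads(tg, merged$dp, merged$ref_reads, qc, colnames(merged$dp))
  } else {
    obs_from_reads(tg, reads$dp, reads$ref_reads, qc, tg$parents)
  }
}

# Pool read draws of same-breed parents: joint depth is the sum of the two
# parents' depths and the genotype is called from the pooled reads.
merge_reads_by_breed <- function(tg, reads) {
  breeds <- unique(unname(tg$breeds[tg$parents]))
  dp <- sapply(breeds, function(b) {
    cols <- tg$parents[tg$breeds[tg$parents] == b]
    rowSums(reads$dp[, cols, drop = FALSE])
  })
  rr <- sapply(breeds, function(b) {
    cols <- tg$parents[tg$breeds[tg$parents] == b]
    rowSums(reads$ref_reads[, cols, drop = FALSE])
  })
  dp <- matrix(as.integer(dp), nrow(reads$dp), length(breeds),
               dimnames = list(NULL, breeds))
  rr <- matrix(as.integer(rr), nrow(reads$dp), length(breeds),
               dimnames = list(NULL, breeds))
  list(dp = dp, ref_reads = rr)
}
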