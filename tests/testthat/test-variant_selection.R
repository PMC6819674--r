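make_vt <- function(pos, fs = 1, qd = 20, dp = 10, chrom = "1",
                    gt = c("hom_ref", "hom_ref", "hom_alt", "hom_alt")) {
  n <- length(pos)
  rec <- function(x) if (length(x) == 1) rep(x, n) else x
  variant_table(
    data.frame(chrom = rec(chrom), pos = as.integer(pos),
               ref = rep("A", n), alt = rep("G", n),
               fs = rec(fs), qd = rec(qd), stringsAsFactors = FALSE),
    matrix(rep(gt, each = n), n, 4, dimnames = list(NULL, PARENTS)),
    matrix(as.integer(rec(dp)), n, 4, dimnames = list(NULL, PARENTS)),
    PARENTS)
}

test_that("quality filters use the quoted strict inequalities and fixed attribution order", {
  vt <- make_vt(pos = c(100, 500, 900, 1300),
                fs = c(30.0, 30.01, 50, 1),
                qd = c(20, 20, 1.5, 2.0))
  res <- filter_sites(vt, filter_config(), strategy = "I")
  # fs = 30 passes, fs > 30 removed; qd = 2 passes, qd < 2 removed;
  # the site failing both FS and QD is attributed to FS (first rule)
  expect_equal(res$sites$sites$pos, c(100, 1300))
  expect_equal(unname(res$removed[c("fs", "qd")]), c(2L, 0L))
})

test_that("cluster rule matches the 35 bp inclusive-span fixture and is window-exact", {
  vt <- make_vt(pos = c(100, 110, 134))  # span 34 -> within one 35 bp window
  res <- filter_sites(vt, filter_config(), strategy = "I")
  expect_equal(unname(res$removed[["cluster"]]), 3L)
  expect_equal(nrow(res$sites$sites), 0)

  vt2 <- make_vt(pos = c(100, 110, 136))  # span 36 -> no 35 bp window
  res2 <- filter_sites(vt2, filter_config(), strategy = "I")
  expect_equal(unname(res2$removed[["cluster"]]), 0L)
  expect_equal(nrow(res2$sites$sites), 3)
})

test_that("cluster rule agrees with a brute-force all-windows oracle", {
  set.seed(7)
  for (rep in 1:25) {
    pos <- sort(sample(1:2000, sample(20:120, 1)))
    k <- sample(2:4, 1); w <- sample(10:60, 1)
    expect_equal(crossASE:::cluster_members(pos, k, w),
                 brute_force_cluster(pos, k, w),
                 info = sprintf("rep %d k=%d w=%d", rep, k, w))
  }
})

test_that("depth rule applies the strategy-specific cutoff to every relevant sample", {
  vt <- make_vt(pos = c(100, 500), dp = 10)
  vt$dp[1, "KNP_F"] <- 2L  # one parent below DP 3
  res <- filter_sites(vt, filter_config(), strategy = "I")
  expect_equal(res$sites$sites$pos, 500)
  expect_equal(unname(res$removed[["dp"]]), 1L)

  # same locus as a joint table: both breed samples at DP 6 pass strategy II
  vt2 <- variant_table(
    vt$sites[1, , drop = FALSE],
    matrix(c("hom_ref", "hom_alt"), 1, 2,
           dimnames = list(NULL, c("KNP", "Landrace"))),
    matrix(c(6L, 6L), 1, 2), c("KNP", "Landrace"))
  res2 <- filter_sites(vt2, filter_config(), strategy = "II")
  expect_equal(nrow(res2$sites$sites), 1)
  # but DP 5 fails the joint cutoff
  vt2$dp[1, 1] <- 5L
  expect_equal(nrow(filter_sites(vt2, filter_config(), "II")$sites$sites), 0)
})

test_that("filtering is idempotent and rejects unsorted input", {
  cfg <- sim_config(n_genes = 80, seed = 5)
  tg <- simulate_true_genotypes(cfg)
  vt <- simulate_genotype_observation(tg, mean_depth = 4, seed = 6)
  f1 <- filter_sites(vt, filter_config(), "I")
  f2 <- filter_sites(f1$sites, filter_config(), "I")
  expect_identical(f1$sites$sites, f2$sites$sites)
  expect_equal(sum(f2$removed[c("fs", "qd", "cluster", "dp")]), 0)

  shuffled <- crossASE:::vt_subset(vt, rev(seq_len(nrow(vt$sites))))
  expect_error(filter_sites(shuffled, filter_config(), "I"), "sorted")
})

test_that("exonic assignment keeps boundary sites and supports overlapping genes", {
  # gene exons [100,250] 1-based (two unioned raw intervals)
  ann <- read_bed(write_text(c("1\t99\t200\tG1", "1\t149\t250\tG1",
                               "1\t200\t400\tG2")))
  vt <- make_vt(pos = c(250, 251, 240))
  # keep sorted: positions 240, 250, 251
  vt <- crossASE:::vt_subset(vt, order(vt$sites$pos))
  res <- assign_exonic(vt, ann)
  expect_equal(res$n_dropped, 0L)
  expect_equal(res$sites$sites$gene_ids, c("G1;G2", "G1;G2", "G2"))

  vt2 <- make_vt(pos = c(250, 500))
  res2 <- assign_exonic(vt2, read_bed(write_text("1\t99\t250\tG1")))
  expect_equal(res2$sites$sites$pos, 250)  # last base of the exon kept
  expect_equal(res2$n_dropped, 1L)         # 1 bp past the end dropped
})

test_that("informative selection demands intra-breed homozygous agreement and inter-breed difference", {
  vt <- make_vt(pos = c(100, 500, 900, 1300, 1700))
  vt$gt[2, "KNP_F"] <- "het"            # het disqualifies
  vt$gt[3, "KNP_F"] <- "missing"        # missing disqualifies
  # breeds disagree internally, but dam != sire within each cross
  vt$gt[4, ] <- c("hom_ref", "hom_alt", "hom_ref", "hom_alt")
  vt$gt[5, ] <- c("hom_ref", "hom_ref", "hom_ref", "hom_ref")  # no difference
  vt$sites$gene_ids <- sprintf("G%d", 1:5)
  inf <- select_informative(vt, "I", PARENT_BREEDS)
  expect_equal(inf$pos, 100)
  expect_equal(inf$knp_allele, "A")     # KNP parents are hom-ref
  expect_equal(inf$landrace_allele, "G")
  expect_error(select_informative(vt, "I", PARENT_BREEDS[-2]), "KNP_F")

  # relaxed mode admits the breed-discordant site via per-cross difference
  rel <- select_informative(vt, "I", PARENT_BREEDS,
                            require_breed_agreement = FALSE,
                            design = default_cross_design())
  expect_setequal(rel$pos, c(100, 1300))
  expect_true(is.na(rel$knp_allele[rel$pos == 1300]))
  expect_equal(rel$allele_KNP_M[rel$pos == 1300], "A")
})

test_that("low-depth observation can create informative false positives at true hets", {
  # KNP_F truly het; at depth 1 the consensus caller must call a hom,
  # which half the time matches KNP_M and fakes an informative site
  hap1 <- matrix(c(0L, 0L, 1L, 1L), 1, 4)
  hap2 <- matrix(c(0L, 1L, 1L, 1L), 1, 4)
  tg <- make_tg(hap1, hap2)
  hits <- 0
  for (s in 1:40) {
    vt <- simulate_genotype_observation(tg, mean_depth = 1, seed = s,
                                        depth_dist = "fixed",
                                        qc_violation_rate = 0)
    expect_true(vt$gt[1, "KNP_F"] %in% c("hom_ref", "hom_alt"))
    vt$sites$gene_ids <- "G1"
    hits <- hits + nrow(select_informative(vt, "I", PARENT_BREEDS))
  }
  expect_gt(hits, 0)   # the false positive is producible
  expect_lt(hits, 40)  # ... but not systematic
})

test_that("strategy comparison identities hold and joint mapping finds more SNPs at low depth", {
  a <- data.frame(chrom = "1", pos = 1:10)
  expect_equal(unlist(compare_strategies(a, a)),
               c(count_i = 10, count_ii = 10, shared = 10,
                 unique_i = 0, unique_ii = 0))
  b <- data.frame(chrom = "1", pos = 11:14)
  expect_equal(unlist(compare_strategies(a[1:3, ], b)),
               c(count_i = 3, count_ii = 4, shared = 0,
                 unique_i = 3, unique_ii = 4))

  cfg0 <- sim_config(n_genes = 40, breed_divergence = 0.2, seed = 1)
  wins <- 0
  for (s in 1:100) {
    cfg <- sim_config(n_genes = 40, breed_divergence = 0.2, seed = s)
    tg <- simulate_true_genotypes(cfg)
    tg$sites$gene_ids <- tg$sites$gene_id  # layout is fully exonic
    vt_i <- simulate_genotype_observation(tg, 4, seed = s + 1000,
                                          qc_violation_rate = 0)
    vt_ii <- simulate_genotype_observation(tg, 4, seed = s + 1000,
                                           qc_violation_rate = 0,
                                           joint = TRUE)
    vt_i$sites$gene_ids <- vt_ii$sites$gene_ids <- tg$sites$gene_id
    fi <- filter_sites(vt_i, filter_config(), "I")$sites
    fii <- filter_sites(vt_ii, filter_config(), "II")$sites
    si <- select_informative(fi, "I", PARENT_BREEDS)
    sii <- select_informative(fii, "II", c(KNP = "KNP",
                                           Landrace = "Landrace"))
    cmp <- compare_strategies(si, sii)
    expect_equal(cmp$shared + cmp$unique_i, cmp$count_i)
    expect_equal(cmp$shared + cmp$unique_ii, cmp$count_ii)
    wins <- wins + (cmp$count_ii >= cmp$count_i)
  }
  expect_gte(wins, 95)
})

test_that("with near-perfect genotypes the two strategies select identical sets", {
  cfg <- sim_config(n_genes = 60, breed_divergence = 0.3, seed = 13)
  tg <- simulate_true_genotypes(cfg)
  vt_i <- simulate_genotype_observation(tg, 50, seed = 14,
                                        depth_dist = "fixed",
                                        qc_violation_rate = 0)
  vt_ii <- simulate_genotype_observation(tg, 50, seed = 14,
                                         depth_dist = "fixed",
                                         qc_violation_rate = 0,
                                         joint = TRUE)
  vt_i$sites$gene_ids <- vt_ii$sites$gene_ids <- tg$sites$gene_id
  si <- select_informative(vt_i, "I", PARENT_BREEDS)
  sii <- select_informative(vt_ii, "II", c(KNP = "KNP",
                                           Landrace = "Landrace"))
  expect_setequal(paste(si$chrom, si$pos), paste(sii$chrom, sii$pos))
  # every truly breed-fixed site is recovered (by-chance diagnostic
  # configurations at non-divergent sites may legitimately add to the set)
  expect_true(all(paste(tg$sites$chrom, tg$sites$pos)[tg$sites$informative]
                  %in% paste(si$chrom, si$pos)))
})
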