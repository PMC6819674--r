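test_that("paternal read ratio follows the count definition", {
  expect_equal(paternal_read_ratio(30, 0), 1.0)
  expect_equal(paternal_read_ratio(0, 25), 0.0)
  expect_equal(round(paternal_read_ratio(2, 5), 3), 0.286)
  expect_true(is.na(paternal_read_ratio(0, 0)))
  expect_equal(paternal_read_ratio(c(1, 3), c(1, 1)), c(0.5, 0.75))
  # maternal ratio is the complement
  expect_equal(1 - paternal_read_ratio(7, 3), paternal_read_ratio(3, 7))
  expect_error(paternal_read_ratio(-1, 5), "non-negative")
})

test_that("candidate flag uses inclusive 0.3/0.7 boundaries", {
  expect_false(flag_candidate(c(0.5, 0.5, 0.5, 0.5)))
  expect_true(flag_candidate(c(0.286, 0.235, 0, 0.3)))  # 0.3 itself flags
  expect_true(flag_candidate(c(0.7, 0.5, 0.5, 0.5)))
  expect_false(flag_candidate(c(0.69, 0.31, 0.4, 0.6)))
  expect_true(flag_candidate(c(NA, NA, 0.9, NA)))
  expect_true(is.na(flag_candidate(c(NA, NA))))
})

test_that("G-test matches closed forms and an independent normal-tail oracle", {
  even <- g_test(10, 10)
  expect_equal(even$G, 0)
  expect_equal(even$p_value, 1)

  onesided <- g_test(20, 0)
  expect_equal(onesided$G, 40 * log(2), tolerance = 1e-12)
  # chi-square(1) upper tail == 2 * Phi(-sqrt(G))
  expect_equal(onesided$p_value, 2 * pnorm(-sqrt(40 * log(2))),
               tolerance = 1e-12)

  g15 <- g_test(15, 5)
  expect_equal(g15$G, 2 * (15 * log(1.5) + 5 * log(0.5)), tolerance = 1e-12)
  expect_equal(g15$G, 5.232, tolerance = 1e-3)
  expect_equal(g15$p_value, 2 * pnorm(-sqrt(g15$G)), tolerance = 1e-12)

  # Williams correction shrinks G by 1 + 1/(2n)
  expect_equal(g_test(15, 5, williams = TRUE)$G,
               g15$G / (1 + 1 / 40), tolerance = 1e-12)
  expect_error(g_test(0, 0), "at least one read")
})

test_that("G is monotone in |ratio - 0.5| at fixed total and additive over pools", {
  tot <- 40
  g <- g_test(20:40, tot - 20:40)$G
  expect_true(all(diff(g) > 0))

  # additivity: the joint statistic over per-pool 1:1 expectations is the
  # sum of the per-pool statistics
  pat <- c(12, 30, 4, 9); mat <- c(10, 2, 16, 9)
  per_pool <- sum(g_test(pat, mat)$G)
  o <- c(pat, mat); e <- rep((pat + mat) / 2, 2)
  joint <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
  expect_equal(per_pool, joint, tolerance = 1e-12)
})

test_that("count orientation maps the sire breed's allele to paternal", {
  design <- default_cross_design()
  inf <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                    gene_ids = "G1", knp_allele = "A",
                    landrace_allele = "G", strategy = "I",
                    stringsAsFactors = FALSE)
  # LxK pool: sire is KNP (= ref) -> paternal = count_ref
  counts <- data.frame(chrom = "1", pos = 100L, pool_id = "LxK_M",
                       count_ref = 7L, count_alt = 3L)
  got <- orient_counts(counts, inf, design)$oriented
  expect_equal(got$paternal_count, 7L)
  expect_equal(got$maternal_count, 3L)
  # reciprocal cross: same counts flip orientation
  counts$pool_id <- "KxL_M"
  got2 <- orient_counts(counts, inf, design)$oriented
  expect_equal(got2$paternal_count, 3L)
  expect_equal(got2$maternal_count, 7L)
  # non-informative SNPs are dropped and counted
  counts2 <- rbind(counts, data.frame(chrom = "1", pos = 999L,
                                      pool_id = "KxL_M", count_ref = 5L,
                                      count_alt = 5L))
  res <- orient_counts(counts2, inf, design)
  expect_equal(res$n_dropped_noninformative, 1L)
  expect_equal(nrow(res$oriented), 1)
  counts$pool_id <- "NOPE"
  expect_error(orient_counts(counts, inf, design), "NOPE")
  # a SNP inside two genes contributes to both
  inf2 <- inf; inf2$gene_ids <- "G1;G2"
  counts$pool_id <- "KxL_M"
  expect_equal(orient_counts(counts, inf2, design)$oriented$gene_id,
               c("G1", "G2"))
})

test_that("swapping dam and sire breeds maps every ratio to its complement, G unchanged", {
  fx <- table3_fixture()
  swapped <- cross_design(
    data.frame(cross_id = fx$design$crosses$cross_id,
               dam = fx$design$crosses$sire,
               sire = fx$design$crosses$dam),
    fx$design$pools, fx$design$breeds)
  a <- run_ase(fx$informative, fx$counts, fx$design)$results
  b <- run_ase(fx$informative, fx$counts, swapped)$results
  b <- b[match(a$gene_id, b$gene_id), ]
  rcols <- grep("^ratio_", names(a), value = TRUE)
  for (cn in rcols) expect_equal(a[[cn]], 1 - b[[cn]])
  expect_equal(a$G, b$G)
  expect_equal(a$p_value, b$p_value)
  # pattern flips parent-of-origin labels but keeps the others
  flip <- c(paternal_biased = "maternal_biased",
            maternal_biased = "paternal_biased",
            allele_dominant = "allele_dominant", biallelic = "biallelic",
            inconsistent = "inconsistent",
            insufficient_data = "insufficient_data")
  expect_equal(unname(flip[a$pattern]), b$pattern)
})

test_that("pattern labels are invariant to relabeling ref/alt at every SNP", {
  fx <- table3_fixture()
  a <- run_ase(fx$informative, fx$counts, fx$design)$results
  inf2 <- fx$informative
  inf2$ref <- fx$informative$alt
  inf2$alt <- fx$informative$ref
  counts2 <- fx$counts
  counts2$count_ref <- fx$counts$count_alt
  counts2$count_alt <- fx$counts$count_ref
  b <- run_ase(inf2, counts2, fx$design)$results
  b <- b[match(a$gene_id, b$gene_id), ]
  expect_equal(a$pattern, b$pattern)
  expect_equal(a[grep("^ratio_", names(a))], b[grep("^ratio_", names(b))],
               ignore_attr = TRUE)
})

test_that("gene evaluation classifies the reciprocal-cross patterns", {
  design <- default_cross_design()
  mk <- function(pat, mat) data.frame(
    chrom = "1", pos = 100L, gene_id = "G1",
    pool_id = design$pools$pool_id, paternal_count = pat,
    maternal_count = mat, stringsAsFactors = FALSE)
  expect_equal(evaluate_gene(mk(c(30, 30, 30, 30), c(0, 0, 0, 0)),
                             design)$pattern, "paternal_biased")
  expect_equal(evaluate_gene(mk(c(30, 30, 0, 0), c(0, 0, 25, 25)),
                             design)$pattern, "allele_dominant")
  expect_equal(evaluate_gene(mk(c(2, 4, 0, 3), c(5, 13, 18, 7)),
                             design)$pattern, "maternal_biased")
  expect_equal(evaluate_gene(mk(c(10, 11, 9, 10), c(10, 9, 11, 10)),
                             design)$pattern, "biallelic")
  # one cross biased, the other balanced -> inconsistent
  expect_equal(evaluate_gene(mk(c(30, 30, 10, 10), c(0, 0, 10, 10)),
                             design)$pattern, "inconsistent")
  # a cross without reads cannot be patterned
  r <- evaluate_gene(mk(c(30, 30, 0, 0), c(0, 0, 0, 0)), design)
  expect_equal(r$pattern, "insufficient_data")
  expect_equal(r$df, 2)
})

test_that("per-SNP testing mode uses every (SNP, pool) unit", {
  design <- default_cross_design()
  ori <- data.frame(
    chrom = "1", pos = rep(c(100L, 200L), each = 4), gene_id = "G1",
    pool_id = rep(design$pools$pool_id, 2),
    paternal_count = c(8, 2, 5, 5, 1, 9, 4, 6),
    maternal_count = c(2, 8, 5, 5, 9, 1, 6, 4))
  pool_mode <- evaluate_gene(ori, design)
  snp_mode <- evaluate_gene(ori, design, per_snp = TRUE)
  expect_equal(pool_mode$df, 4)
  expect_equal(snp_mode$df, 8)
  expect_equal(snp_mode$G,
               sum(g_test(ori$paternal_count, ori$maternal_count)$G))
})

test_that("run_ase handles empty inputs cleanly and supports BH correction", {
  fx <- table3_fixture()
  empty <- fx$counts[0, ]
  res <- run_ase(fx$informative, empty, fx$design)
  expect_equal(res$summary$n_genes, 0)
  expect_equal(nrow(res$results), 0)

  bh <- run_ase(fx$informative, fx$counts, fx$design, bh = TRUE)$results
  expect_true("p_adjusted" %in% names(bh))
  expect_true(all(bh$p_adjusted >= bh$p_value))
})
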