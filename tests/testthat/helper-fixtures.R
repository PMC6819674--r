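# Shared fixture builders. Everything is generated in code at test time.

write_text <- function(lines) {
  path <- tempfile()
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  path
}

vcf_header <- function(samples) c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=FS,Number=1,Type=Float,Description=\"x\">",
  "##INFO=<ID=QD,Number=1,Type=Float,Description=\"x\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", samples), collapse = "\t"))

vcf_record <- function(chrom, pos, ref, alt, fs = 1, qd = 20,
                       calls = c("0/0:10", "0/0:10", "1/1:10", "1/1:10"),
                       info = NULL) {
  if (is.null(info)) info <- sprintf("FS=%s;QD=%s", fs, qd)
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT:DP", calls),
        collapse = "\t")
}

PARENTS <- c("KNP_M", "KNP_F", "LR_M", "LR_F")
PARENT_BREEDS <- c(KNP_M = "KNP", KNP_F = "KNP",
                   LR_M = "Landrace", LR_F = "Landrace")

# A minimal true_genotypes object built by hand (codes: 0 = ref, 1 = alt).
make_tg <- function(hap1, hap2, chrom = NULL, pos = NULL, gene_id = NULL,
                    truth = NULL) {
  n <- nrow(hap1)
  colnames(hap1) <- colnames(hap2) <- PARENTS
  hom <- hap1 == hap2
  informative <- hom[, "KNP_M"] & hom[, "KNP_F"] & hom[, "LR_M"] &
    hom[, "LR_F"] & hap1[, "KNP_M"] == hap1[, "KNP_F"] &
    hap1[, "LR_M"] == hap1[, "LR_F"] & hap1[, "KNP_M"] != hap1[, "LR_M"]
  sites <- data.frame(
    chrom = chrom %||% rep("1", n),
    pos = pos %||% (seq_len(n) * 1000L),
    gene_id = gene_id %||% sprintf("G%04d", seq_len(n)),
    ref = rep("A", n), alt = rep("G", n),
    informative = informative,
    stringsAsFactors = FALSE)
  if (is.null(truth)) {
    g <- unique(sites$gene_id)
    truth <- data.frame(gene_id = g, true_mode = "biallelic",
                        true_paternal_fraction = 0.5,
                        favored_breed = NA_character_,
                        stringsAsFactors = FALSE)
  }
  structure(list(sites = sites, hap1 = hap1, hap2 = hap2,
                 parents = PARENTS, breeds = PARENT_BREEDS,
                 exons = NULL, truth = truth,
                 config = sim_config()),
            class = "true_genotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Informative-SNP table taken straight from the simulation truth: every
# truly breed-divergent site, with the true breed-to-allele map.
truth_informative <- function(tg, strategy = "I") {
  idx <- which(tg$sites$informative)
  knp_code <- tg$hap1[idx, "KNP_M"]
  lr_code <- tg$hap1[idx, "LR_M"]
  data.frame(
    chrom = tg$sites$chrom[idx], pos = tg$sites$pos[idx],
    ref = tg$sites$ref[idx], alt = tg$sites$alt[idx],
    gene_ids = tg$sites$gene_id[idx],
    knp_allele = ifelse(knp_code == 0, tg$sites$ref[idx],
                        tg$sites$alt[idx]),
    landrace_allele = ifelse(lr_code == 0, tg$sites$ref[idx],
                             tg$sites$alt[idx]),
    strategy = strategy, stringsAsFactors = FALSE)
}

# Brute-force SNP-cluster oracle: a position is in a cluster iff some
# window of `w` consecutive bases contains it and >= k positions in total.
brute_force_cluster <- function(pos, k, w) {
  bad <- logical(length(pos))
  for (s in pos) {
    inside <- pos >= s & pos <= s + w - 1
    if (sum(inside) >= k) bad <- bad | inside
  }
  bad
}

# The nine-gene worked example: per-pool paternal/maternal count pairs
# whose full-precision ratios round (3 d.p.) to the published per-pool
# paternal read ratios. KNP allele is REF ("A") at every SNP.
table3_fixture <- function() {
  genes <- list(
    #         gene              chrom pos        KxL_M    KxL_F    LxK_M    LxK_F
    NUSAP1  = list("NUSAP1",    "1", 129993052, c(30, 0), c(30, 0), c(30, 0), c(30, 0)),
    FAM83H  = list("FAM83H",    "4", 907296,    c(30, 0), c(30, 0), c(0, 25), c(0, 25)),
    SLC6A17 = list("SLC6A17",   "4", 109921555, c(26, 3), c(10, 5), c(3, 29), c(25, 51)),
    MANBA   = list("MANBA",     "8", 118361691, c(0, 25), c(0, 25), c(30, 0), c(30, 0)),
    PEG10   = list("PEG10",     "9", 74485347,  c(30, 0), c(30, 0), c(30, 0), c(30, 0)),
    G10703  = list("ENSSSCG00000010703", "14", 132103321,
                   c(10, 5), c(13, 4), c(11, 28), c(16, 69)),
    G10719  = list("ENSSSCG00000010719", "14", 132495049,
                   c(7, 2), c(23, 2), c(4, 19), c(5, 20)),
    TFR2    = list("TFR2",      "3", 8560671,   c(2, 7), c(0, 20), c(9, 1), c(8, 3)),
    PPFIBP1 = list("PPFIBP1",   "5", 46032153,  c(2, 5), c(4, 13), c(0, 18), c(3, 7)))
  design <- default_cross_design()
  pools <- design$pools$pool_id
  sires <- vapply(pools, function(p) crossASE:::sire_breed(design, p), "")
  informative <- do.call(rbind, lapply(genes, function(g) data.frame(
    chrom = g[[2]], pos = g[[3]], ref = "A", alt = "G",
    gene_ids = g[[1]], knp_allele = "A", landrace_allele = "G",
    strategy = "I", stringsAsFactors = FALSE)))
  counts <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(seq_along(pools), function(k) {
      pm <- g[[3 + k]]  # (paternal, maternal)
      # paternal allele is the sire breed's allele; KNP = ref here
      if (sires[k] == "KNP")
        data.frame(chrom = g[[2]], pos = g[[3]], pool_id = pools[k],
                   count_ref = pm[1], count_alt = pm[2])
      else
        data.frame(chrom = g[[2]], pos = g[[3]], pool_id = pools[k],
                   count_ref = pm[2], count_alt = pm[1])
    }))
  }))
  rownames(informative) <- rownames(counts) <- NULL
  printed <- rbind(
    NUSAP1  = c(1, 1, 1, 1),
    FAM83H  = c(1, 1, 0, 0),
    SLC6A17 = c(0.897, 0.667, 0.094, 0.329),
    MANBA   = c(0, 0, 1, 1),
    PEG10   = c(1, 1, 1, 1),
    ENSSSCG00000010703 = c(0.667, 0.765, 0.282, 0.188),
    ENSSSCG00000010719 = c(0.778, 0.920, 0.174, 0.200),
    TFR2    = c(0.222, 0, 0.9, 0.727),
    PPFIBP1 = c(0.286, 0.235, 0, 0.3))
  colnames(printed) <- pools
  list(informative = informative, counts = counts, design = design,
       printed = printed)
}
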