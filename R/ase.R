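#' Paternal read ratio
#'
#' The fraction of informative RNA reads carrying the paternally inherited
#' allele: `paternal / (paternal + maternal)`. The maternal ratio is
#' `1 - paternal read ratio` by construction. Undefined (`NA`) when both
#' counts are zero. 0.5 under balanced biallelic expression; 1 under
#' complete paternal expression.
#'
#' @param paternal_count,maternal_count non-negative read counts
#'   (vectorized).
#' @return Numeric vector of ratios in `[0, 1]`, `NA` where no reads.
#' @export
paternal_read_ratio <- function(paternal_count, maternal_count) {
  if (any(paternal_count < 0, na.rm = TRUE) ||
      any(maternal_count < 0, na.rm = TRUE))
    stopf("counts must be non-negative")
  tot <- paternal_count + maternal_count
  ifelse(tot == 0, NA_real_, paternal_count / tot)
}

#' Candidate ASE flag
#'
#' A gene (or SNP) is a candidate for allele-biased expression when any of
#' its per-pool paternal read ratios falls outside the biallelic band:
#' at or below `lo`, or at or above `hi` (boundaries inclusive — a ratio of
#' exactly 0.3 counts as biased). Ratios strictly inside `(lo, hi)` in all
#' pools mean biallelic expression.
#'
#' @param ratios per-pool ratios (`NA` = undefined).
#' @param lo,hi the biallelic band boundaries.
#' @return `TRUE`/`FALSE`, or `NA` when every ratio is undefined
#'   (insufficient data).
#' @export
flag_candidate <- function(ratios, lo = 0.3, hi = 0.7) {
  r <- ratios[!is.na(ratios)]
  if (length(r) == 0) return(NA)
  any(r <= lo | r >= hi)
}

#' G-test of goodness-of-fit against a 1:1 allelic ratio
#'
#' Likelihood-ratio statistic `G = 2 * sum(O * ln(O / E))` over the
#' paternal/maternal read counts with expectations `E = total / 2`;
#' zero-count cells contribute 0. The p-value is the chi-square upper tail
#' with 1 degree of freedom. The optional Williams correction divides G by
#' `q = 1 + 1/(2 * total)` before the tail computation.
#'
#' @param paternal_count,maternal_count non-negative counts (vectorized;
#'   each pair must total at least 1 read).
#' @param williams apply the Williams small-sample correction.
#' @return data.frame with columns `G` and `p_value`.
#' @export
g_test <- function(paternal_count, maternal_count, williams = FALSE) {
  tot <- paternal_count + maternal_count
  if (any(tot == 0)) stopf("g_test needs at least one read")
  term <- function(o) ifelse(o > 0, o * log(2 * o / tot), 0)
  g <- 2 * (term(paternal_count) + term(maternal_count))
  g <- pmax(g, 0)  # guard tiny negative rounding at exact 1:1
  if (williams) g <- g / (1 + 1 / (2 * tot))
  data.frame(G = g, p_value = stats::pchisq(g, df = 1, lower.tail = FALSE))
}

#' Orient allele counts by parental origin
#'
#' Converts ref/alt allele counts into paternal/maternal counts using the
#' informative SNPs' breed-to-allele map and the cross design: in every
#' pool, the sire breed's allele is the paternal allele. Counts at SNPs not
#' in the informative set are dropped and counted. A SNP lying in the exons
#' of several genes yields one oriented record per gene.
#'
#' @param counts allele-count data.frame (`chrom, pos, pool_id, count_ref,
#'   count_alt`).
#' @param informative informative-SNP data.frame from
#'   [select_informative].
#' @param design a [cross_design].
#' @return A list with `oriented` (data.frame `chrom, pos, gene_id,
#'   pool_id, paternal_count, maternal_count`) and
#'   `n_dropped_noninformative`.
#' @export
orient_counts <- function(counts, informative, design) {
  stopifnot(inherits(design, "cross_design"))
  counts <- as.data.frame(counts)
  bad_pool <- setdiff(unique(counts$pool_id), design$pools$pool_id)
  if (length(bad_pool) > 0)
    stopf("pool_id '%s' is not in the cross design", bad_pool[1])
  key_c <- paste(counts$chrom, counts$pos)
  key_i <- paste(informative$chrom, informative$pos)
  mi <- match(key_c, key_i)
  n_dropped <- sum(is.na(mi))
  keep <- which(!is.na(mi))
  empty <- data.frame(chrom = character(), pos = integer(),
                      gene_id = character(), pool_id = character(),
                      paternal_count = integer(), maternal_count = integer(),
                      stringsAsFactors = FALSE)
  if (length(keep) == 0)
    return(list(oriented = empty, n_dropped_noninformative = n_dropped))
  cc <- counts[keep, ]
  inf <- informative[mi[keep], ]
  sb <- sire_breed(design, cc$pool_id)

  pat_allele <- ifelse(sb == "KNP", inf$knp_allele, inf$landrace_allele)
  has_sample_cols <- any(grepl("^allele_", names(informative)))
  if (has_sample_cols && anyNA(pat_allele)) {
    # relaxed-mode sites: orient via the allele of each pool's sire sample
    ci <- design$pools$cross_id[match(cc$pool_id, design$pools$pool_id)]
    sire <- design$crosses$sire[match(ci, design$crosses$cross_id)]
    idx <- which(is.na(pat_allele))
    for (i in idx) {
      col <- paste0("allele_", sire[i])
      if (col %in% names(inf)) pat_allele[i] <- inf[[col]][i]
    }
  }
  ok <- !is.na(pat_allele)
  n_dropped <- n_dropped + sum(!ok)
  cc <- cc[ok, ]; inf <- inf[ok, ]; pat_allele <- pat_allele[ok]

  pat_is_ref <- pat_allele == inf$ref
  paternal <- ifelse(pat_is_ref, cc$count_ref, cc$count_alt)
  maternal <- ifelse(pat_is_ref, cc$count_alt, cc$count_ref)
  genes <- strsplit(inf$gene_ids, ";", fixed = TRUE)
  reps <- lengths(genes)
  oriented <- data.frame(
    chrom = rep(cc$chrom, reps), pos = rep(cc$pos, reps),
    gene_id = unlist(genes), pool_id = rep(cc$pool_id, reps),
    paternal_count = rep(paternal, reps),
    maternal_count = rep(maternal, reps),
    stringsAsFactors = FALSE)
  rownames(oriented) <- NULL
  list(oriented = oriented, n_dropped_noninformative = n_dropped)
}

#' Evaluate allele-specific expression for one gene
#'
#' Sums oriented counts over the gene's informative SNPs within each pool,
#' computes the four per-pool paternal read ratios, flags the gene as an
#' ASE candidate when any defined ratio leaves the biallelic band (see
#' [flag_candidate]), and tests deviation from the 1:1 expectation by
#' summing per-pool G statistics (G statistics over independent pools add;
#' degrees of freedom = number of pools with at least one read). Setting
#' `per_snp = TRUE` instead sums G over every (SNP, pool) unit with reads.
#' The cross-pattern label compares the mean defined ratio of each cross
#' (`r1`, `r2`; the two pools of a cross are biological replicates):
#' both at or above `hi` = `paternal_biased`; both at or below `lo` =
#' `maternal_biased`; one high and one low = `allele_dominant` (the flipped
#' direction follows which cross's sire carries the favored allele); both
#' strictly inside the band = `biallelic`; anything else `inconsistent`;
#' no reads (or a cross with no defined ratio) = `insufficient_data`.
#'
#' @param oriented oriented counts of one gene (see [orient_counts]).
#' @param design a [cross_design].
#' @param alpha significance level for the G-test.
#' @param lo,hi biallelic band boundaries.
#' @param williams apply the Williams correction per tested unit.
#' @param per_snp test per (SNP, pool) instead of per pool.
#' @return One-row data.frame: `gene_id, n_snps, n_pools`, one
#'   `ratio_<pool>` column per pool, `G, df, p_value, candidate, pattern,
#'   significant`.
#' @export
evaluate_gene <- function(oriented, design, alpha = 0.05, lo = 0.3,
                          hi = 0.7, williams = FALSE, per_snp = FALSE) {
  stopifnot(nrow(oriented) >= 1, length(unique(oriented$gene_id)) == 1)
  pools <- design_pools(design)
  pat <- vapply(pools, function(p)
    sum(oriented$paternal_count[oriented$pool_id == p]), 0)
  mat <- vapply(pools, function(p)
    sum(oriented$maternal_count[oriented$pool_id == p]), 0)
  ratios <- paternal_read_ratio(pat, mat)
  names(ratios) <- pools

  if (per_snp) {
    u_pat <- oriented$paternal_count
    u_mat <- oriented$maternal_count
  } else {
    u_pat <- pat
    u_mat <- mat
  }
  with_reads <- u_pat + u_mat >= 1
  df <- sum(with_reads)
  if (df > 0) {
    gt <- g_test(u_pat[with_reads], u_mat[with_reads], williams = williams)
    G <- sum(gt$G)
    p <- stats::pchisq(G, df = df, lower.tail = FALSE)
  } else {
    G <- NA_real_; p <- NA_real_
  }

  candidate <- flag_candidate(ratios, lo, hi)
  cross_of <- design$pools$cross_id[match(pools, design$pools$pool_id)]
  cids <- design$crosses$cross_id
  r1 <- mean(ratios[cross_of == cids[1]], na.rm = TRUE)
  r2 <- mean(ratios[cross_of == cids[2]], na.rm = TRUE)
  pattern <-
    if (df == 0 || is.nan(r1) || is.nan(r2)) "insufficient_data"
    else if (r1 >= hi && r2 >= hi) "paternal_biased"
    else if (r1 <= lo && r2 <= lo) "maternal_biased"
    else if ((r1 >= hi && r2 <= lo) || (r1 <= lo && r2 >= hi))
      "allele_dominant"
    else if (r1 > lo && r1 < hi && r2 > lo && r2 < hi) "biallelic"
    else "inconsistent"

  res <- data.frame(gene_id = oriented$gene_id[1],
                    n_snps = length(unique(paste(oriented$chrom,
                                                 oriented$pos))),
                    n_pools = sum(pat + mat >= 1),
                    stringsAsFactors = FALSE)
  for (p_id in pools) res[[paste0("ratio_", p_id)]] <- ratios[[p_id]]
  res$G <- G
  res$df <- df
  res$p_value <- p
  res$candidate <- candidate
  res$pattern <- pattern
  res$significant <- !is.na(p) && p < alpha
  res
}

#' Run the ASE analysis over all genes
#'
#' Orients the allele counts by parental origin, then evaluates every gene
#' that has at least one informative SNP with reads (see [evaluate_gene]).
#' With `bh = TRUE`, Benjamini-Hochberg adjusted p-values are added and
#' used for the significance call; by default raw p-values are compared to
#' `alpha`.
#'
#' @param informative informative-SNP data.frame.
#' @param counts allele-count data.frame (all pools together).
#' @param design a [cross_design].
#' @inheritParams evaluate_gene
#' @param bh apply Benjamini-Hochberg correction across genes.
#' @return A list with `results` (one row per gene), `summary` (gene counts
#'   by pattern, candidate and significance) and
#'   `n_dropped_noninformative`.
#' @export
run_ase <- function(informative, counts, design = default_cross_design(),
                    alpha = 0.05, lo = 0.3, hi = 0.7, williams = FALSE,
                    per_snp = FALSE, bh = FALSE) {
  ori <- orient_counts(counts, informative, design)
  oriented <- ori$oriented
  expressed <- oriented[oriented$paternal_count +
                          oriented$maternal_count > 0, ]
  genes <- unique(oriented$gene_id[oriented$gene_id %in%
                                     expressed$gene_id])
  by_gene <- split(oriented, factor(oriented$gene_id, levels = genes))
  rows <- lapply(by_gene, function(g)
    evaluate_gene(g, design, alpha = alpha, lo = lo, hi = hi,
                  williams = williams, per_snp = per_snp))
  results <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(0))
  if (bh && nrow(results) > 0) {
    results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
    results$significant <- !is.na(results$p_adjusted) &
      results$p_adjusted < alpha
  }
  pattern_counts <- if (nrow(results) > 0)
    table(factor(results$pattern, levels = ASE_PATTERNS)) else
    table(factor(character(0), levels = ASE_PATTERNS))
  summary <- list(
    n_genes = nrow(results),
    n_candidate = if (nrow(results) > 0)
      sum(results$candidate, na.rm = TRUE) else 0L,
    n_significant = if (nrow(results) > 0)
      sum(results$significant, na.rm = TRUE) else 0L,
    pattern_counts = as.list(pattern_counts))
  list(results = results, summary = summary,
       n_dropped_noninformative = ori$n_dropped_noninformative)
}

#' Format an ASE result table for output
#'
#' Rounds the per-pool ratios to three decimal places for reporting
#' (internal computation stays full precision) and writes a TSV.
#'
#' @param results result data.frame from [run_ase].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ase_results <- function(results, path) {
  out <- results
  for (cn in grep("^ratio_", names(out), value = TRUE))
    out[[cn]] <- round(out[[cn]], 3)
  out$G <- round(out$G, 4)
  out$p_value <- signif(out$p_value, 4)
  write_tsv(out, path)
  invisible(path)
}
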