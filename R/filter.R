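#' Variant filtration thresholds
#'
#' Hard filters applied to called variant sites before informative-SNP
#' selection: strand bias (remove FS > `fs_max`), quality by depth (remove
#' QD < `qd_min`), SNP clusters (remove sites where `cluster_size` or more
#' SNPs fall within a `cluster_window_bp` window), and read depth (remove
#' sites where any relevant sample has DP below `dp_min_individual` under
#' the individual mapping strategy I or `dp_min_joint` under the same-breed
#' joint strategy II). All inequalities are strict, so e.g. FS = 30 and
#' DP = 3 pass.
#'
#' @param fs_max maximum Fisher-strand phred score retained.
#' @param qd_min minimum quality-by-depth retained.
#' @param cluster_size number of SNPs within a window that defines a
#'   cluster.
#' @param cluster_window_bp cluster window width in bases (inclusive span:
#'   a window holds positions p..p+window-1).
#' @param dp_min_individual minimum per-parent depth, strategy I.
#' @param dp_min_joint minimum per-breed depth, strategy II.
#' @return A `filter_config` object.
#' @export
filter_config <- function(fs_max = 30, qd_min = 2, cluster_size = 3,
                          cluster_window_bp = 35, dp_min_individual = 3,
                          dp_min_joint = 6) {
  vals <- c(fs_max = fs_max, qd_min = qd_min, cluster_size = cluster_size,
            cluster_window_bp = cluster_window_bp,
            dp_min_individual = dp_min_individual,
            dp_min_joint = dp_min_joint)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all filter thresholds must be finite and > 0")
  structure(as.list(vals), class = "filter_config")
}

# Indices of positions (sorted, one chromosome) lying in some window of
# `window` consecutive bases that contains >= `k` candidate SNPs.
cluster_members <- function(pos, k, window) {
  m <- length(pos)
  bad <- logical(m)
  if (m < k) return(bad)
  j <- 1L
  for (i in seq_len(m - k + 1L)) {
    if (j < i + k - 1L) j <- i + k - 1L
    while (j < m && pos[j + 1L] - pos[i] <= window - 1L) j <- j + 1L
    if (pos[j] - pos[i] <= window - 1L && j - i + 1L >= k)
      bad[i:j] <- TRUE
  }
  bad
}

#' Apply hard site filters
#'
#' Removes sites in a fixed rule order — strand bias (FS), quality by depth
#' (QD), SNP cluster, read depth (DP) — and reports how many sites each rule
#' removed. A site failing several rules is counted once, under the first
#' failing rule in that order. The cluster rule is evaluated per chromosome
#' on the set that survives the FS/QD quality filters: a SNP is removed iff
#' some window of `cluster_window_bp` consecutive bases contains it together
#' with at least `cluster_size - 1` other surviving SNPs. The DP rule
#' removes a site if any relevant sample (all four parents under strategy I;
#' both breed samples under strategy II) has depth below the strategy's
#' cutoff; missing genotypes have depth 0 and are removed with it.
#' Filtering is idempotent.
#'
#' @param vt a [variant_table], sorted by chromosome and position.
#' @param config a [filter_config].
#' @param strategy `"I"` (individual mapping) or `"II"` (joint mapping);
#'   selects which DP cutoff applies.
#' @return A list with `sites` (the retained [variant_table]) and `removed`
#'   (named integer vector of per-rule removal counts plus `retained`).
#' @export
filter_sites <- function(vt, config = filter_config(),
                         strategy = c("I", "II")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(vt, "variant_table"), inherits(config, "filter_config"))
  n <- n_sites(vt)
  if (n > 1) {
    ch <- vt$sites$chrom
    blocks <- rle(ch)$values
    by_chrom <- split(vt$sites$pos, factor(ch, unique(ch)))
    if (anyDuplicated(blocks) > 0 || any(vapply(by_chrom, is.unsorted, TRUE)))
      stopf("sites must be sorted by chromosome and position")
  }
  removed_by <- rep(NA_character_, n)
  removed_by[vt$sites$fs > config$fs_max] <- "fs"
  removed_by[is.na(removed_by) & vt$sites$qd < config$qd_min] <- "qd"

  alive <- which(is.na(removed_by))
  if (length(alive) > 0) {
    for (ch in unique(vt$sites$chrom[alive])) {
      idx <- alive[vt$sites$chrom[alive] == ch]
      bad <- cluster_members(vt$sites$pos[idx], config$cluster_size,
                             config$cluster_window_bp)
      removed_by[idx[bad]] <- "cluster"
    }
  }

  dp_min <- if (strategy == "I") config$dp_min_individual
            else config$dp_min_joint
  low_dp <- apply(vt$dp < dp_min, 1, any)
  removed_by[is.na(removed_by) & low_dp] <- "dp"

  keep <- is.na(removed_by)
  removed <- c(fs = sum(removed_by == "fs", na.rm = TRUE),
               qd = sum(removed_by == "qd", na.rm = TRUE),
               cluster = sum(removed_by == "cluster", na.rm = TRUE),
               dp = sum(removed_by == "dp", na.rm = TRUE),
               retained = sum(keep))
  list(sites = vt_subset(vt, keep), removed = removed)
}

#' Attach gene ids to exonic sites
#'
#' Keeps the sites whose position falls inside the unioned exons of at
#' least one gene and records the containing gene ids (`;`-joined when a
#' site lies in overlapping genes — such sites contribute to every
#' containing gene downstream). Non-exonic sites are dropped and counted.
#'
#' @param vt a [variant_table].
#' @param annotation an `exon_annotation` from [read_bed].
#' @return A list with `sites` (a [variant_table] whose site table gains a
#'   `gene_ids` column) and `n_dropped`.
#' @export
assign_exonic <- function(vt, annotation) {
  stopifnot(inherits(vt, "variant_table"),
            inherits(annotation, "exon_annotation"))
  n <- n_sites(vt)
  if (n == 0) {
    vt$sites$gene_ids <- character(0)
    return(list(sites = vt, n_dropped = 0L))
  }
  q <- GenomicRanges::GRanges(vt$sites$chrom,
                              IRanges::IRanges(vt$sites$pos, vt$sites$pos))
  hits <- as.data.frame(GenomicRanges::findOverlaps(q, annotation$gr))
  genes <- rep(NA_character_, n)
  if (nrow(hits) > 0) {
    gl <- tapply(annotation$gr$gene_id[hits$subjectHits], hits$queryHits,
                 function(g) paste(sort(unique(g)), collapse = ";"))
    genes[as.integer(names(gl))] <- unname(gl)
  }
  keep <- !is.na(genes)
  out <- vt_subset(vt, keep)
  out$sites$gene_ids <- genes[keep]
  list(sites = out, n_dropped = sum(!keep))
}
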