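#' Variant site tables
#'
#' A `variant_table` holds biallelic SNP sites together with per-sample
#' genotype calls and read depths. It is the in-memory form of the minimal
#' VCF dialect the pipeline reads and writes: one row per site with
#' chromosome, 1-based position, single-base REF/ALT, the Fisher-strand (FS)
#' and quality-by-depth (QD) annotations, plus a genotype matrix
#' (`hom_ref`/`het`/`hom_alt`/`missing`) and a depth matrix over samples.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `fs`, `qd`.
#' @param gt character matrix (sites x samples) of genotype codes.
#' @param dp integer matrix (sites x samples) of read depths.
#' @param samples character vector of sample names (column order of `gt`).
#' @param dropped named integer vector of records dropped on read
#'   (`multiallelic`, `indel`, `other`).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp, samples,
                          dropped = c(multiallelic = 0L, indel = 0L,
                                      other = 0L)) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "fs", "qd") %in% names(sites)))
  gt <- as.matrix(gt)
  dp <- as.matrix(dp)
  n <- nrow(sites)
  if (nrow(gt) != n || nrow(dp) != n || ncol(gt) != length(samples) ||
      ncol(dp) != length(samples))
    stopf("genotype/depth matrices do not match sites x samples")
  if (n > 0) {
    if (any(sites$pos < 1)) stopf("positions must be >= 1")
    if (any(sites$ref == sites$alt)) stopf("ref and alt alleles must differ")
    if (!all(sites$ref %in% BASES) || !all(sites$alt %in% BASES))
      stopf("alleles must be single bases A/C/G/T")
    if (!all(gt %in% GT_LEVELS)) stopf("invalid genotype code")
    # dp == 0 implies a missing call
    if (any(dp == 0L & gt != "missing"))
      stopf("a call with dp = 0 must be 'missing'")
  }
  colnames(gt) <- colnames(dp) <- samples
  structure(list(sites = sites, gt = gt, dp = dp, samples = samples,
                 dropped = dropped),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(x$samples, collapse = ", ")))
  if (sum(x$dropped) > 0)
    cat(sprintf("  dropped on read: %s\n",
                paste(names(x$dropped), x$dropped, sep = "=",
                      collapse = ", ")))
  invisible(x)
}

n_sites <- function(vt) nrow(vt$sites)

# Row-subset a variant_table, keeping drop counters.
vt_subset <- function(vt, idx) {
  variant_table(vt$sites[idx, , drop = FALSE],
                vt$gt[idx, , drop = FALSE],
                vt$dp[idx, , drop = FALSE],
                vt$samples, vt$dropped)
}

.info_field <- function(info, key) {
  pat <- paste0("(^|;)", key, "=([^;]*)")
  m <- regexpr(pat, info)
  out <- rep(NA_real_, length(info))
  hit <- m > 0
  if (any(hit)) {
    s <- regmatches(info, m)[hit]
    out[hit] <- suppressWarnings(as.numeric(sub(pat, "\\2", s)))
  }
  out
}

#' Read a minimal VCF 4.2 file of biallelic SNPs
#'
#' Parses the VCF dialect used throughout the pipeline: INFO keys `FS`
#' (Fisher-strand phred score) and `QD` (quality by depth), FORMAT keys
#' `GT` and `DP`. Multi-allelic records and indels are dropped and counted,
#' never decomposed, because the informative-SNP rule and the paternal read
#' ratio are defined for exactly two alleles. A missing FS or QD annotation
#' is parsed as 0.0 (i.e. the site is not removed on that criterion) with a
#' warning. A call with `DP` 0 or `GT` `./.` is stored as a missing genotype.
#'
#' @param path path to a VCF file.
#' @param required_samples sample columns that must be present; output
#'   columns follow this order.
#' @param verbose emit a message with the number of dropped records.
#' @return A [variant_table]; the `dropped` element counts excluded records
#'   so that dropped + returned equals the number of data lines.
#' @export
read_vcf <- function(path, required_samples, verbose = FALSE) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "##")
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1)
    stopf("%s: expected exactly one #CHROM header line", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stopf("%s: no sample columns in header", path)
  file_samples <- hdr[-(1:9)]
  missing_s <- setdiff(required_samples, file_samples)
  if (length(missing_s) > 0)
    stopf("required sample '%s' not found in %s", missing_s[1], path)
  scol <- match(required_samples, file_samples) + 9L

  body_i <- setdiff(which(!is_meta & nzchar(lines)), hdr_i)
  n_data <- length(body_i)
  empty <- variant_table(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), fs = numeric(), qd = numeric()),
    matrix(character(), 0, length(required_samples)),
    matrix(integer(), 0, length(required_samples)),
    required_samples)
  if (n_data == 0) return(empty)

  fields <- strsplit(lines[body_i], "\t", fixed = TRUE)
  len <- lengths(fields)
  if (any(len != length(hdr)))
    stopf("%s: malformed record at line %d (expected %d fields, got %d)",
          path, body_i[which(len != length(hdr))[1]],
          length(hdr), len[len != length(hdr)][1])
  m <- matrix(unlist(fields), nrow = n_data, byrow = TRUE)

  ref <- m[, 4]; alt <- m[, 5]
  multi <- grepl(",", alt, fixed = TRUE)
  snp_shape <- !multi & nchar(ref) == 1 & nchar(alt) == 1
  indel <- !multi & !snp_shape
  keep <- snp_shape & ref %in% BASES & alt %in% BASES & ref != alt
  other <- snp_shape & !keep
  dropped <- c(multiallelic = sum(multi), indel = sum(indel),
               other = sum(other))
  if (verbose && sum(dropped) > 0)
    message(sprintf("read_vcf: dropped %d multiallelic, %d indel, %d other",
                    dropped[1], dropped[2], dropped[3]))
  if (!any(keep)) {
    empty$dropped <- dropped
    return(empty)
  }
  m <- m[keep, , drop = FALSE]
  lineno <- body_i[keep]

  fs <- .info_field(m[, 8], "FS")
  qd <- .info_field(m[, 8], "QD")
  if (anyNA(fs) || anyNA(qd)) {
    warning(sprintf(
      "%s: FS missing at %d and QD missing at %d site(s); defaulting to 0",
      path, sum(is.na(fs)), sum(is.na(qd))), call. = FALSE)
    fs[is.na(fs)] <- 0
    qd[is.na(qd)] <- 0
  }

  nk <- nrow(m)
  ns <- length(required_samples)
  gt <- matrix(NA_character_, nk, ns)
  dp <- matrix(NA_integer_, nk, ns)
  fmt_keys <- strsplit(m[, 9], ":", fixed = TRUE)
  for (j in seq_len(ns)) {
    parts <- strsplit(m[, scol[j]], ":", fixed = TRUE)
    for (i in seq_len(nk)) {
      keys <- fmt_keys[[i]]
      gi <- match("GT", keys); di <- match("DP", keys)
      if (is.na(gi))
        stopf("%s: FORMAT without GT at line %d", path, lineno[i])
      g <- parts[[i]][gi]
      if (!grepl("^[01.][/|][01.]$", g))
        stopf("%s: malformed GT '%s' at line %d (sample %s)",
              path, g, lineno[i], required_samples[j])
      d <- if (is.na(di) || di > length(parts[[i]])) "." else parts[[i]][di]
      dv <- if (d %in% c(".", "")) 0L else suppressWarnings(as.integer(d))
      if (is.na(dv))
        stopf("%s: malformed DP '%s' at line %d", path, d, lineno[i])
      a <- substr(g, 1, 1); b <- substr(g, 3, 3)
      gv <- if (a == "." || b == "." || dv == 0L) "missing"
            else c("hom_ref", "het", "hom_alt")[
              as.integer(a) + as.integer(b) + 1L]
      gt[i, j] <- gv
      dp[i, j] <- if (gv == "missing" && dv == 0L) 0L else dv
    }
  }
  # dp = 0 forces a missing call
  gt[dp == 0L] <- "missing"

  variant_table(
    data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), ref = ref[keep],
               alt = alt[keep], fs = fs, qd = qd,
               stringsAsFactors = FALSE),
    gt, dp, required_samples, dropped)
}

#' Write a variant table as minimal VCF 4.2
#'
#' Inverse of [read_vcf] for the dialect documented there. Output is
#' tab-separated UTF-8 with LF line endings and a fixed header, so identical
#' tables produce byte-identical files.
#'
#' @param vt a [variant_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred-scaled Fisher strand bias\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant quality by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t"))
  n <- n_sites(vt)
  body <- character(0)
  if (n > 0) {
    gt_str <- matrix(c(`hom_ref` = "0/0", `het` = "0/1", `hom_alt` = "1/1",
                       `missing` = "./.")[vt$gt], n, length(vt$samples))
    cells <- matrix(paste0(gt_str, ":", vt$dp), n, length(vt$samples))
    body <- paste(
      vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref, vt$sites$alt, ".",
      "PASS",
      paste0("FS=", formatC(vt$sites$fs, format = "f", digits = 2),
             ";QD=", formatC(vt$sites$qd, format = "f", digits = 2)),
      "GT:DP",
      apply(cells, 1, paste, collapse = "\t"),
      sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
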