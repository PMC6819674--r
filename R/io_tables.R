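COUNT_COLS <- c("chrom", "pos", "pool_id", "count_ref", "count_alt")

#' Read / write per-SNP allele count tables
#'
#' Allele counts are stored as a TSV with header
#' `chrom, pos, pool_id, count_ref, count_alt`: the number of RNA reads
#' carrying the site's reference and alternate allele in one offspring pool.
#' Positions are 1-based; counts must be non-negative integers;
#' `(chrom, pos, pool_id)` is unique within a table. `write_counts` followed
#' by `read_counts` is the identity on the record list.
#'
#' @param path path to a TSV file.
#' @return `read_counts`: a data.frame of allele count records.
#' @export
read_counts <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, COUNT_COLS))
    stopf("%s: expected header '%s'", path, paste(COUNT_COLS, collapse = ", "))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "integer", "character",
                                     "integer", "integer")),
    error = function(e) stopf("%s: %s (counts must be integers)",
                              path, conditionMessage(e)))
  if (nrow(df) > 0) {
    if (any(df$count_ref < 0) || any(df$count_alt < 0))
      stopf("%s: negative counts are not allowed", path)
    key <- paste(df$chrom, df$pos, df$pool_id)
    if (anyDuplicated(key))
      stopf("%s: duplicate (chrom, pos, pool_id) record", path)
  }
  df
}

#' @rdname read_counts
#' @param counts data.frame with the columns listed above.
#' @export
write_counts <- function(counts, path) {
  counts <- as.data.frame(counts)[, COUNT_COLS]
  if (nrow(counts) > 0 &&
      (any(counts$count_ref < 0) || any(counts$count_alt < 0)))
    stopf("negative counts are not allowed")
  write_tsv(counts, path)
  invisible(path)
}

# Deterministic TSV writer: tab-separated, LF, no quoting, no row names.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

INFORMATIVE_COLS <- c("chrom", "pos", "ref", "alt", "gene_ids",
                      "knp_allele", "landrace_allele", "strategy")

#' Read / write informative-SNP tables
#'
#' Informative SNPs (breed-diagnostic exonic sites) are stored as a TSV with
#' columns `chrom, pos, ref, alt, gene_ids, knp_allele, landrace_allele,
#' strategy`; `gene_ids` is a `;`-joined set. Extra per-sample allele columns
#' (`allele_<sample>`) produced under the relaxed selection mode are
#' preserved.
#'
#' @param path path to a TSV file.
#' @return `read_informative`: a data.frame.
#' @export
read_informative <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(INFORMATIVE_COLS %in% names(df)))
    stopf("%s: missing informative-SNP columns", path)
  df$pos <- as.integer(df$pos)
  df
}

#' @rdname read_informative
#' @param informative data.frame as produced by [select_informative].
#' @export
write_informative <- function(informative, path) {
  extra <- grep("^allele_", names(informative), value = TRUE)
  write_tsv(informative[, c(INFORMATIVE_COLS, extra)], path)
  invisible(path)
}

TRUTH_COLS <- c("gene_id", "true_mode", "true_paternal_fraction",
                "favored_breed")

#' Read / write simulation truth tables
#'
#' The truth table records, per simulated gene, the generating ASE mode,
#' the expected paternal expression share (for `allele_dominant` genes the
#' favored allele's share) and, for dominant genes, the favored breed.
#'
#' @param path path to a TSV file.
#' @return `read_truth`: a data.frame with one row per gene.
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  if (!all(TRUTH_COLS %in% names(df)))
    stopf("%s: missing truth columns", path)
  df
}

#' @rdname read_truth
#' @param truth data.frame with columns `gene_id`, `true_mode`,
#'   `true_paternal_fraction`, `favored_breed`.
#' @export
write_truth <- function(truth, path) {
  truth <- as.data.frame(truth)[, TRUTH_COLS]
  truth$favored_breed[is.na(truth$favored_breed)] <- ""
  write_tsv(truth, path)
  invisible(path)
}
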