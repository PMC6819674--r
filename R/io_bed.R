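#' Read a BED exon annotation
#'
#' Loads a 4+ column BED file (0-based half-open intervals, fourth column the
#' gene identifier) and unions the intervals of each gene into a sorted,
#' non-overlapping exon set. All downstream coordinates are 1-based; the
#' 0-based-to-1-based conversion happens here and only here.
#'
#' @param path path to a BED4 file.
#' @return An `exon_annotation` object wrapping a
#'   [GenomicRanges::GRanges] of unioned exons with a `gene_id`
#'   metadata column.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4) stopf("%s: BED file must have >= 4 columns", path)
  start0 <- suppressWarnings(as.numeric(df[[2]]))
  end0 <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(start0) || anyNA(end0))
    stopf("%s: non-numeric BED coordinates", path)
  bad <- which(start0 >= end0)
  if (length(bad) > 0)
    stopf("%s: start >= end at line %d", path, bad[1])
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df[[1]]),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    gene_id = as.character(df[[4]]))
  by_gene <- GenomicRanges::split(gr, gr$gene_id)
  red <- GenomicRanges::reduce(by_gene)
  flat <- unlist(red, use.names = TRUE)
  flat$gene_id <- names(flat)
  names(flat) <- NULL
  flat <- GenomicRanges::sort(flat, ignore.strand = TRUE)
  structure(list(gr = flat, genes = sort(unique(flat$gene_id))),
            class = "exon_annotation")
}

#' @export
print.exon_annotation <- function(x, ...) {
  cat(sprintf("exon_annotation: %d unioned exon intervals, %d genes\n",
              length(x$gr), length(x$genes)))
  invisible(x)
}

#' Genes whose unioned exons contain a position
#'
#' Point query against an [read_bed] annotation using 1-based coordinates.
#' A position inside the exons of two overlapping genes returns both gene
#' ids.
#'
#' @param annotation an `exon_annotation`.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return Sorted character vector of gene ids (possibly empty).
#' @export
query_genes <- function(annotation, chrom, pos) {
  stopifnot(inherits(annotation, "exon_annotation"))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, annotation$gr)
  sort(unique(annotation$gr$gene_id[S4Vectors_subjectHits(hits)]))
}

# small shim so we depend only on the GenomicRanges surface
S4Vectors_subjectHits <- function(h) {
  as.data.frame(h)$subjectHits
}

# Internal BED writer used by the dataset generator (gene exons, 0-based).
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start0", "end0", "gene_id") %in% names(df)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(df$chrom, df$start0, df$end0, df$gene_id, sep = "\t"),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
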