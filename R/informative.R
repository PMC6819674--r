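#' Select breed-informative SNPs
#'
#' An informative SNP is homozygous in every parent (or per-breed joint
#' sample) but carries different alleles in the two breeds, so every F1
#' offspring is heterozygous with a known parental origin for each allele.
#' Under strategy I the four individually sequenced parents must all be
#' called homozygous and, by default, the two same-breed parents must agree
#' (the cross design makes parentage unambiguous only then); under strategy
#' II the two per-breed joint samples must be homozygous and different. A
#' missing genotype disqualifies a site. Each selected SNP records the
#' breed-to-allele map used downstream to orient read counts by parental
#' origin.
#'
#' With `require_breed_agreement = FALSE` (strategy I only), sites where
#' the same-breed parents are homozygous for different alleles are also
#' selected provided the dam and sire differ within each cross of
#' `design`; such sites have no breed-level allele (`NA`) and instead carry
#' per-sample allele columns `allele_<sample>` for per-cross orientation.
#'
#' @param vt a [variant_table] with a `gene_ids` column (see
#'   [assign_exonic]).
#' @param strategy `"I"` or `"II"`.
#' @param breed_map named character vector mapping every sample of `vt` to
#'   a breed (`"KNP"`/`"Landrace"`).
#' @param require_breed_agreement require same-breed parents to carry the
#'   same allele (default).
#' @param design a [cross_design]; only consulted when
#'   `require_breed_agreement = FALSE`.
#' @return data.frame with columns `chrom, pos, ref, alt, gene_ids,
#'   knp_allele, landrace_allele, strategy` (plus `allele_<sample>` columns
#'   in relaxed mode).
#' @export
select_informative <- function(vt, strategy = c("I", "II"), breed_map,
                               require_breed_agreement = TRUE,
                               design = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(vt, "variant_table"))
  miss <- setdiff(vt$samples, names(breed_map))
  if (length(miss) > 0)
    stopf("sample-to-breed map is missing sample '%s'", miss[1])
  breeds <- unname(breed_map[vt$samples])
  if (!setequal(unique(breeds), c("KNP", "Landrace")))
    stopf("breed map must cover both breeds KNP and Landrace")
  if (strategy == "II" && length(vt$samples) != 2)
    stopf("strategy II requires exactly two per-breed samples")
  if (strategy == "I" && length(vt$samples) != 4)
    stopf("strategy I requires the four parent samples")
  if (!"gene_ids" %in% names(vt$sites))
    stopf("sites have no gene assignment; run assign_exonic first")

  n <- n_sites(vt)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene_ids = character(), knp_allele = character(),
                      landrace_allele = character(), strategy = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  gt <- vt$gt
  hom <- gt == "hom_ref" | gt == "hom_alt"
  all_hom <- rowSums(hom) == length(vt$samples)
  # allele code per sample: 0 = ref, 1 = alt, NA when not hom
  code <- matrix(NA_integer_, n, length(vt$samples),
                 dimnames = list(NULL, vt$samples))
  code[gt == "hom_ref"] <- 0L
  code[gt == "hom_alt"] <- 1L

  knp_cols <- vt$samples[breeds == "KNP"]
  lr_cols <- vt$samples[breeds == "Landrace"]
  knp_agree <- apply(code[, knp_cols, drop = FALSE], 1,
                     function(x) length(unique(x)) == 1)
  lr_agree <- apply(code[, lr_cols, drop = FALSE], 1,
                    function(x) length(unique(x)) == 1)
  knp_code <- code[, knp_cols[1]]
  lr_code <- code[, lr_cols[1]]

  agree_ok <- all_hom & knp_agree & lr_agree & knp_code != lr_code
  agree_ok[is.na(agree_ok)] <- FALSE

  relax_ok <- rep(FALSE, n)
  if (strategy == "I" && !require_breed_agreement) {
    if (is.null(design))
      stopf("relaxed selection needs the cross design")
    per_cross <- rep(TRUE, n)
    for (i in seq_len(nrow(design$crosses))) {
      d <- code[, design$crosses$dam[i]]
      s <- code[, design$crosses$sire[i]]
      ok <- !is.na(d) & !is.na(s) & d != s
      per_cross <- per_cross & ok
    }
    relax_ok <- all_hom & per_cross & !agree_ok
  }

  keep <- which(agree_ok | relax_ok)
  if (length(keep) == 0) return(empty)
  base_of <- function(codes, idx)
    ifelse(codes[idx] == 0L, vt$sites$ref[idx], vt$sites$alt[idx])
  out <- data.frame(
    chrom = vt$sites$chrom[keep], pos = vt$sites$pos[keep],
    ref = vt$sites$ref[keep], alt = vt$sites$alt[keep],
    gene_ids = vt$sites$gene_ids[keep],
    knp_allele = ifelse(agree_ok[keep], base_of(knp_code, keep),
                        NA_character_),
    landrace_allele = ifelse(agree_ok[keep], base_of(lr_code, keep),
                             NA_character_),
    strategy = strategy, stringsAsFactors = FALSE)
  if (any(relax_ok)) {
    for (sm in vt$samples)
      out[[paste0("allele_", sm)]] <- base_of(code[, sm], keep)
  }
  out
}

#' Compare the informative-SNP sets of the two mapping strategies
#'
#' Summarizes the overlap of two informative-SNP tables keyed by
#' `(chrom, pos)`: total per strategy, shared, and unique to each. The
#' identities `shared + unique_i = count_i` hold by construction.
#'
#' @param set_i,set_ii informative-SNP data.frames.
#' @return Named list `count_i, count_ii, shared, unique_i, unique_ii`.
#' @export
compare_strategies <- function(set_i, set_ii) {
  key_i <- paste(set_i$chrom, set_i$pos)
  key_ii <- paste(set_ii$chrom, set_ii$pos)
  shared <- length(intersect(key_i, key_ii))
  list(count_i = length(key_i), count_ii = length(key_ii), shared = shared,
       unique_i = length(key_i) - shared,
       unique_ii = length(key_ii) - shared)
}
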