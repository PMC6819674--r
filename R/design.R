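#' Describe a reciprocal cross design
#'
#' A cross design names the two reciprocal crosses (dam and sire parent
#' samples swapped between breeds), the four offspring RNA pools (one male
#' and one female pool per cross, each a pool of littermates), and the breed
#' of every parent sample. Parent-of-origin orientation of allele counts is
#' derived from it: at an informative SNP the sire breed's allele is the
#' paternal allele of every offspring in that cross.
#'
#' @param crosses data.frame with columns `cross_id`, `dam`, `sire`
#'   (parent sample names); exactly two rows, reciprocal by breed.
#' @param pools data.frame with columns `pool_id`, `cross_id`, `sex`
#'   (`"M"`/`"F"`); one male and one female pool per cross.
#' @param breeds named character vector mapping parent sample names to
#'   breed labels (`"KNP"` or `"Landrace"`).
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(crosses, pools, breeds) {
  crosses <- as.data.frame(crosses)
  pools <- as.data.frame(pools)
  stopifnot(all(c("cross_id", "dam", "sire") %in% names(crosses)),
            all(c("pool_id", "cross_id", "sex") %in% names(pools)))
  if (nrow(crosses) != 2) stopf("a reciprocal design has exactly two crosses")
  miss <- setdiff(c(crosses$dam, crosses$sire), names(breeds))
  if (length(miss) > 0)
    stopf("breed of parent sample '%s' not given", miss[1])
  db <- unname(breeds[crosses$dam]); sb <- unname(breeds[crosses$sire])
  if (any(db == sb)) stopf("dam and sire of a cross must be different breeds")
  if (!(db[1] == sb[2] && sb[1] == db[2]))
    stopf("crosses are not reciprocal (dam/sire breeds must swap)")
  if (anyDuplicated(pools$pool_id)) stopf("duplicate pool_id")
  if (!all(pools$cross_id %in% crosses$cross_id))
    stopf("pool references unknown cross_id")
  for (cid in crosses$cross_id) {
    sx <- sort(pools$sex[pools$cross_id == cid])
    if (!identical(sx, c("F", "M")))
      stopf("cross %s needs one male and one female pool", cid)
  }
  structure(list(crosses = crosses, pools = pools, breeds = breeds),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  for (i in 1:2) {
    cid <- x$crosses$cross_id[i]
    cat(sprintf("cross %s: dam %s (%s) x sire %s (%s); pools %s\n",
                cid, x$crosses$dam[i], x$breeds[[x$crosses$dam[i]]],
                x$crosses$sire[i], x$breeds[[x$crosses$sire[i]]],
                paste(x$pools$pool_id[x$pools$cross_id == cid],
                      collapse = ", ")))
  }
  invisible(x)
}

#' Default KNP x Landrace reciprocal design
#'
#' Two breeds, one male and one female parent each, crossed reciprocally.
#' Cross labels follow the dam-first convention by default: `"KxL"` is the
#' cross with the KNP dam and the Landrace sire. Set `dam_first = FALSE` to
#' read labels sire-first instead; all classification downstream is
#' symmetric in this convention.
#'
#' @param dam_first interpret "AxB" cross labels as dam A x sire B.
#' @return A [cross_design].
#' @export
default_cross_design <- function(dam_first = TRUE) {
  breeds <- c(KNP_M = "KNP", KNP_F = "KNP",
              LR_M = "Landrace", LR_F = "Landrace")
  if (dam_first) {
    crosses <- data.frame(cross_id = c("KxL", "LxK"),
                          dam = c("KNP_F", "LR_F"),
                          sire = c("LR_M", "KNP_M"))
  } else {
    crosses <- data.frame(cross_id = c("KxL", "LxK"),
                          dam = c("LR_F", "KNP_F"),
                          sire = c("KNP_M", "LR_M"))
  }
  pools <- data.frame(
    pool_id = c("KxL_M", "KxL_F", "LxK_M", "LxK_F"),
    cross_id = c("KxL", "KxL", "LxK", "LxK"),
    sex = c("M", "F", "M", "F"))
  cross_design(crosses, pools, breeds)
}

# pool_id -> breed of the sire of that pool's cross
sire_breed <- function(design, pool_id) {
  ci <- design$pools$cross_id[match(pool_id, design$pools$pool_id)]
  if (anyNA(ci)) stopf("unknown pool_id '%s'", pool_id[is.na(ci)][1])
  sire <- design$crosses$sire[match(ci, design$crosses$cross_id)]
  unname(design$breeds[sire])
}

# pool ids in design order
design_pools <- function(design) design$pools$pool_id
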