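#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed; keeps values in 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * k) %% .Machine$integer.max)
}

# 32-bit polynomial rolling hash of a string, returned as 8 hex digits.
# Used only to stamp provenance records; not cryptographic.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")
ASE_MODES <- c("biallelic", "paternal_imprinted", "maternal_imprinted",
               "allele_dominant")
ASE_PATTERNS <- c("paternal_biased", "maternal_biased", "allele_dominant",
                  "biallelic", "inconsistent", "insufficient_data")
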