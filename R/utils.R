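#' @keywords internal
"_PACKAGE"

#' @importFrom stats median p.adjust pchisq phyper quantile rbinom rnbinom
#'   rpois runif setNames wilcox.test chisq.test
#' @importFrom utils read.table write.table head
NULL

# Consequence classes counted as putatively protein-altering; everything
# else (synonymous, deep intronic, ...) is excluded from the rare-variant
# analysis.
INCLUDED_CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift_indel", "inframe_indel",
  "splice_canonical"
)

ALL_CONSEQUENCES <- c(INCLUDED_CONSEQUENCES, "synonymous", "other")

#' Normalize HGNC-style gene symbols
#'
#' Uppercases and strips surrounding whitespace. Matching everywhere in the
#' package is exact after this normalization; no alias resolution is
#' attempted (aliases are an annotation-time concern).
#'
#' @param x character vector of gene symbols.
#' @return character vector, same length.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Build a variant key
#'
#' Canonical `chrom:pos:ref:alt` identifier used to join genotype rows,
#' annotation rows and truth records.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

# Seed derivation for per-family RNG streams: deterministic in
# (seed, index), kept inside 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483646L) + 1L
}
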