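# Relatedness verification. The within-pair KING-robust estimator is used
# to confirm that declared parent-offspring pairs are genuine before any
# de novo call is believed: kinship ~= 0.25 for parent-offspring with an
# IBS0 rate near zero, ~= 0.5 for duplicates/MZ twins, ~= 0 for
# unrelated pairs, regardless of allele-frequency misspecification.

#' KING-robust kinship for one sample pair
#'
#' Given genotype dosages (0/1/2 alternate-allele counts) for two samples
#' over shared biallelic sites, computes
#' `kinship = (N_het,het - 2 * N_opp_hom) / (N_het1 + N_het2)`
#' where `N_het,het` counts sites heterozygous in both samples,
#' `N_opp_hom` counts opposite homozygotes (IBS0), and `N_het,i` counts
#' heterozygous sites in sample i. Sites missing in either sample are
#' dropped.
#'
#' @param g1,g2 integer vectors of dosages (`NA` = missing), same length.
#' @param pair optional character(2) of sample ids for labelling.
#' @param min_sites minimum informative (complete) sites; default 200.
#' @return object of class `KinshipEstimate`: list with `pair`, `kinship`,
#'   `ibs0_rate`, `n_sites`.
#' @export
estimate_kinship <- function(g1, g2, pair = c("sample1", "sample2"),
                             min_sites = 200L) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < min_sites) {
    stop_("only ", n, " informative sites for pair ",
          paste(pair, collapse = "-"),
          "; at least ", min_sites, " are required - add sites")
  }
  n_het_het <- sum(g1 == 1L & g2 == 1L)
  n_opp_hom <- sum((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L))
  n_het1 <- sum(g1 == 1L)
  n_het2 <- sum(g2 == 1L)
  if (n_het1 + n_het2 == 0L) {
    stop_("no heterozygous sites in pair ", paste(pair, collapse = "-"),
          "; kinship undefined - add informative sites")
  }
  structure(list(
    pair = pair,
    kinship = (n_het_het - 2 * n_opp_hom) / (n_het1 + n_het2),
    ibs0_rate = n_opp_hom / n,
    n_sites = n
  ), class = "KinshipEstimate")
}

#' @exportS3Method base::print
print.KinshipEstimate <- function(x, ...) {
  cat(sprintf("KinshipEstimate %s-%s: kinship = %.4f, IBS0 = %.4f (%d sites)\n",
              x$pair[1], x$pair[2], x$kinship, x$ibs0_rate, x$n_sites))
  invisible(x)
}

#' Genotype dosage matrix from a long genotype table
#'
#' @param genotypes long data.frame with `variant_id`, `sample_id`, `gt`.
#' @param samples sample ids to include (columns).
#' @param variant_ids optional variant ids to include (rows); default all.
#' @return integer matrix sites x samples of alternate-allele dosages.
#' @export
genotype_dosage <- function(genotypes, samples,
                            variant_ids = unique(genotypes$variant_id)) {
  sub <- genotypes[genotypes$sample_id %in% samples &
                     genotypes$variant_id %in% variant_ids, , drop = FALSE]
  m <- matrix(NA_integer_, nrow = length(variant_ids),
              ncol = length(samples),
              dimnames = list(variant_ids, samples))
  ri <- match(sub$variant_id, variant_ids)
  ci <- match(sub$sample_id, samples)
  m[cbind(ri, ci)] <- gt_alt_count(sub$gt)
  m
}

#' Verify relatedness of a trio
#'
#' Both declared parent-offspring pairs must show KING-robust kinship in
#' `po_range` with an IBS0 rate below `max_ibs0`; otherwise the family is
#' reported as failing and should be excluded from de novo analysis.
#'
#' @param dosage dosage matrix (sites x samples) covering the trio.
#' @param trio single-row trio record.
#' @param po_range acceptable parent-offspring kinship band; default
#'   `c(0.15, 0.40)`.
#' @param max_ibs0 maximum IBS0 rate for a parent-offspring pair;
#'   default 0.02.
#' @param min_sites passed to [estimate_kinship()].
#' @return list with `pass` (logical), `father` and `mother`
#'   `KinshipEstimate`s.
#' @export
verify_trio_relatedness <- function(dosage, trio, po_range = c(0.15, 0.40),
                                    max_ibs0 = 0.02, min_sites = 200L) {
  kf <- estimate_kinship(dosage[, trio$proband_id], dosage[, trio$father_id],
                         pair = c(trio$proband_id, trio$father_id),
                         min_sites = min_sites)
  km <- estimate_kinship(dosage[, trio$proband_id], dosage[, trio$mother_id],
                         pair = c(trio$proband_id, trio$mother_id),
                         min_sites = min_sites)
  ok <- function(k) {
    k$kinship >= po_range[1] && k$kinship <= po_range[2] &&
      k$ibs0_rate <= max_ibs0
  }
  list(pass = ok(kf) && ok(km), father = kf, mother = km)
}
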