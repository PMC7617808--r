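# Trio inheritance classification: parental-origin assignment, Mendelian
# violation (de novo) detection with VAF-based mosaicism banding,
# compound-heterozygote pairing and outlier-proband flagging.

ORIGIN_LEVELS <- c(
  "paternal", "maternal", "biparental_ambiguous", "de_novo_germline",
  "de_novo_mosaic_suspect", "homozygous_recessive", "compound_het_partner",
  "unresolved"
)

#' Alternate-allele count of a genotype string
#'
#' Parses diploid `GT` strings (`0/1`, `1|1`, ...) into alternate-allele
#' dosage; any missing allele yields `NA`.
#'
#' @param gt character vector of genotype strings.
#' @return integer vector of dosages in `{0, 1, 2, NA}`.
#' @export
gt_alt_count <- function(gt) {
  norm <- gsub("|", "/", gt, fixed = TRUE)
  vapply(norm, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "/", fixed = TRUE)[[1L]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify inheritance of one variant in one trio
#'
#' Determines the origin of a proband's alternate allele by comparison
#' with the parental genotypes:
#' * proband het, exactly one parent carries the allele: `paternal` /
#'   `maternal`;
#' * both parents carry it, proband het: `biparental_ambiguous` (phase
#'   unknowable without reads);
#' * proband hom-alt with both parents carrying: `homozygous_recessive`;
#' * both parents hom-ref and the quality gates pass: a Mendelian
#'   violation, banded by proband VAF into `de_novo_germline`
#'   (VAF >= `mosaic_vaf[2]`) or `de_novo_mosaic_suspect`
#'   (`mosaic_vaf[1] <= VAF < mosaic_vaf[2]`, the post-zygotic signature);
#' * anything with missing genotypes or failed gates: `unresolved` -
#'   degraded evidence never promotes to de novo.
#'
#' Gates for a de novo call: proband `dp >= min_dp`, `gq >= min_gq`,
#' `ad_alt >= min_alt_reads`; each parent `dp >= min_dp` with
#' `ad_alt <= max_parent_alt`. Hemizygous male X calls are compared
#' against the mother only and flagged `hemizygous` in the notes.
#'
#' @param proband,father,mother single genotype rows (lists/data.frames
#'   with `gt`, `ad_ref`, `ad_alt`, `dp`, `gq`, `vaf`).
#' @param chrom chromosome name, used for X-hemizygosity handling.
#' @param proband_sex `female`/`male`/`unknown`.
#' @param gates see [default_gates()].
#' @param mosaic_vaf numeric(2): the mosaic VAF band, default
#'   `c(0.10, 0.30)` - a round boundary containing the descriptive
#'   10-26% band seen in somatic-mosaicism cases.
#' @return list with `origin`, `quality_pass`, `notes`.
#' @export
classify_inheritance <- function(proband, father, mother, chrom = "1",
                                 proband_sex = "unknown",
                                 gates = default_gates(),
                                 mosaic_vaf = c(0.10, 0.30)) {
  p_alt <- gt_alt_count(proband$gt)
  f_alt <- gt_alt_count(father$gt)
  m_alt <- gt_alt_count(mother$gt)
  hemi <- chrom %in% c("X", "chrX") && identical(proband_sex, "male")

  res <- function(origin, pass, notes = "") {
    list(origin = origin, quality_pass = pass, notes = notes)
  }
  if (is.na(p_alt)) return(res("unresolved", FALSE, "proband genotype missing"))
  if (p_alt == 0L) return(res("unresolved", TRUE, "proband carries no alt"))

  pro_qc <- !is.na(proband$dp) && proband$dp >= gates$min_dp &&
    !is.na(proband$gq) && proband$gq >= gates$min_gq
  dn_pro <- pro_qc && !is.na(proband$ad_alt) &&
    proband$ad_alt >= gates$min_alt_reads
  parent_clean <- function(gp) {
    !is.na(gp$dp) && gp$dp >= gates$min_dp &&
      !is.na(gp$ad_alt) && gp$ad_alt <= gates$max_parent_alt
  }
  band <- function(note = "") {
    vaf <- proband$vaf
    if (is.na(vaf)) return(res("unresolved", FALSE,
                               paste0("de novo candidate, VAF undefined", note)))
    if (vaf >= mosaic_vaf[2]) return(res("de_novo_germline", TRUE, trimws(note)))
    if (vaf >= mosaic_vaf[1]) {
      return(res("de_novo_mosaic_suspect", TRUE,
                 trimws(paste0("low VAF ", round(vaf, 3), note))))
    }
    res("unresolved", FALSE,
        paste0("de novo candidate below mosaic VAF floor", note))
  }

  if (hemi) {
    # Male X: single parental comparison against the mother; the father
    # does not transmit an X to his son.
    if (is.na(m_alt)) return(res("unresolved", FALSE,
                                 "hemizygous; mother genotype missing"))
    if (m_alt > 0L) return(res("maternal", pro_qc, "hemizygous"))
    if (dn_pro && parent_clean(mother)) return(band(" hemizygous"))
    return(res("unresolved", FALSE, "hemizygous; de novo gates failed"))
  }

  if (is.na(f_alt) || is.na(m_alt)) {
    return(res("unresolved", FALSE, "parental genotype missing"))
  }
  if (f_alt == 0L && m_alt == 0L) {
    if (dn_pro && parent_clean(father) && parent_clean(mother)) return(band())
    return(res("unresolved", FALSE, "de novo gates failed"))
  }
  if (p_alt == 2L && f_alt > 0L && m_alt > 0L) {
    return(res("homozygous_recessive", pro_qc, ""))
  }
  if (f_alt > 0L && m_alt > 0L) return(res("biparental_ambiguous", pro_qc, ""))
  if (f_alt > 0L) return(res("paternal", pro_qc, ""))
  res("maternal", pro_qc, "")
}

#' Classify inheritance for every alt-carrying variant of one trio
#'
#' Deterministic, order-independent application of
#' [classify_inheritance()] across a trio's variant set. Only variants
#' where the proband carries the alternate allele (or has a missing
#' genotype while a parent carries it) generate calls; the sum of
#' per-origin counts therefore equals the proband's alt-carrying variant
#' count.
#'
#' @param variants variant table (needs `variant_id`, `chrom`).
#' @param genotypes long genotype table covering the trio's samples.
#' @param trio single-row trio record.
#' @inheritParams classify_inheritance
#' @return data.frame: `variant_id`, `family_id`, `proband_id`, `origin`,
#'   `quality_pass`, `vaf`, `notes`.
#' @export
classify_trio_variants <- function(variants, genotypes, trio,
                                   gates = default_gates(),
                                   mosaic_vaf = c(0.10, 0.30)) {
  gsub_ <- function(id) {
    g <- genotypes[genotypes$sample_id == id, , drop = FALSE]
    g[match(variants$variant_id, g$variant_id), , drop = FALSE]
  }
  gp <- gsub_(trio$proband_id)
  gf <- gsub_(trio$father_id)
  gm <- gsub_(trio$mother_id)
  carries <- gt_alt_count(gp$gt)
  idx <- which(!is.na(carries) & carries > 0L)
  if (length(idx) == 0L) {
    return(data.frame(variant_id = character(), family_id = character(),
                      proband_id = character(), origin = character(),
                      quality_pass = logical(), vaf = numeric(),
                      notes = character(), stringsAsFactors = FALSE))
  }
  calls <- lapply(idx, function(i) {
    classify_inheritance(gp[i, ], gf[i, ], gm[i, ],
                         chrom = variants$chrom[i],
                         proband_sex = trio$proband_sex,
                         gates = gates, mosaic_vaf = mosaic_vaf)
  })
  data.frame(
    variant_id = variants$variant_id[idx],
    family_id = trio$family_id,
    proband_id = trio$proband_id,
    origin = vapply(calls, `[[`, "", "origin"),
    quality_pass = vapply(calls, `[[`, NA, "quality_pass"),
    vaf = gp$vaf[idx],
    notes = vapply(calls, `[[`, "", "notes"),
    stringsAsFactors = FALSE
  )
}

#' Enumerate compound-heterozygous pairs per gene
#'
#' Pairs of rare variants in the same gene, one of paternal and one of
#' maternal origin, in the same proband. Variants with
#' `biparental_ambiguous` origin are excluded from pairing (the phase is
#' unknowable), as are de novo and unresolved calls.
#'
#' @param calls inheritance calls (from [classify_trio_variants()]) for
#'   one or more probands.
#' @param variants variant table with `variant_id` and `gene`.
#' @return data.frame: `proband_id`, `gene`, `paternal_variant`,
#'   `maternal_variant`, one row per trans pair.
#' @export
find_compound_hets <- function(calls, variants) {
  calls <- calls[calls$origin %in% c("paternal", "maternal"), , drop = FALSE]
  calls$gene <- variants$gene[match(calls$variant_id, variants$variant_id)]
  calls <- calls[!is.na(calls$gene), , drop = FALSE]
  out <- list()
  for (grp in split(calls, list(calls$proband_id, calls$gene), drop = TRUE)) {
    pat <- grp$variant_id[grp$origin == "paternal"]
    mat <- grp$variant_id[grp$origin == "maternal"]
    if (length(pat) == 0L || length(mat) == 0L) next
    pairs <- expand.grid(paternal_variant = pat, maternal_variant = mat,
                         stringsAsFactors = FALSE)
    pairs$proband_id <- grp$proband_id[1L]
    pairs$gene <- grp$gene[1L]
    out[[length(out) + 1L]] <- pairs
  }
  if (length(out) == 0L) {
    return(data.frame(proband_id = character(), gene = character(),
                      paternal_variant = character(),
                      maternal_variant = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("proband_id", "gene", "paternal_variant", "maternal_variant")]
}

#' Flag probands with outlying de novo counts
#'
#' Probands whose de novo count exceeds `Q3 + 3 * IQR` of the cohort
#' distribution are flagged as candidate somatic-mosaicism cases
#' (a large excess of post-zygotic calls mimics an implausible germline
#' de novo burden). Ties at the threshold are broken toward not flagging
#' (strict inequality). With fewer than 5 probands no flagging is
#' attempted.
#'
#' @param counts named integer vector of per-proband de novo counts.
#' @return list with `flagged` (character vector of proband ids),
#'   `threshold`, `q3`, `iqr`.
#' @export
flag_outlier_probands <- function(counts) {
  if (length(counts) < 5L) {
    warn_("fewer than 5 probands; outlier flagging skipped")
    return(list(flagged = character(), threshold = NA_real_,
                q3 = NA_real_, iqr = NA_real_))
  }
  q <- quantile(counts, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  thr <- q[2] + 3 * iqr
  list(flagged = names(counts)[counts > thr], threshold = thr,
       q3 = q[2], iqr = iqr)
}

#' Per-proband fraction of low-VAF de novo calls
#'
#' The descriptive companion to outlier flagging: among a proband's
#' de novo calls, the fraction with VAF below `cutoff`. An excess of
#' low-VAF calls points at post-zygotic (somatic) origin.
#'
#' @param calls inheritance calls.
#' @param cutoff VAF boundary; default 0.30.
#' @return named numeric vector (proband -> fraction; `NaN` when the
#'   proband has no de novo calls).
#' @export
low_vaf_fraction <- function(calls, cutoff = 0.30) {
  dn <- calls[startsWith(calls$origin, "de_novo"), , drop = FALSE]
  probands <- unique(calls$proband_id)
  out <- setNames(rep(NaN, length(probands)), probands)
  if (nrow(dn) > 0L) {
    frac <- tapply(dn$vaf < cutoff, dn$proband_id, mean, na.rm = TRUE)
    out[names(frac)] <- frac
  }
  out
}
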