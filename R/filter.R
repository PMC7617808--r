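# The rare-variant filter cascade: consequence inclusion, dual-population
# MAF filtering, read-support gates, panel tagging and the three-tool
# damage-prediction consensus.

#' Classify a variant consequence annotation
#'
#' Maps free-text consequence annotations onto the enum used throughout
#' the package: `missense`, `nonsense`, `frameshift_indel`,
#' `inframe_indel`, `splice_canonical`, `synonymous`, `other`. Splice
#' annotations count as canonical only within the +1/+2 donor and -1/-2
#' acceptor positions: when `splice_offset` is supplied (distance in
#' nucleotides from the exon-intron boundary, sign-free), an annotation of
#' `splice` with `|offset| <= 2` is `splice_canonical` and anything deeper
#' is `other`. Unknown strings map to `other` with a warning.
#'
#' @param x character vector of consequence annotations.
#' @param splice_offset optional numeric vector of intronic offsets for
#'   splice-region annotations.
#' @return character vector of consequence enums.
#' @export
classify_consequence <- function(x, splice_offset = NULL) {
  x0 <- tolower(trimws(as.character(x)))
  out <- rep("other", length(x0))
  out[x0 %in% c("missense", "missense_variant")] <- "missense"
  out[x0 %in% c("nonsense", "stop_gained", "stop_gain")] <- "nonsense"
  out[grepl("^frameshift", x0)] <- "frameshift_indel"
  out[grepl("^inframe", x0) | x0 %in% c("inframe_insertion",
                                        "inframe_deletion")] <- "inframe_indel"
  out[x0 %in% c("synonymous", "synonymous_variant")] <- "synonymous"
  is_splice <- grepl("splice", x0)
  out[x0 %in% c("splice_canonical", "splice_donor_variant",
                "splice_acceptor_variant", "splice_donor",
                "splice_acceptor")] <- "splice_canonical"
  if (!is.null(splice_offset)) {
    generic_splice <- is_splice & out == "other"
    canonical <- generic_splice & !is.na(splice_offset) &
      abs(splice_offset) <= 2
    out[canonical] <- "splice_canonical"
  }
  unknown <- !(x0 %in% c(
    "missense", "missense_variant", "nonsense", "stop_gained", "stop_gain",
    "synonymous", "synonymous_variant", "splice_canonical",
    "splice_donor_variant", "splice_acceptor_variant", "splice_donor",
    "splice_acceptor", "other"
  )) & !grepl("^frameshift|^inframe", x0) & !is_splice
  if (any(unknown & !is.na(x0))) {
    warn_("unknown consequence string(s) mapped to 'other': ",
          paste(unique(x0[unknown & !is.na(x0)]), collapse = ", "))
  }
  out[is.na(x0)] <- "other"
  out
}

#' Is a consequence class included in the rare-variant analysis?
#'
#' The screen keeps missense, nonsense, coding-region indels and canonical
#' splice-site variants; synonymous and everything else is excluded.
#'
#' @param consequence character vector of consequence enums.
#' @return logical vector.
#' @export
consequence_included <- function(consequence) {
  consequence %in% INCLUDED_CONSEQUENCES
}

#' Dual-population MAF filter
#'
#' A variant passes when its frequency does not exceed the threshold in
#' *both* reference populations (global and East-Asian). An absent
#' frequency is treated as passing — a variant never observed in the
#' reference panels is by definition rare, never frequency 0 coerced from
#' missingness. Variants with frequency strictly greater than the
#' threshold are excluded; frequency exactly at the threshold passes.
#'
#' @param af_global,af_eas numeric vectors of allele frequencies in
#'   `[0, 1]`, `NA` for absent.
#' @param threshold MAF cut-off; default 0.005.
#' @return logical vector: `TRUE` = rare, keep.
#' @export
maf_filter <- function(af_global, af_eas, threshold = 0.005) {
  pass_g <- is.na(af_global) | af_global <= threshold
  pass_e <- is.na(af_eas) | af_eas <= threshold
  pass_g & pass_e
}

#' Three-tool damage-prediction consensus
#'
#' Combines PolyPhen-2, SIFT and CADD into a consensus call. Each
#' available tool casts one vote: PolyPhen-2 `probably_damaging` or
#' `possibly_damaging`, SIFT `deleterious`, CADD phred at or above
#' `cadd_cutoff`. A variant is `likely_damaging` when at least
#' `min_votes` of the available tools vote damaging and at least two
#' tools are available; with fewer than two tools available the call is
#' `indeterminate`.
#'
#' @param polyphen character: `probably_damaging`, `possibly_damaging`,
#'   `benign`, or `NA`.
#' @param sift character: `deleterious`, `tolerated`, or `NA`.
#' @param cadd_phred numeric scaled CADD score, `NA` when absent.
#' @param cadd_cutoff CADD phred treated as damaging; default 20.
#' @param min_votes votes required for `likely_damaging`; default 2.
#' @return character vector in `{likely_damaging, not_damaging,
#'   indeterminate}`.
#' @export
damage_consensus <- function(polyphen, sift, cadd_phred,
                             cadd_cutoff = 20, min_votes = 2) {
  pp_vote <- ifelse(is.na(polyphen), NA,
                    polyphen %in% c("probably_damaging", "possibly_damaging"))
  sift_vote <- ifelse(is.na(sift), NA, sift == "deleterious")
  cadd_vote <- ifelse(is.na(cadd_phred), NA, cadd_phred >= cadd_cutoff)
  votes_mat <- cbind(pp_vote, sift_vote, cadd_vote)
  n_avail <- rowSums(!is.na(votes_mat))
  n_votes <- rowSums(votes_mat, na.rm = TRUE)
  ifelse(n_avail < 2, "indeterminate",
         ifelse(n_votes >= min_votes, "likely_damaging", "not_damaging"))
}

#' Tag variants with SLE panel membership
#'
#' Adds one logical column per panel (`in_<panel>`) and a combined tag
#' string. Tags are not exclusive: a gene can sit in several panels.
#'
#' @param variants data.frame with a `gene` column.
#' @param panels named list of `GenePanel` objects.
#' @return `variants` with the membership columns and `panel_tag` added.
#' @export
panel_intersect <- function(variants, panels) {
  genes <- normalize_symbols(variants$gene)
  for (nm in names(panels)) {
    variants[[paste0("in_", nm)]] <- genes %in% panels[[nm]]$genes
  }
  member_cols <- paste0("in_", names(panels))
  variants$panel_tag <- apply(
    as.matrix(variants[, member_cols, drop = FALSE]), 1L,
    function(r) if (any(r)) paste(names(panels)[r], collapse = ",") else "none"
  )
  variants
}

#' Default read-support quality gates
#'
#' Gates applied to a proband's genotype before a variant qualifies, and
#' to parental genotypes before a Mendelian violation is believed:
#' proband depth >= `min_dp`, genotype quality >= `min_gq`, alternate
#' reads >= `min_alt_reads` (the read-support reading of the minor allele
#' count filter); each parent depth >= `min_dp` with at most
#' `max_parent_alt` alternate reads (tolerating stray sequencing error).
#'
#' @param min_dp minimum depth; default 10.
#' @param min_gq minimum genotype quality; default 20.
#' @param min_alt_reads minimum proband alternate-allele reads; default 5.
#' @param max_parent_alt maximum parental alternate reads compatible with
#'   a de novo call; default 1.
#' @return named list of gates.
#' @export
default_gates <- function(min_dp = 10, min_gq = 20, min_alt_reads = 5,
                          max_parent_alt = 1) {
  list(min_dp = min_dp, min_gq = min_gq, min_alt_reads = min_alt_reads,
       max_parent_alt = max_parent_alt)
}

#' Run the rare-variant filter cascade
#'
#' Applies the filtering stages in order over a carrier table (one row per
#' proband x alternate-allele record) and logs per-stage attrition.
#' Default stage order: `decompose` (assert biallelic records; performed
#' upstream by the VCF reader, counted here), `consequence` (keep
#' protein-altering classes), `maf` (dual-population threshold), `qc`
#' (read-support gates on the carrier genotype), `panel` (membership
#' tagging; annotates, removes nothing).
#'
#' @param carriers data.frame with at least `variant_id`, `gene`,
#'   `consequence`, `af_global`, `af_eas`, `dp`, `gq`, `ad_alt`.
#' @param panels named list of `GenePanel`s for the tagging stage.
#' @param maf_threshold MAF cut-off; default 0.005.
#' @param gates read-support gates, see [default_gates()].
#' @param stages character vector ordering the stages.
#' @param mac_mode `"reads"` (default): the minor-allele-count filter is
#'   the proband read-support gate; `"cohort"`: additionally drop
#'   variants whose total alternate-allele count across carriers is below
#'   `gates$min_alt_reads`.
#' @return list with `variants` (surviving rows, panel-tagged) and
#'   `attrition` (data.frame `stage`, `n_in`, `n_out`).
#' @export
run_filter_cascade <- function(carriers, panels, maf_threshold = 0.005,
                               gates = default_gates(),
                               stages = c("decompose", "consequence", "maf",
                                          "qc", "panel"),
                               mac_mode = c("reads", "cohort")) {
  mac_mode <- match.arg(mac_mode)
  cur <- carriers
  attr_log <- data.frame(stage = character(), n_in = integer(),
                         n_out = integer(), stringsAsFactors = FALSE)
  for (st in stages) {
    n_in <- nrow(cur)
    cur <- switch(
      st,
      decompose = {
        if (any(grepl(",", cur$variant_id, fixed = TRUE))) {
          stop_("multi-allelic records reached the cascade undecomposed")
        }
        cur
      },
      consequence = cur[consequence_included(cur$consequence), , drop = FALSE],
      maf = cur[maf_filter(cur$af_global, cur$af_eas, maf_threshold), ,
                drop = FALSE],
      qc = {
        keep <- !is.na(cur$dp) & cur$dp >= gates$min_dp &
          !is.na(cur$gq) & cur$gq >= gates$min_gq &
          !is.na(cur$ad_alt) & cur$ad_alt >= gates$min_alt_reads
        cur <- cur[keep, , drop = FALSE]
        if (mac_mode == "cohort" && nrow(cur) > 0L) {
          ac <- tapply(cur$ad_alt > 0, cur$variant_id, sum)
          cur <- cur[ac[cur$variant_id] >= gates$min_alt_reads, ,
                     drop = FALSE]
        }
        cur
      },
      panel = panel_intersect(cur, panels),
      stop_("unknown cascade stage '", st, "'")
    )
    attr_log <- rbind(attr_log, data.frame(stage = st, n_in = n_in,
                                           n_out = nrow(cur)))
  }
  if (nrow(cur) == 0L) warn_("filter cascade produced an empty variant set")
  list(variants = cur, attrition = attr_log)
}

#' Per-proband panel category
#'
#' Classifies each proband by where its qualifying rare variants fall:
#' `monogenic_carrier` (at least one variant in a monogenic-SLE gene),
#' `gwas_only` (variants only in GWAS genes), or `none`.
#'
#' @param filtered cascade-surviving carrier table with `proband_id` and
#'   `in_monogenic` / `in_gwas` columns.
#' @param proband_ids all proband ids in the cohort (so carriers of
#'   nothing are reported as `none`).
#' @return named character vector, one category per proband.
#' @export
proband_panel_category <- function(filtered, proband_ids) {
  cat_of <- setNames(rep("none", length(proband_ids)), proband_ids)
  if (nrow(filtered) > 0L) {
    mono <- tapply(filtered$in_monogenic, filtered$proband_id, any)
    gwas <- tapply(filtered$in_gwas, filtered$proband_id, any)
    for (p in names(mono)) {
      if (!p %in% proband_ids) next
      cat_of[p] <- if (isTRUE(mono[[p]])) "monogenic_carrier"
      else if (isTRUE(gwas[[p]])) "gwas_only" else "none"
    }
  }
  cat_of
}
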