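# End-to-end orchestration: relatedness checks, per-trio inheritance
# classification, the filter cascade, burden statistics, prioritization,
# and a machine-readable report with every threshold echoed for
# provenance.

#' Run the full trio analysis
#'
#' Orchestrates all stages over a cohort: (1) KING-robust relatedness
#' verification per trio (families failing the parent-offspring check are
#' excluded and logged); (2) inheritance classification of every
#' alt-carrying proband variant; (3) the rare-variant filter cascade with
#' attrition logging; (4) per-proband burden tables, proband categories,
#' compound-heterozygote pairs, de novo counts, outlier flags and low-VAF
#' fractions; (5) case-control statistics when control count tables are
#' supplied; (6) over-representation analysis and candidate-gene
#' prioritization when a gene-set collection and expression matrix are
#' supplied (outlier probands' de novo genes are excluded from the
#' enrichment query, matching the cohort analysis convention).
#'
#' @param cohort a `TrioCohortSim` (from [simulate_cohort()]) or a
#'   directory path written by [write_cohort()].
#' @param controls optional list with `rare_counts`, `denovo_counts` and
#'   optionally `gene_carriers`, e.g. from [simulate_controls()].
#' @param gmt optional named list of gene sets (from [read_gmt()]).
#' @param expr optional expression matrix (from [read_expression()]).
#' @param maf_threshold MAF cut-off for the cascade; default 0.005.
#' @param gates read-support gates; default [default_gates()].
#' @param mosaic_vaf mosaic VAF band; default `c(0.10, 0.30)`.
#' @param kinship_range acceptable parent-offspring kinship band.
#' @param expression_mode passed to [expression_criterion()].
#' @param ora_background gene universe for the enrichment test; default
#'   all genes present in the annotation table. Supply the full
#'   exome-scale universe of the annotation source when available — a
#'   background restricted to variant-carrying genes makes the query a
#'   dense fraction of the universe and dilutes enrichment.
#' @return a `TrioReport`: nested list of tables and statistics; see the
#'   vignette for the schema.
#' @export
run_trio_pipeline <- function(cohort, controls = NULL, gmt = NULL,
                              expr = NULL, maf_threshold = 0.005,
                              gates = default_gates(),
                              mosaic_vaf = c(0.10, 0.30),
                              kinship_range = c(0.15, 0.40),
                              expression_mode = "argmax",
                              ora_background = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  ped <- cohort$pedigree
  variants <- cohort$variants
  genotypes <- cohort$genotypes
  panels <- cohort$panels

  # Stage 1: relatedness. De novo calls are only believable in verified
  # biological trios.
  kin_log <- lapply(seq_len(nrow(ped)), function(k) {
    trio <- ped[k, ]
    dose <- genotype_dosage(
      genotypes[genotypes$sample_id %in%
                  c(trio$proband_id, trio$father_id, trio$mother_id), ,
                drop = FALSE],
      samples = c(trio$proband_id, trio$father_id, trio$mother_id),
      variant_ids = cohort$backbone_ids
    )
    v <- verify_trio_relatedness(dose, trio, po_range = kinship_range)
    data.frame(family_id = trio$family_id, pass = v$pass,
               kinship_father = v$father$kinship,
               kinship_mother = v$mother$kinship,
               ibs0_father = v$father$ibs0_rate,
               ibs0_mother = v$mother$ibs0_rate,
               stringsAsFactors = FALSE)
  })
  kin_log <- do.call(rbind, kin_log)
  excluded_families <- kin_log$family_id[!kin_log$pass]
  ped_ok <- ped[!ped$family_id %in% excluded_families, , drop = FALSE]

  # Stage 2: inheritance classification per trio.
  calls <- lapply(seq_len(nrow(ped_ok)), function(k) {
    trio <- ped_ok[k, ]
    gt_sub <- genotypes[genotypes$sample_id %in%
                          c(trio$proband_id, trio$father_id,
                            trio$mother_id), , drop = FALSE]
    var_sub <- variants[variants$variant_id %in% gt_sub$variant_id, ,
                        drop = FALSE]
    classify_trio_variants(var_sub, gt_sub, trio, gates = gates,
                           mosaic_vaf = mosaic_vaf)
  })
  calls <- do.call(rbind, calls)

  # Stage 3: filter cascade over the proband carrier table.
  carriers <- build_carrier_table(calls, variants, genotypes)
  cascade <- run_filter_cascade(carriers, panels,
                                maf_threshold = maf_threshold,
                                gates = gates)
  filtered <- cascade$variants

  # Stage 4: burden summaries.
  burden <- per_proband_counts(filtered, ped_ok$proband_id, panels)
  categories <- proband_panel_category(filtered, ped_ok$proband_id)
  type_props <- if (nrow(filtered) > 0L) {
    summarize_variant_types(filtered)
  } else NULL

  denovo <- denovo_calls(calls, variants, maf_threshold)
  dn_counts <- count_per_proband(denovo, ped_ok$proband_id)
  outliers <- suppressWarnings(flag_outlier_probands(dn_counts))
  lowvaf <- low_vaf_fraction(calls, cutoff = mosaic_vaf[2])
  comphets <- find_compound_hets(
    calls[calls$variant_id %in% filtered$variant_id, , drop = FALSE],
    variants
  )

  report <- list(
    thresholds = list(maf_threshold = maf_threshold, gates = gates,
                      mosaic_vaf = mosaic_vaf,
                      kinship_range = kinship_range,
                      expression_mode = expression_mode),
    kinship = kin_log, excluded_families = excluded_families,
    n_trios = nrow(ped_ok), calls = calls, attrition = cascade$attrition,
    filtered = filtered, burden = burden, categories = categories,
    category_counts = table(factor(categories,
                                   c("monogenic_carrier", "gwas_only",
                                     "none"))),
    variant_type_proportions = type_props,
    denovo = denovo, denovo_counts = dn_counts,
    n_probands_no_denovo = sum(dn_counts == 0L),
    outliers = outliers, low_vaf_fraction = lowvaf, comphets = comphets,
    kindred_table = kindred_table(calls, variants, filtered, ped_ok)
  )

  if (!is.null(controls)) {
    report$burden_test <- burden_chisq(burden$table$sle,
                                       controls$rare_counts)
    report$denovo_test <- denovo_rate_comparison(
      dn_counts, controls$denovo_counts, exclude = outliers$flagged
    )
    if (!is.null(controls$gene_carriers)) {
      eqtl_filtered <- filtered[filtered$in_eqtl, , drop = FALSE]
      case_car <- carrier_counts(eqtl_filtered)
      report$gene_carriers <- gene_carrier_comparison(
        case_car, controls$gene_carriers,
        n_case = nrow(ped_ok), n_control = controls$n_rare
      )
    }
  }

  if (!is.null(gmt) && !is.null(expr)) {
    report$prioritization <- prioritize_denovo_genes(
      denovo, filtered, variants, gmt, expr, panels,
      outlier_probands = outliers$flagged,
      expression_mode = expression_mode,
      background = ora_background
    )
  }
  class(report) <- "TrioReport"
  report
}

#' @exportS3Method base::print
print.TrioReport <- function(x, ...) {
  cat("TrioReport:", x$n_trios, "verified trios;",
      nrow(x$filtered), "qualifying rare carrier records;",
      sum(x$denovo_counts), "de novo calls\n")
  cat("  SLE-panel median per proband:", x$burden$medians[["sle"]],
      "| de novo median:", median(x$denovo_counts), "\n")
  invisible(x)
}

build_carrier_table <- function(calls, variants, genotypes) {
  idx <- match(calls$variant_id, variants$variant_id)
  gkey <- paste(genotypes$variant_id, genotypes$sample_id)
  gi <- match(paste(calls$variant_id, calls$proband_id), gkey)
  data.frame(
    proband_id = calls$proband_id, variant_id = calls$variant_id,
    origin = calls$origin, quality_pass = calls$quality_pass,
    gene = variants$gene[idx], consequence = variants$consequence[idx],
    af_global = variants$af_global[idx], af_eas = variants$af_eas[idx],
    polyphen = variants$polyphen[idx], sift = variants$sift[idx],
    cadd_phred = variants$cadd_phred[idx],
    dp = genotypes$dp[gi], gq = genotypes$gq[gi],
    ad_alt = genotypes$ad_alt[gi], vaf = genotypes$vaf[gi],
    stringsAsFactors = FALSE
  )
}

# Rare coding de novo calls: classifier-issued de novo origin plus the
# rarity and consequence-inclusion requirements.
denovo_calls <- function(calls, variants, maf_threshold = 0.005) {
  dn <- calls[startsWith(calls$origin, "de_novo"), , drop = FALSE]
  idx <- match(dn$variant_id, variants$variant_id)
  keep <- consequence_included(variants$consequence[idx]) &
    maf_filter(variants$af_global[idx], variants$af_eas[idx],
               maf_threshold)
  dn <- dn[keep, , drop = FALSE]
  dn$gene <- variants$gene[match(dn$variant_id, variants$variant_id)]
  dn
}

count_per_proband <- function(df, proband_ids) {
  out <- setNames(rep(0L, length(proband_ids)), proband_ids)
  if (nrow(df) > 0L) {
    cnt <- table(df$proband_id)
    out[names(cnt)] <- as.integer(cnt)
  }
  out
}

carrier_counts <- function(filtered) {
  if (nrow(filtered) == 0L) return(integer())
  pairs <- unique(filtered[, c("proband_id", "gene")])
  cnt <- table(pairs$gene)
  setNames(as.integer(cnt), names(cnt))
}

#' Proportions of qualifying variants by consequence type
#'
#' Fractions over the four included classes (indels pooled), summing
#' to 1.
#'
#' @param filtered cascade-surviving variant table with a `consequence`
#'   column.
#' @return named numeric vector over `missense`, `nonsense`, `indel`,
#'   `splice_canonical`.
#' @export
summarize_variant_types <- function(filtered) {
  if (nrow(filtered) == 0L) stop_("no variants to summarize")
  cls <- filtered$consequence
  cls[cls %in% c("frameshift_indel", "inframe_indel")] <- "indel"
  cls <- factor(cls, levels = c("missense", "nonsense", "indel",
                                "splice_canonical"))
  if (anyNA(cls)) stop_("non-included consequence class in filtered set")
  prop <- table(cls) / length(cls)
  setNames(as.numeric(prop), names(prop))
}

# Per-kindred inheritance landscape: paternal / maternal / de novo gene
# lists per family, over cascade-surviving variants.
kindred_table <- function(calls, variants, filtered, ped) {
  keep <- calls[calls$variant_id %in% filtered$variant_id, , drop = FALSE]
  keep$gene <- variants$gene[match(keep$variant_id, variants$variant_id)]
  genes_of <- function(fid, origins) {
    g <- keep$gene[keep$family_id == fid & keep$origin %in% origins]
    paste(sort(unique(g)), collapse = ",")
  }
  data.frame(
    family_id = ped$family_id,
    paternal = vapply(ped$family_id, genes_of, "",
                      origins = "paternal"),
    maternal = vapply(ped$family_id, genes_of, "",
                      origins = "maternal"),
    de_novo = vapply(ped$family_id, genes_of, "",
                     origins = c("de_novo_germline",
                                 "de_novo_mosaic_suspect")),
    stringsAsFactors = FALSE
  )
}

prioritize_denovo_genes <- function(denovo, filtered, variants, gmt, expr,
                                    panels, outlier_probands = character(),
                                    expression_mode = "argmax",
                                    background = NULL) {
  dn_core <- denovo[!denovo$proband_id %in% outlier_probands, ,
                    drop = FALSE]
  dn_genes <- unique(dn_core$gene)
  query <- unique(c(dn_genes, filtered$gene[filtered$in_monogenic |
                                              filtered$in_gwas]))
  if (is.null(background)) {
    background <- unique(normalize_symbols(variants$gene))
  }
  background <- unique(c(normalize_symbols(background), query))
  enrichment <- ora(query, gmt, background)
  top <- select_top_pathways(enrichment)
  top_sets <- lapply(setNames(top$term, top$term), function(t) gmt[[t]])
  pathway_genes <- dn_genes[vapply(dn_genes, function(g) {
    any(vapply(top_sets, function(s) g %in% normalize_symbols(s),
               logical(1)))
  }, logical(1))]
  expr_flag <- expression_criterion(dn_genes, expr, mode = expression_mode)
  candidates <- intersect_candidates(
    dn_genes, pathway_genes, names(expr_flag)[expr_flag], panels,
    top_sets = top_sets
  )
  list(enrichment = enrichment, top_pathways = top,
       expression_positive = expr_flag, venn = candidates$venn,
       candidates = candidates$candidates)
}

#' Write a report to disk
#'
#' JSON for the scalar/statistical content plus TSVs for the main
#' tables (filtered carriers, inheritance calls, burden table, kindred
#' landscape, attrition log, candidates when present).
#'
#' @param report a `TrioReport`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  tsv(report$filtered, "filtered_variants.tsv")
  tsv(report$calls, "inheritance_calls.tsv")
  tsv(report$burden$table, "burden_table.tsv")
  tsv(report$kindred_table, "kindred_landscape.tsv")
  tsv(report$attrition, "attrition.tsv")
  if (!is.null(report$prioritization)) {
    tsv(report$prioritization$candidates, "candidates.tsv")
    tsv(report$prioritization$enrichment, "enrichment.tsv")
  }
  scalars <- list(
    thresholds = report$thresholds,
    n_trios = report$n_trios,
    excluded_families = report$excluded_families,
    category_counts = as.list(report$category_counts),
    medians = as.list(report$burden$medians),
    variant_type_proportions = as.list(report$variant_type_proportions),
    denovo_counts = as.list(report$denovo_counts),
    n_probands_no_denovo = report$n_probands_no_denovo,
    outliers = report$outliers,
    burden_test = if (!is.null(report$burden_test)) {
      list(statistic = report$burden_test$statistic,
           p_value = report$burden_test$p_value)
    },
    denovo_test = if (!is.null(report$denovo_test)) {
      report$denovo_test[c("mean_case", "mean_control", "rate_ratio",
                           "p_value", "excluded")]
    },
    venn = if (!is.null(report$prioritization)) {
      as.list(report$prioritization$venn)
    }
  )
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Score de novo recovery against simulation truth
#'
#' Recovery definitions: *germline sensitivity* is the fraction of
#' implanted germline (VAF 0.5) de novo variants called
#' `de_novo_germline`; *false calls* are classifier de novo calls on
#' variants the truth table does not record as de novo; *mosaic band
#' assignment* is evaluated over mosaic implants whose observed reads
#' pass the de novo gates and whose observed VAF reaches the mosaic
#' floor (classification is necessarily a function of observed, not
#' latent, allele fractions) — each such implant must be called
#' `de_novo_mosaic_suspect`.
#'
#' @param calls inheritance calls from the pipeline.
#' @param truth truth table from [simulate_cohort()].
#' @param genotypes long genotype table (for gate evaluation on mosaic
#'   implants).
#' @param gates the gates used in classification.
#' @param mosaic_floor lower VAF bound of the mosaic band; default 0.10.
#' @return list of counts and rates.
#' @export
evaluate_denovo_recovery <- function(calls, truth, genotypes,
                                     gates = default_gates(),
                                     mosaic_floor = 0.10) {
  dn_truth <- truth[truth$class == "de_novo", , drop = FALSE]
  key <- function(v, p) paste(v, p)
  call_key <- key(calls$variant_id, calls$proband_id)
  truth_key <- key(dn_truth$variant_id, dn_truth$proband_id)

  germ <- dn_truth[!dn_truth$mosaic, , drop = FALSE]
  gi <- match(key(germ$variant_id, germ$proband_id), call_key)
  germ_recovered <- !is.na(gi) & calls$origin[gi] == "de_novo_germline"

  dn_calls <- calls[startsWith(calls$origin, "de_novo"), , drop = FALSE]
  false_calls <- sum(!key(dn_calls$variant_id, dn_calls$proband_id) %in%
                       truth_key)

  mos <- dn_truth[dn_truth$mosaic, , drop = FALSE]
  gkey <- paste(genotypes$variant_id, genotypes$sample_id)
  mi <- match(key(mos$variant_id, mos$proband_id), gkey)
  gate_pass <- !is.na(mi) &
    genotypes$dp[mi] >= gates$min_dp &
    genotypes$gq[mi] >= gates$min_gq &
    genotypes$ad_alt[mi] >= gates$min_alt_reads &
    !is.na(genotypes$vaf[mi]) & genotypes$vaf[mi] >= mosaic_floor
  mos_gp <- mos[gate_pass, , drop = FALSE]
  ci <- match(key(mos_gp$variant_id, mos_gp$proband_id), call_key)
  mos_correct <- !is.na(ci) & calls$origin[ci] == "de_novo_mosaic_suspect"

  list(
    n_germline = nrow(germ),
    n_germline_recovered = sum(germ_recovered),
    sensitivity_germline = if (nrow(germ) > 0) mean(germ_recovered) else NA,
    n_false_calls = false_calls,
    n_mosaic = nrow(mos),
    n_mosaic_gate_pass = nrow(mos_gp),
    n_mosaic_correct = sum(mos_correct),
    mosaic_assignment_rate = if (nrow(mos_gp) > 0) mean(mos_correct) else NA
  )
}
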