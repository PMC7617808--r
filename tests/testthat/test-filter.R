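test_that("splice classification honours the canonical +/-2 window", {
  expect_equal(classify_consequence("splice_region", splice_offset = 2),
               "splice_canonical")
  expect_equal(classify_consequence("splice_region", splice_offset = -1),
               "splice_canonical")
  expect_equal(classify_consequence("splice_region", splice_offset = 3),
               "other")
  expect_equal(classify_consequence("splice_donor_variant"), "splice_canonical")
  expect_true(consequence_included("splice_canonical"))
  expect_false(consequence_included(classify_consequence("synonymous")))
  expect_warning(out <- classify_consequence("upstream_gene_variant"),
                 "unknown")
  expect_equal(out, "other")
})

test_that("the MAF filter excludes strictly above threshold in either population", {
  # The C4A example frequencies: rare in one reference release, common in
  # the other.
  expect_true(maf_filter(NA, 0.002091))
  expect_false(maf_filter(NA, 0.03653))
  expect_false(maf_filter(0.03653, 0.002091))
  # Novel variants (both frequencies absent) are rare by definition.
  expect_true(maf_filter(NA_real_, NA_real_))
  # Boundary: exactly at threshold passes (strictly-greater exclusion).
  expect_true(maf_filter(0.005, 0.005))
  expect_false(maf_filter(0.0050001, 0.001))
})

test_that("the damage consensus needs two damaging votes of the available tools", {
  expect_equal(damage_consensus("probably_damaging", "deleterious", 25),
               "likely_damaging")
  expect_equal(damage_consensus("benign", "tolerated", 3), "not_damaging")
  # 2-of-3 with a dissenting tool.
  expect_equal(damage_consensus("benign", "deleterious", 24),
               "likely_damaging")
  expect_equal(damage_consensus(NA, "deleterious", NA), "indeterminate")
  expect_equal(damage_consensus(NA, "deleterious", 25), "likely_damaging")
  # Vectorized over variants.
  expect_equal(
    damage_consensus(c("benign", "possibly_damaging"),
                     c("deleterious", "deleterious"), c(3, 19.9)),
    c("not_damaging", "likely_damaging")
  )
})

test_that("panel tagging is non-exclusive and exact after normalization", {
  panels <- make_default_panels()
  v <- data.frame(gene = c("C4A", "tyk2", "NOTAGENE"),
                  stringsAsFactors = FALSE)
  tagged <- panel_intersect(v, panels)
  expect_true(tagged$in_monogenic[1])
  expect_true(tagged$in_eqtl[1])  # C4A sits in several panels
  expect_true(tagged$in_gwas[2])
  expect_equal(tagged$panel_tag[3], "none")
})

toy_carriers <- function() {
  # 10 variants: 3 common, 2 synonymous-rare, 5 rare coding - 5 survive.
  data.frame(
    proband_id = "P1",
    variant_id = paste0("v", 1:10),
    gene = c("C4A", "TYK2", "BLK", "STAT4", "IRF5",
             "ACP5", "TREX1", "BANK1", "ETS1", "LYN"),
    consequence = c(rep("missense", 3), rep("synonymous", 2),
                    rep("missense", 4), "nonsense"),
    af_global = c(0.02, 0.1, 0.3, 0.001, 0.002,
                  0.001, NA, 0.004, 0.0001, NA),
    af_eas = c(0.02, 0.1, 0.3, 0.001, 0.002,
               0.001, NA, 0.004, 0.0001, NA),
    dp = 40, gq = 99, ad_alt = 20, vaf = 0.5,
    stringsAsFactors = FALSE
  )
}

test_that("the cascade reproduces hand-enumerated attrition on a toy table", {
  res <- run_filter_cascade(toy_carriers(), make_default_panels())
  expect_equal(nrow(res$variants), 5L)
  expect_setequal(res$variants$variant_id, paste0("v", 6:10))
  expect_equal(res$attrition$stage,
               c("decompose", "consequence", "maf", "qc", "panel"))
  expect_equal(res$attrition$n_in, c(10L, 10L, 8L, 5L, 5L))
  expect_equal(res$attrition$n_out, c(10L, 8L, 5L, 5L, 5L))
})

test_that("a unit MAF threshold removes nothing at the MAF stage", {
  res <- run_filter_cascade(toy_carriers(), make_default_panels(),
                            maf_threshold = 1.0)
  att <- res$attrition
  expect_equal(att$n_in[att$stage == "maf"], att$n_out[att$stage == "maf"])
})

random_carriers <- function(n, seed) {
  set.seed(seed)
  panels <- make_default_panels()
  data.frame(
    proband_id = sample(paste0("P", 1:5), n, TRUE),
    variant_id = paste0("v", seq_len(n)),
    gene = sample(c(panel_union(panels), paste0("GENE", 1:50)), n, TRUE),
    consequence = sample(c("missense", "nonsense", "synonymous", "other",
                           "splice_canonical"), n, TRUE),
    af_global = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.05)),
    af_eas = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.05)),
    dp = rpois(n, 40), gq = sample(c(99, 30, 10), n, TRUE),
    ad_alt = rpois(n, 12), vaf = runif(n),
    stringsAsFactors = FALSE
  )
}

test_that("filter laws: MAF monotonicity, idempotence, stage commutativity", {
  panels <- make_default_panels()
  for (seed in c(501, 502, 503)) {
    carriers <- random_carriers(300, seed)
    # Monotonicity: lowering the threshold never enlarges the output.
    prev <- NULL
    for (thr in c(0.05, 0.01, 0.005, 0.001, 0)) {
      out <- run_filter_cascade(carriers, panels, maf_threshold = thr)
      ids <- out$variants$variant_id
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
    # Idempotence: running the cascade on its own output changes nothing.
    once <- run_filter_cascade(carriers, panels)
    twice <- run_filter_cascade(once$variants, panels)
    expect_setequal(twice$variants$variant_id, once$variants$variant_id)
    # Commutativity: MAF and consequence stages are order-exchangeable.
    ab <- run_filter_cascade(carriers, panels,
                             stages = c("consequence", "maf", "qc", "panel"))
    ba <- run_filter_cascade(carriers, panels,
                             stages = c("maf", "consequence", "qc", "panel"))
    expect_setequal(ab$variants$variant_id, ba$variants$variant_id)
  }
})

test_that("the cohort-AC reading of the minor-allele-count filter is available", {
  carriers <- toy_carriers()
  # With a single carrier per variant, cohort alternate-allele count is 1
  # (< 5): the cohort reading empties the table.
  expect_warning(
    res <- run_filter_cascade(carriers, make_default_panels(),
                              mac_mode = "cohort"),
    "empty"
  )
  expect_equal(nrow(res$variants), 0L)
})

test_that("probands are categorized by panel membership of their variants", {
  panels <- make_default_panels()
  filtered <- panel_intersect(data.frame(
    proband_id = c("P1", "P1", "P2", "P3"),
    variant_id = paste0("v", 1:4),
    gene = c("ACP5", "TYK2", "STAT4", "UNKNOWN1"),
    stringsAsFactors = FALSE
  ), panels)
  cats <- proband_panel_category(filtered, c("P1", "P2", "P3", "P4"))
  expect_equal(unname(cats[c("P1", "P2", "P3", "P4")]),
               c("monogenic_carrier", "gwas_only", "none", "none"))
})
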