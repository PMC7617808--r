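test_that("a textbook Mendelian violation is called de novo germline", {
  call <- classify_inheritance(geno_row("0/1", 10, 10),
                               geno_row("0/0", 20, 0),
                               geno_row("0/0", 22, 0))
  expect_equal(call$origin, "de_novo_germline")
  expect_true(call$quality_pass)
})

test_that("insufficient alternate-read support demotes a violation to unresolved", {
  call <- classify_inheritance(geno_row("0/1", 17, 3),
                               geno_row("0/0", 30, 0),
                               geno_row("0/0", 28, 0))
  expect_equal(call$origin, "unresolved")
  expect_false(call$quality_pass)
})

test_that("low-VAF violations are flagged as mosaic suspects", {
  call <- classify_inheritance(geno_row("0/1", 30, 6),
                               geno_row("0/0", 25, 0),
                               geno_row("0/0", 25, 0))
  expect_equal(call$origin, "de_novo_mosaic_suspect")
  expect_true(call$quality_pass)
  # VAF below the mosaic floor: not a believable call at all.
  low <- classify_inheritance(geno_row("0/1", 57, 5),
                              geno_row("0/0", 25, 0),
                              geno_row("0/0", 25, 0))
  expect_equal(low$origin, "unresolved")
})

test_that("parental carriage assigns origin sides and ambiguity correctly", {
  pat <- classify_inheritance(geno_row("0/1", 10, 10),
                              geno_row("0/1", 11, 9),
                              geno_row("0/0", 20, 0))
  expect_equal(pat$origin, "paternal")
  mat <- classify_inheritance(geno_row("0/1", 10, 10),
                              geno_row("0/0", 20, 0),
                              geno_row("1/1", 0, 20))
  expect_equal(mat$origin, "maternal")
  bip <- classify_inheritance(geno_row("0/1", 10, 10),
                              geno_row("0/1", 11, 9),
                              geno_row("0/1", 9, 11))
  expect_equal(bip$origin, "biparental_ambiguous")
  hom <- classify_inheritance(geno_row("1/1", 0, 20),
                              geno_row("0/1", 11, 9),
                              geno_row("0/1", 9, 11))
  expect_equal(hom$origin, "homozygous_recessive")
})

test_that("missing or contaminated parental genotypes never yield de novo", {
  miss <- classify_inheritance(geno_row("0/1", 10, 10),
                               geno_row(NA, 0, 0, dp = 0, gq = 0),
                               geno_row("0/0", 20, 0))
  expect_equal(miss$origin, "unresolved")
  # Parent with 2 alt reads exceeds the contamination tolerance.
  cont <- classify_inheritance(geno_row("0/1", 10, 10),
                               geno_row("0/0", 18, 2),
                               geno_row("0/0", 20, 0))
  expect_equal(cont$origin, "unresolved")
  # One stray parental read is tolerated.
  ok <- classify_inheritance(geno_row("0/1", 10, 10),
                             geno_row("0/0", 19, 1),
                             geno_row("0/0", 20, 0))
  expect_equal(ok$origin, "de_novo_germline")
})

test_that("male X calls compare against the mother only", {
  mat <- classify_inheritance(geno_row("1/1", 0, 30),
                              geno_row("0/0", 20, 0),
                              geno_row("0/1", 10, 10),
                              chrom = "X", proband_sex = "male")
  expect_equal(mat$origin, "maternal")
  expect_match(mat$notes, "hemizygous")
  # Mother hom-ref, father irrelevant: de novo on the X.
  dn <- classify_inheritance(geno_row("1/1", 0, 30),
                             geno_row("0/1", 10, 10),
                             geno_row("0/0", 20, 0),
                             chrom = "X", proband_sex = "male")
  expect_equal(dn$origin, "de_novo_germline")
})

test_that("compound-het pairing requires trans configuration", {
  variants <- data.frame(
    variant_id = paste0("v", 1:5), chrom = "19",
    gene = c("ACP5", "ACP5", "ACP5", "ACP5", "TYK2"),
    stringsAsFactors = FALSE
  )
  mk_calls <- function(origins, ids = paste0("v", seq_along(origins))) {
    data.frame(variant_id = ids, family_id = "FAM1", proband_id = "P1",
               origin = origins, quality_pass = TRUE, vaf = 0.5,
               notes = "", stringsAsFactors = FALSE)
  }
  one <- find_compound_hets(mk_calls(c("paternal", "maternal")), variants)
  expect_equal(nrow(one), 1L)
  expect_equal(one$gene, "ACP5")

  cis <- find_compound_hets(mk_calls(c("paternal", "paternal")), variants)
  expect_equal(nrow(cis), 0L)

  # 2 paternal x 1 maternal: enumeration gives 2 pairs.
  two <- find_compound_hets(
    mk_calls(c("paternal", "paternal", "maternal"), c("v1", "v2", "v3")),
    variants
  )
  expect_equal(nrow(two), 2L)
  expect_setequal(two$paternal_variant, c("v1", "v2"))

  # Ambiguous-phase variants never pair.
  amb <- find_compound_hets(
    mk_calls(c("paternal", "biparental_ambiguous")), variants
  )
  expect_equal(nrow(amb), 0L)
})

test_that("outlier flagging isolates implausible de novo burdens", {
  counts <- setNames(c(rep(0L, 12), rep(1L, 20), rep(2L, 12), rep(3L, 4),
                       34L, 33L), paste0("P", 1:50))
  fl <- flag_outlier_probands(counts)
  expect_setequal(fl$flagged, c("P49", "P50"))
  same <- setNames(rep(2L, 10), paste0("P", 1:10))
  expect_equal(flag_outlier_probands(same)$flagged, character())
  expect_warning(flag_outlier_probands(setNames(1:3, paste0("P", 1:3))),
                 "fewer than 5")
})

test_that("classification is deterministic and order-independent", {
  sim <- small_sim()
  trio <- sim$pedigree[1L, ]
  gt_sub <- sim$genotypes[sim$genotypes$sample_id %in%
                            c(trio$proband_id, trio$father_id,
                              trio$mother_id), ]
  vars <- sim$variants[sim$variants$variant_id %in% gt_sub$variant_id, ]
  a <- classify_trio_variants(vars, gt_sub, trio)
  set.seed(42)
  perm <- sample(nrow(vars))
  b <- classify_trio_variants(vars[perm, ], gt_sub, trio)
  b <- b[match(a$variant_id, b$variant_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("per-origin counts partition the proband's alt-carrying variants", {
  sim <- small_sim()
  for (k in 1:3) {
    trio <- sim$pedigree[k, ]
    gt_sub <- sim$genotypes[sim$genotypes$sample_id %in%
                              c(trio$proband_id, trio$father_id,
                                trio$mother_id), ]
    vars <- sim$variants[sim$variants$variant_id %in% gt_sub$variant_id, ]
    calls <- classify_trio_variants(vars, gt_sub, trio)
    pro <- gt_sub[gt_sub$sample_id == trio$proband_id, ]
    n_alt <- sum(gt_alt_count(pro$gt) > 0, na.rm = TRUE)
    expect_equal(nrow(calls), n_alt)
    expect_true(all(calls$origin %in% c(
      "paternal", "maternal", "biparental_ambiguous", "de_novo_germline",
      "de_novo_mosaic_suspect", "homozygous_recessive", "unresolved"
    )))
  }
})
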