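test_that("per-proband counts use distinct variants and midpoint medians", {
  panels <- make_default_panels()
  filtered <- panel_intersect(data.frame(
    proband_id = c("P1", "P2", "P2", "P3", "P3", "P3",
                   rep("P4", 11)),
    # P4 carries 10 distinct variants; the 11th row is a duplicate
    # record that must not double-count.
    variant_id = c(paste0("v", 1:16), "v16"),
    gene = "TYK2",
    stringsAsFactors = FALSE
  ), panels)
  pc <- per_proband_counts(filtered, paste0("P", 1:4), panels)
  expect_equal(pc$table$gwas, c(1L, 2L, 3L, 10L))
  # Even n: midpoint of the central pair.
  expect_equal(pc$medians[["gwas"]], 2.5)
  pc3 <- per_proband_counts(filtered[filtered$proband_id != "P4", ],
                            paste0("P", 1:3), panels)
  expect_equal(pc3$medians[["gwas"]], 2)
})

test_that("burden table column sums are conserved under input reordering", {
  sim <- small_sim()
  rep <- small_report()
  filtered <- rep$filtered
  panels <- sim$panels
  a <- per_proband_counts(filtered, sim$pedigree$proband_id, panels)
  set.seed(7)
  b <- per_proband_counts(filtered[sample(nrow(filtered)), ],
                          sim$pedigree$proband_id, panels)
  expect_equal(colSums(a$table[, -1]), colSums(b$table[, -1]))
  expect_equal(sum(a$table$all), nrow(filtered))
})

test_that("the carrier-mode chi-square matches the hand-computed fixture", {
  # Observed [[10,90],[30,70]]; expected margins 20/80 per row; the
  # Pearson statistic is 100/20 + 100/80 + 100/20 + 100/80 = 12.5.
  case <- c(rep(0L, 10), rep(1L, 90))
  ctrl <- c(rep(0L, 30), rep(1L, 70))
  res <- burden_chisq(case, ctrl, mode = "carrier")
  expect_equal(res$statistic, 12.5)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(12.5, 1, lower.tail = FALSE))
})

test_that("identical distributions give a zero statistic and p = 1", {
  x <- c(0L, 1L, 1L, 2L, 3L, 5L, 7L)
  res <- burden_chisq(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("degenerate single-bin tables are an error", {
  expect_error(burden_chisq(rep(0L, 50), rep(0L, 105)), "degenerate")
})

test_that("the binned chi-square detects a case burden shift", {
  # Poisson(6) cases vs Poisson(3) controls at the study sizes: the
  # Monte-Carlo oracle says rejection should be near-certain.
  set.seed(601)
  rejected <- replicate(200, {
    p <- suppressWarnings(
      burden_chisq(rpois(50, 6), rpois(105, 3))$p_value
    )
    p < 0.05
  })
  expect_gte(mean(rejected), 0.95)
})

test_that("carrier comparison computes ratios and division conventions", {
  res <- gene_carrier_comparison(c(TYK2 = 5L), c(TYK2 = 2L),
                                 n_case = 50, n_control = 105)
  expect_equal(res$ratio, (5 / 50) / (2 / 105))
  expect_equal(res$ratio, 5.25)
  expect_true(res$selected)

  eq <- gene_carrier_comparison(c(BLK = 5L), c(BLK = 5L),
                                n_case = 50, n_control = 50)
  expect_false(eq$selected)

  inf <- gene_carrier_comparison(c(C4A = 1L), integer(),
                                 n_case = 50, n_control = 105)
  expect_true(is.infinite(inf$ratio))
  expect_true(inf$selected)
})

test_that("carrier ratios are invariant under duplicating every sample", {
  a <- gene_carrier_comparison(c(TYK2 = 5L, BLK = 3L),
                               c(TYK2 = 2L, BLK = 4L), 50, 105)
  b <- gene_carrier_comparison(c(TYK2 = 10L, BLK = 6L),
                               c(TYK2 = 4L, BLK = 8L), 100, 210)
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$selected, b$selected)
})

test_that("de novo rate comparison: null case and simulated enrichment", {
  x <- setNames(c(0L, 1L, 1L, 2L, 0L, 1L), paste0("P", 1:6))
  null <- denovo_rate_comparison(x, unname(x), exclude = character())
  expect_equal(null$rate_ratio, 1)
  expect_equal(null$p_value, 1)

  # Simulation oracle: Poisson(1.2) cases (n=48) vs Poisson(0.8)
  # controls (n=2049) gives a rate ratio of 1.5; the Monte-Carlo mean
  # over replicates concentrates inside 1.5 +/- 0.2.
  set.seed(602)
  ratios <- replicate(100, {
    case <- setNames(rpois(48, 1.2), paste0("P", 1:48))
    ctrl <- rpois(2049, 0.8)
    denovo_rate_comparison(case, ctrl, exclude = character())$rate_ratio
  })
  expect_gt(mean(ratios), 1.3)
  expect_lt(mean(ratios), 1.7)
})

test_that("excluding the largest cases shrinks but can keep the enrichment", {
  set.seed(603)
  case <- setNames(c(rpois(48, 1.2), 34L, 33L), paste0("P", 1:50))
  ctrl <- rpois(2049, 0.8)
  res <- denovo_rate_comparison(case, ctrl)
  expect_setequal(res$excluded, c("P49", "P50"))
  expect_lt(res$sensitivity$rate_ratio, res$rate_ratio)
  expect_gt(res$sensitivity$rate_ratio, 1)
})

test_that("2^-ddCt fold changes follow the defining arithmetic", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(24, 20, 25, 20), 2)
  expect_equal(ddct_fold_change(25, 20, 26, 20), 2)
  expect_equal(ddct_fold_change(26, 20, 24, 20), 0.25)
})

test_that("binned chi-square type-I error is near nominal under the null", {
  set.seed(604)
  rej <- replicate(400, {
    p <- suppressWarnings(burden_chisq(rpois(50, 2), rpois(105, 2))$p_value)
    p < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})
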