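test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 21, n_trios = 3, n_background_sites = 250)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # Written outputs are byte-identical too.
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("per-family streams leave existing families untouched when growing", {
  a <- simulate_cohort(sim_config(seed = 22, n_trios = 3,
                                  n_background_sites = 250,
                                  n_outlier_probands = 0L))
  b <- simulate_cohort(sim_config(seed = 22, n_trios = 5,
                                  n_background_sites = 250,
                                  n_outlier_probands = 0L))
  fam1 <- function(s) s$genotypes[s$genotypes$sample_id %in%
                                    c("F01_P", "F01_F", "F01_M"), ]
  expect_identical(fam1(a), fam1(b))
})

test_that("gene-dropped children are Mendelian-consistent at backbone sites", {
  sim <- small_sim()
  for (k in 1:4) {
    trio <- sim$pedigree[k, ]
    dose <- genotype_dosage(sim$genotypes,
                            c(trio$proband_id, trio$father_id,
                              trio$mother_id),
                            variant_ids = sim$backbone_ids)
    child <- dose[, 1]; fat <- dose[, 2]; mot <- dose[, 3]
    # A child allele must be transmissible: no alt without a carrier
    # parent, no hom-alt unless both carry, and mirror rules for ref.
    expect_true(all(child <= (fat > 0) + (mot > 0)))
    expect_true(all(child >= (fat == 2) + (mot == 2)))
  }
})

test_that("zero de novo rate plus noiseless reads yields zero violations", {
  cfg <- sim_config(seed = 23, n_trios = 4, n_background_sites = 300,
                    de_novo_rate = 0, n_outlier_probands = 0L,
                    read_model = "expected")
  sim <- simulate_cohort(cfg)
  rep <- run_trio_pipeline(sim)
  expect_equal(sum(startsWith(rep$calls$origin, "de_novo")), 0L)
})

test_that("count-level replicates recover the configured medians", {
  cfg <- sim_config(seed = 24)
  set.seed(24)
  rare <- sample_rare_counts(500, cfg)
  expect_lte(abs(median(rare) - 6), 1)
  dn <- sample_denovo_counts(500, cfg)
  expect_equal(median(dn), 1)
})

test_that("the backbone allele-frequency spectrum matches its target", {
  cfg <- sim_config(seed = 25, n_trios = 2, n_background_sites = 10000L)
  sim <- simulate_cohort(cfg)
  af <- sim$variants$af_global[startsWith(sim$variants$gene, "BG")]
  ks <- suppressWarnings(
    stats::ks.test(af, stats::punif, 0.05, 0.5)$statistic
  )
  expect_lt(unname(ks), 0.05)
})

test_that("control cohorts have the configured sizes and rates", {
  cfg <- sim_config(seed = 26)
  ctrl <- simulate_controls(cfg, make_default_panels())
  expect_length(ctrl$rare_counts, 105L)
  expect_length(ctrl$denovo_counts, 2049L)
  # Law of large numbers: mean de novo count near 0.79 at n = 2049.
  expect_lt(abs(mean(ctrl$denovo_counts) - 0.79), 0.06)
  expect_equal(length(ctrl$gene_carriers), 64L)

  zero <- sim_config(seed = 26, control_rare_rate = 0,
                     control_denovo_rate = 0)
  zc <- simulate_controls(zero)
  expect_true(all(zc$rare_counts == 0))
  expect_true(all(zc$denovo_counts == 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(seed = 27, de_novo_rate = -1), "non-negative")
  expect_error(sim_config(seed = 27, n_trios = 3, n_outlier_probands = 5),
               "outlier")
  expect_error(sim_config(), "seed")
})

test_that("truth bookkeeping covers every implant with disjoint labels", {
  sim <- small_sim()
  expect_false(anyDuplicated(sim$truth$variant_id) > 0)
  expect_true(all(sim$truth$class %in%
                    c("inherited", "de_novo", "decoy_common",
                      "decoy_synonymous")))
  # Implanted variants all appear in the annotation and the proband's
  # genotypes.
  expect_true(all(sim$truth$variant_id %in% sim$variants$variant_id))
  gkey <- paste(sim$genotypes$variant_id, sim$genotypes$sample_id)
  expect_true(all(paste(sim$truth$variant_id, sim$truth$proband_id) %in%
                    gkey))
  # Mosaic truth VAFs sit inside the configured band.
  mos <- sim$truth[sim$truth$mosaic, ]
  expect_true(all(mos$true_vaf >= 0.10 & mos$true_vaf <= 0.26))
})

test_that("a written cohort reads back equivalent for the pipeline", {
  sim <- small_sim()
  dir <- file.path(tempdir(), "roundtrip_sim")
  write_cohort(sim, dir)
  back <- read_cohort_dir(dir)
  expect_equal(nrow(back$pedigree), nrow(sim$pedigree))
  expect_setequal(back$variants$variant_id, sim$variants$variant_id)
  expect_setequal(back$backbone_ids, sim$backbone_ids)
  expect_equal(nrow(back$genotypes), nrow(sim$genotypes))
  unlink(dir, recursive = TRUE)
})
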