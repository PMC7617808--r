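# Shared fixtures built in code. The expensive cohort simulations are
# memoised so several test files can reuse them within one run.

geno_row <- function(gt, ad_ref, ad_alt, dp = ad_ref + ad_alt, gq = 99) {
  denom <- ad_ref + ad_alt
  list(gt = gt, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, gq = gq,
       vaf = if (denom > 0) ad_alt / denom else NA_real_)
}

write_mini_vcf <- function(body_rows, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body_rows), path)
  path
}

mini_trio <- function() {
  data.frame(family_id = "FAM1", proband_id = "P1", father_id = "D1",
             mother_id = "M1", proband_sex = "female", affected = TRUE,
             stringsAsFactors = FALSE)
}

# A small cohort exercising every stage, shared across test files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_trios = 8, n_background_sites = 400)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

small_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      ctrl <- simulate_controls(sim$config, sim$panels)
      cache <<- run_trio_pipeline(sim, controls = ctrl)
    }
    cache
  }
})

# The study-scale cohort in the noiseless (expected-read) limit, used by
# the recovery and median checks.
study_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 2026, read_model = "expected")
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

study_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- study_sim()
      ctrl <- simulate_controls(sim$config, sim$panels)
      cache <<- run_trio_pipeline(sim, controls = ctrl)
    }
    cache
  }
})
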