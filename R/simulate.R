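# Synthetic trio-cohort generator. Emulates the study design the
# analysis assumes: 50 case trios with Hardy-Weinberg parental genotypes
# at a common-variant backbone (used for relatedness verification),
# Mendelian gene-dropping to offspring, implanted rare variants in the
# SLE panels targeting a per-proband median of ~6, Poisson de novo
# implants (median 1) with a low-VAF mosaic subpopulation, two outlier
# probands carrying a large somatic-like mosaic excess, decoy variants
# that must fall out of the filter cascade, negative-binomial read
# depths with binomial allele sampling, and matched control cohorts
# without case enrichment. Every implant is recorded in a truth table.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed RNG seed (mandatory; all randomness flows from it, with
#'   one derived stream per family so cohorts are extensible).
#' @param n_trios number of case trios; default 50.
#' @param n_background_sites common biallelic backbone sites shared by
#'   the cohort; default 1500.
#' @param background_af allele-frequency band of the backbone spectrum;
#'   default `c(0.05, 0.5)`.
#' @param rare_rate_monogenic,rare_rate_gwas Poisson means of qualifying
#'   rare inherited variants per proband in each panel; defaults 1.0 and
#'   5.0 (total median 6).
#' @param decoy_common_rate,decoy_synonymous_rate Poisson means of
#'   implanted decoys per proband that must fail the MAF or consequence
#'   stage; defaults 2.0 and 1.0.
#' @param de_novo_rate Poisson mean of rare coding de novo variants per
#'   proband; default 1.2 (count median 1 with a realistic upper tail).
#' @param mosaic_fraction fraction of ordinary de novo implants drawn as
#'   post-zygotic mosaics; default 0.10.
#' @param mosaic_vaf VAF band for mosaic implants; default
#'   `c(0.10, 0.26)`.
#' @param n_outlier_probands probands carrying an extra somatic-like
#'   mosaic load; default 2 (the last families of the cohort).
#' @param outlier_extra_rate Poisson mean of the extra mosaic calls per
#'   outlier proband; default 30.
#' @param comphet_rate probability a proband carries an implanted
#'   compound-heterozygous pair in a monogenic gene; default 0.05.
#' @param depth_mean,depth_size negative-binomial read-depth model
#'   (mean and size/dispersion); defaults 40 and 20.
#' @param read_model `"binomial"`: alt reads ~ Binomial(dp, VAF);
#'   `"expected"`: deterministic `round(dp * VAF)` (the noiseless limit).
#' @param error_rate per-read error probability generating alternate
#'   reads on true hom-ref genotypes; default 0 (noiseless).
#' @param novel_af_fraction fraction of qualifying implants generated
#'   with absent population frequencies (novel variants); default 0.15.
#' @param damaging_fraction_panel,damaging_fraction_denovo fraction of
#'   panel / de novo implants drawn with damaging predictor profiles;
#'   defaults 0.42 and 0.216.
#' @param consequence_probs distribution over included consequence
#'   classes for qualifying implants.
#' @param control_rare_rate,n_controls_rare Poisson mean and size of the
#'   rare-variant control cohort; defaults 3.0 and 105.
#' @param control_denovo_rate,n_controls_denovo Poisson mean and size of
#'   the de novo control cohort; defaults 0.79 and 2049.
#' @return object of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_trios = 50L,
                       n_background_sites = 1500L,
                       background_af = c(0.05, 0.5),
                       rare_rate_monogenic = 1.0,
                       rare_rate_gwas = 5.0,
                       decoy_common_rate = 2.0,
                       decoy_synonymous_rate = 1.0,
                       de_novo_rate = 1.2,
                       mosaic_fraction = 0.10,
                       mosaic_vaf = c(0.10, 0.26),
                       n_outlier_probands = 2L,
                       outlier_extra_rate = 30,
                       comphet_rate = 0.05,
                       depth_mean = 40,
                       depth_size = 20,
                       read_model = c("binomial", "expected"),
                       error_rate = 0,
                       novel_af_fraction = 0.15,
                       damaging_fraction_panel = 0.42,
                       damaging_fraction_denovo = 0.216,
                       consequence_probs = c(missense = 0.92,
                                             nonsense = 0.03,
                                             frameshift_indel = 0.02,
                                             inframe_indel = 0.01,
                                             splice_canonical = 0.02),
                       control_rare_rate = 3.0,
                       n_controls_rare = 105L,
                       control_denovo_rate = 0.79,
                       n_controls_denovo = 2049L) {
  if (missing(seed) || is.null(seed)) stop_("a seed is mandatory")
  read_model <- match.arg(read_model)
  rates <- c(rare_rate_monogenic, rare_rate_gwas, decoy_common_rate,
             decoy_synonymous_rate, de_novo_rate, outlier_extra_rate,
             control_rare_rate, control_denovo_rate, error_rate)
  if (any(rates < 0)) stop_("all rates must be non-negative")
  if (mosaic_fraction < 0 || mosaic_fraction > 1) {
    stop_("mosaic_fraction must lie in [0, 1]")
  }
  if (n_outlier_probands > n_trios) {
    stop_("more outlier probands than trios")
  }
  stopifnot(length(mosaic_vaf) == 2L, mosaic_vaf[1] < mosaic_vaf[2])
  cfg <- list(
    seed = as.integer(seed), n_trios = as.integer(n_trios),
    n_background_sites = as.integer(n_background_sites),
    background_af = background_af,
    rare_rate_monogenic = rare_rate_monogenic,
    rare_rate_gwas = rare_rate_gwas,
    decoy_common_rate = decoy_common_rate,
    decoy_synonymous_rate = decoy_synonymous_rate,
    de_novo_rate = de_novo_rate, mosaic_fraction = mosaic_fraction,
    mosaic_vaf = mosaic_vaf,
    n_outlier_probands = as.integer(n_outlier_probands),
    outlier_extra_rate = outlier_extra_rate, comphet_rate = comphet_rate,
    depth_mean = depth_mean, depth_size = depth_size,
    read_model = read_model, error_rate = error_rate,
    novel_af_fraction = novel_af_fraction,
    damaging_fraction_panel = damaging_fraction_panel,
    damaging_fraction_denovo = damaging_fraction_denovo,
    consequence_probs = consequence_probs,
    control_rare_rate = control_rare_rate,
    n_controls_rare = as.integer(n_controls_rare),
    control_denovo_rate = control_denovo_rate,
    n_controls_denovo = as.integer(n_controls_denovo)
  )
  structure(cfg, class = "SimConfig")
}

# Per-proband count law shared by the cohort generator and the
# count-level replicate samplers.
draw_proband_counts <- function(cfg, outlier = FALSE) {
  list(
    n_mono = rpois(1L, cfg$rare_rate_monogenic),
    n_gwas = rpois(1L, cfg$rare_rate_gwas),
    comphet = runif(1L) < cfg$comphet_rate,
    n_denovo = rpois(1L, cfg$de_novo_rate),
    n_decoy_common = rpois(1L, cfg$decoy_common_rate),
    n_decoy_syn = rpois(1L, cfg$decoy_synonymous_rate),
    n_outlier = if (outlier) rpois(1L, cfg$outlier_extra_rate) else 0L
  )
}

#' Sample per-proband qualifying rare-variant counts
#'
#' Draws from the same count law the cohort generator uses for the SLE
#' panels (monogenic + GWAS qualifying implants, plus the
#' compound-heterozygote pair), without building genotypes. Used for
#' large count-level replicates.
#'
#' @param n number of probands.
#' @param cfg a `SimConfig`.
#' @return integer vector of counts.
#' @export
sample_rare_counts <- function(n, cfg) {
  rpois(n, cfg$rare_rate_monogenic) + rpois(n, cfg$rare_rate_gwas) +
    2L * (runif(n) < cfg$comphet_rate)
}

#' Sample per-proband de novo counts
#'
#' The ordinary (non-outlier) de novo count law of the generator.
#'
#' @inheritParams sample_rare_counts
#' @return integer vector of counts.
#' @export
sample_denovo_counts <- function(n, cfg) {
  rpois(n, cfg$de_novo_rate)
}

#' Simulate a trio cohort with known truth
#'
#' See the package vignette for the generative model. Deterministic given
#' the seed; family-level randomness uses one derived stream per family,
#' so growing `n_trios` leaves existing families untouched.
#'
#' @param cfg a `SimConfig`.
#' @param panels named list of `GenePanel`s; default
#'   [make_default_panels()].
#' @return object of class `TrioCohortSim`: list with `config`,
#'   `pedigree`, `variants` (annotation table), `genotypes` (long table),
#'   `truth`, `panels`, `backbone_ids`, `samples`.
#' @export
simulate_cohort <- function(cfg, panels = make_default_panels()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  backbone <- make_backbone_sites(cfg)
  denovo_pool <- sprintf("DNV%03d", 1:200)
  outlier_families <- if (cfg$n_outlier_probands > 0L) {
    seq(cfg$n_trios - cfg$n_outlier_probands + 1L, cfg$n_trios)
  } else integer()

  fam <- lapply(seq_len(cfg$n_trios), function(i) {
    simulate_family(i, cfg, backbone, panels, denovo_pool,
                    outlier = i %in% outlier_families)
  })

  pedigree <- do.call(rbind, lapply(fam, `[[`, "pedigree"))
  implants <- do.call(rbind, lapply(fam, `[[`, "implants"))
  genotypes <- do.call(rbind, lapply(fam, `[[`, "genotypes"))
  truth <- do.call(rbind, lapply(fam, `[[`, "truth"))
  rownames(pedigree) <- rownames(genotypes) <- rownames(truth) <- NULL
  variants <- rbind(backbone$annotation, implants)
  rownames(variants) <- NULL
  structure(list(
    config = cfg, pedigree = pedigree, variants = variants,
    genotypes = genotypes, truth = truth, panels = panels,
    backbone_ids = backbone$annotation$variant_id,
    samples = c(rbind(pedigree$proband_id, pedigree$father_id,
                      pedigree$mother_id))
  ), class = "TrioCohortSim")
}

#' @exportS3Method base::print
print.TrioCohortSim <- function(x, ...) {
  cat("TrioCohortSim:", nrow(x$pedigree), "trios,",
      nrow(x$variants), "variant records,",
      nrow(x$truth), "implants (seed", x$config$seed, ")\n")
  invisible(x)
}

make_backbone_sites <- function(cfg) {
  n <- cfg$n_background_sites
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  ann <- data.frame(
    chrom = sample(as.character(1:22), n, replace = TRUE),
    pos = sample.int(1e8, n),  # without replacement: keys unique
    ref = ref, alt = unname(alt),
    gene = sprintf("BG%04d", ceiling(seq_len(n) / 5)),
    consequence = sample(c("missense", "synonymous"), n, replace = TRUE),
    af_global = NA_real_, af_eas = NA_real_,
    polyphen = NA_character_, sift = NA_character_,
    cadd_phred = NA_real_, clinvar = NA_character_,
    dbsnp = sprintf("rs%07d", sample.int(9999999L, n)),
    stringsAsFactors = FALSE
  )
  af <- runif(n, cfg$background_af[1], cfg$background_af[2])
  ann$af_global <- round(af, 5)
  ann$af_eas <- round(pmin(pmax(af * runif(n, 0.8, 1.2), 0.011), 0.99), 5)
  ann$variant_id <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann <- ann[, c("variant_id", ANNOTATION_COLS)]
  list(annotation = ann, af = af)
}

simulate_family <- function(i, cfg, backbone, panels, denovo_pool, outlier) {
  set.seed(derive_seed(cfg$seed, i))
  fid <- sprintf("FAM%02d", i)
  ids <- c(proband = sprintf("F%02d_P", i), father = sprintf("F%02d_F", i),
           mother = sprintf("F%02d_M", i))
  sex <- if (runif(1) < 0.784) "female" else "male"
  pedigree <- data.frame(
    family_id = fid, proband_id = ids[["proband"]],
    father_id = ids[["father"]], mother_id = ids[["mother"]],
    proband_sex = sex, affected = TRUE, stringsAsFactors = FALSE
  )

  # Backbone: HWE parents, Mendelian gene-dropping to the child.
  n_bg <- nrow(backbone$annotation)
  af <- backbone$af
  g_fat <- rbinom(n_bg, 2L, af)
  g_mot <- rbinom(n_bg, 2L, af)
  g_pro <- rbinom(n_bg, 1L, g_fat / 2) + rbinom(n_bg, 1L, g_mot / 2)

  counts <- draw_proband_counts(cfg, outlier = outlier)
  implants <- make_family_implants(i, cfg, panels, denovo_pool, counts)

  geno_bg <- backbone_genotypes(cfg, backbone$annotation$variant_id,
                                ids, g_pro, g_fat, g_mot)
  geno_imp <- implant_genotypes(cfg, implants, ids)

  truth <- if (nrow(implants) > 0L) {
    data.frame(
      variant_id = implants$variant_id, family_id = fid,
      proband_id = ids[["proband"]], class = implants$class,
      side = implants$side, mosaic = implants$mosaic,
      comphet = implants$comphet, true_vaf = implants$true_vaf,
      panel = implants$panel, gene = implants$gene,
      qualifying = implants$class %in% c("inherited", "de_novo"),
      stringsAsFactors = FALSE
    )
  } else NULL

  list(pedigree = pedigree,
       implants = implants[, c("variant_id", ANNOTATION_COLS)],
       genotypes = rbind(geno_bg, geno_imp), truth = truth)
}

# Draw the family's implanted variants (annotation + truth attributes).
make_family_implants <- function(i, cfg, panels, denovo_pool, counts) {
  rows <- list()
  add <- function(n, class, genes, consequence, rare, side = NA,
                  mosaic = FALSE, panel = "none", damaging_frac = 0,
                  comphet = FALSE) {
    if (n == 0L) return(invisible(NULL))
    side <- if (length(side) == 1L) rep(side, n) else side
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, gene = genes, consequence = consequence,
      rare = rare, side = side, mosaic = mosaic, panel = panel,
      damaging_frac = damaging_frac, comphet = comphet,
      stringsAsFactors = FALSE
    )
    invisible(NULL)
  }
  draw_csq <- function(n) {
    sample(names(cfg$consequence_probs), n, replace = TRUE,
           prob = cfg$consequence_probs)
  }
  rnd_side <- function(n) sample(c("paternal", "maternal"), n, replace = TRUE)

  with(counts, {
    add(n_mono, "inherited", sample(panels$monogenic$genes, n_mono, TRUE),
        draw_csq(n_mono), rare = TRUE, side = rnd_side(n_mono),
        panel = "monogenic", damaging_frac = cfg$damaging_fraction_panel)
    add(n_gwas, "inherited", sample(panels$gwas$genes, n_gwas, TRUE),
        draw_csq(n_gwas), rare = TRUE, side = rnd_side(n_gwas),
        panel = "gwas", damaging_frac = cfg$damaging_fraction_panel)
    if (comphet) {
      g <- sample(panels$monogenic$genes, 1L)
      add(2L, "inherited", rep(g, 2L), draw_csq(2L), rare = TRUE,
          side = c("paternal", "maternal"), panel = "monogenic",
          damaging_frac = cfg$damaging_fraction_panel, comphet = TRUE)
    }
    n_dn_mosaic <- rbinom(1L, n_denovo, cfg$mosaic_fraction)
    n_dn_germ <- n_denovo - n_dn_mosaic
    dn_gene <- function(n) {
      pool_hit <- runif(n) < 0.96
      ifelse(pool_hit, sample(denovo_pool, n, TRUE),
             sample(panel_union(panels), n, TRUE))
    }
    add(n_dn_germ, "de_novo", dn_gene(n_dn_germ), draw_csq(n_dn_germ),
        rare = TRUE, damaging_frac = cfg$damaging_fraction_denovo)
    add(n_dn_mosaic, "de_novo", dn_gene(n_dn_mosaic),
        draw_csq(n_dn_mosaic), rare = TRUE, mosaic = TRUE,
        damaging_frac = cfg$damaging_fraction_denovo)
    add(n_outlier, "de_novo", dn_gene(n_outlier), draw_csq(n_outlier),
        rare = TRUE, mosaic = TRUE,
        damaging_frac = cfg$damaging_fraction_denovo)
    all_panel <- panel_union(panels)
    add(n_decoy_common, "decoy_common", sample(all_panel, n_decoy_common, TRUE),
        draw_csq(n_decoy_common), rare = FALSE, side = rnd_side(n_decoy_common),
        panel = "panel")
    add(n_decoy_syn, "decoy_synonymous", sample(all_panel, n_decoy_syn, TRUE),
        rep("synonymous", n_decoy_syn), rare = TRUE,
        side = rnd_side(n_decoy_syn), panel = "panel")
  })
  imp <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(class = character(), gene = character(),
               consequence = character(), rare = logical(),
               side = character(), mosaic = logical(), panel = character(),
               damaging_frac = numeric(), comphet = logical(),
               stringsAsFactors = FALSE)
  }
  n <- nrow(imp)
  if (n == 0L) {
    e <- empty_annotation_cols()
    e$variant_id <- character()
    e$class <- character()
    e$side <- character()
    e$mosaic <- logical()
    e$comphet <- logical()
    e$panel <- character()
    e$true_vaf <- numeric()
    return(e)
  }
  bases <- c("A", "C", "G", "T")
  imp$chrom <- sample(as.character(1:22), n, replace = TRUE)
  # Family-indexed position blocks keep implant keys globally unique.
  imp$pos <- as.integer(2e8 + i * 1e4 + seq_len(n))
  imp$ref <- sample(bases, n, replace = TRUE)
  imp$alt <- vapply(seq_len(n), function(j) {
    if (grepl("indel", imp$consequence[j])) {
      paste0(imp$ref[j], sample(bases, 1L))
    } else sample(setdiff(bases, imp$ref[j]), 1L)
  }, "")
  # Population frequencies: rare implants below the MAF threshold or
  # novel (absent); common decoys clearly above it.
  novel <- imp$rare & runif(n) < cfg$novel_af_fraction
  imp$af_global <- ifelse(imp$rare, runif(n, 0, 0.005), runif(n, 0.02, 0.2))
  imp$af_eas <- ifelse(imp$rare, runif(n, 0, 0.005), runif(n, 0.02, 0.2))
  imp$af_global[novel] <- NA_real_
  imp$af_eas[novel] <- NA_real_
  # Predictor profiles: damaging implants get a 3-of-3 damaging profile,
  # the rest a benign one; a sprinkle of absent predictors either way.
  damaging <- runif(n) < imp$damaging_frac
  imp$polyphen <- ifelse(damaging,
                         sample(c("probably_damaging", "possibly_damaging"),
                                n, TRUE, prob = c(0.7, 0.3)),
                         "benign")
  imp$sift <- ifelse(damaging, "deleterious", "tolerated")
  imp$cadd_phred <- ifelse(damaging, runif(n, 21, 35), runif(n, 0, 15))
  miss <- runif(n) < 0.05
  imp$polyphen[miss] <- NA_character_
  imp$clinvar <- sample(c("VUS", "LB", "B", NA_character_), n, TRUE,
                        prob = c(0.45, 0.1, 0.1, 0.35))
  imp$dbsnp <- ifelse(novel, NA_character_,
                      sprintf("rs9%06d", sample.int(999999L, n)))
  imp$true_vaf <- ifelse(imp$mosaic,
                         runif(n, cfg$mosaic_vaf[1], cfg$mosaic_vaf[2]), 0.5)
  imp$variant_id <- variant_key(imp$chrom, imp$pos, imp$ref, imp$alt)
  imp
}

empty_annotation_cols <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), consequence = character(),
             af_global = numeric(), af_eas = numeric(),
             polyphen = character(), sift = character(),
             cadd_phred = numeric(), clinvar = character(),
             dbsnp = character(), stringsAsFactors = FALSE)
}

# Read-level simulation for one family: negative-binomial depth and
# binomial (or expected, in the noiseless limit) alt-read sampling.
sample_reads <- function(cfg, n, true_vaf) {
  dp <- rnbinom(n, size = cfg$depth_size, mu = cfg$depth_mean)
  if (cfg$read_model == "expected") {
    ad_alt <- round(dp * true_vaf)
  } else {
    ad_alt <- rbinom(n, dp, pmax(true_vaf, cfg$error_rate))
  }
  gq <- ifelse(dp >= 15, 99, pmax(3 * dp, 1))
  data.frame(dp = dp, ad_alt = ad_alt, ad_ref = dp - ad_alt, gq = gq)
}

backbone_genotypes <- function(cfg, variant_ids, ids, g_pro, g_fat, g_mot) {
  one <- function(sample_id, g) {
    vaf_true <- g / 2
    rd <- sample_reads(cfg, length(g), vaf_true)
    gt <- c("0/0", "0/1", "1/1")[g + 1L]
    denom <- rd$ad_ref + rd$ad_alt
    data.frame(
      variant_id = variant_ids, sample_id = sample_id, gt = gt,
      ad_ref = rd$ad_ref, ad_alt = rd$ad_alt, dp = rd$dp, gq = rd$gq,
      vaf = ifelse(denom > 0, rd$ad_alt / denom, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  rbind(one(ids[["proband"]], g_pro), one(ids[["father"]], g_fat),
        one(ids[["mother"]], g_mot))
}

implant_genotypes <- function(cfg, implants, ids) {
  n <- nrow(implants)
  if (n == 0L) return(empty_genotypes())
  vaf_of <- function(role) {
    v <- numeric(n)
    carrier_parent <- ifelse(implants$class %in%
                               c("inherited", "decoy_common",
                                 "decoy_synonymous"),
                             implants$side, NA)
    if (role == "proband") {
      v <- implants$true_vaf
    } else {
      v <- ifelse(!is.na(carrier_parent) & carrier_parent ==
                    c(father = "paternal", mother = "maternal")[role],
                  0.5, 0)
    }
    v
  }
  one <- function(role) {
    v <- vaf_of(role)
    rd <- sample_reads(cfg, n, v)
    gt <- ifelse(v == 0, "0/0", "0/1")
    denom <- rd$ad_ref + rd$ad_alt
    data.frame(
      variant_id = implants$variant_id, sample_id = ids[[role]], gt = gt,
      ad_ref = rd$ad_ref, ad_alt = rd$ad_alt, dp = rd$dp, gq = rd$gq,
      vaf = ifelse(denom > 0, rd$ad_alt / denom, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  rbind(one("proband"), one("father"), one("mother"))
}

#' Simulate control cohorts
#'
#' Per-individual count tables with no case enrichment: a rare-variant
#' control cohort (1KGP-like, default n = 105, Poisson mean 3) and a
#' de novo control cohort (population WES database-like, default
#' n = 2049, Poisson mean 0.79). When `panels` is supplied, per-gene
#' control carrier counts over the eQTL panel are generated too, for the
#' carrier-frequency comparison.
#'
#' @param cfg a `SimConfig`.
#' @param panels optional named list of `GenePanel`s.
#' @return list with `rare_counts`, `denovo_counts`, and optionally
#'   `gene_carriers` (named integer vector) plus `n_rare`, `n_denovo`.
#' @export
simulate_controls <- function(cfg, panels = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(derive_seed(cfg$seed, 1000003L))
  out <- list(
    rare_counts = rpois(cfg$n_controls_rare, cfg$control_rare_rate),
    denovo_counts = rpois(cfg$n_controls_denovo, cfg$control_denovo_rate),
    n_rare = cfg$n_controls_rare, n_denovo = cfg$n_controls_denovo
  )
  if (!is.null(panels) && "eqtl" %in% names(panels)) {
    genes <- panels$eqtl$genes
    p_gene <- cfg$control_rare_rate / length(panel_union(panels))
    out$gene_carriers <- setNames(
      rbinom(length(genes), cfg$n_controls_rare, p_gene), genes
    )
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Emits one VCF per trio (`trio_<FAMILY>.vcf`, backbone plus that
#' family's implants), the pedigree (`cohort.ped`), the cohort annotation
#' table (`annotation.tsv`), the truth table (`truth.tsv`) and the three
#' panel TSVs.
#'
#' @param sim a `TrioCohortSim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ped(sim$pedigree, file.path(dir, "cohort.ped"))
  write_annotation(sim$variants, file.path(dir, "annotation.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  for (nm in names(sim$panels)) {
    write_panel(sim$panels[[nm]],
                file.path(dir, paste0("panel_", nm, ".tsv")))
  }
  for (k in seq_len(nrow(sim$pedigree))) {
    trio <- sim$pedigree[k, ]
    samples <- c(trio$proband_id, trio$father_id, trio$mother_id)
    geno <- sim$genotypes[sim$genotypes$sample_id %in% samples, ,
                          drop = FALSE]
    vars <- sim$variants[sim$variants$variant_id %in%
                           unique(geno$variant_id), , drop = FALSE]
    write_vcf(vars, geno, samples,
              file.path(dir, paste0("trio_", trio$family_id, ".vcf")))
  }
  invisible(dir)
}

#' Read a cohort directory back into a `TrioCohortSim`-like object
#'
#' The inverse of [write_cohort()]: loads the pedigree, annotation,
#' panels, truth table, and the per-trio VCFs, reassembling the long
#' genotype table (annotation taken from the TSV, which is authoritative
#' over the VCF INFO copies).
#'
#' @param dir directory written by [write_cohort()].
#' @return list with the same fields as a `TrioCohortSim` except
#'   `config`.
#' @export
read_cohort_dir <- function(dir) {
  pedigree <- read_ped(file.path(dir, "cohort.ped"))
  variants <- read_annotation(file.path(dir, "annotation.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read.table(truth_path, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE, na.strings = "NA")
  } else NULL
  panel_paths <- Sys.glob(file.path(dir, "panel_*.tsv"))
  names(panel_paths) <- sub("^panel_", "", sub("\\.tsv$", "",
                                               basename(panel_paths)))
  panels <- read_panels(panel_paths)
  geno <- vector("list", nrow(pedigree))
  for (k in seq_len(nrow(pedigree))) {
    trio <- pedigree[k, ]
    vcf <- read_trio_vcf(file.path(dir, paste0("trio_", trio$family_id,
                                               ".vcf")), trio)
    geno[[k]] <- vcf$genotypes
  }
  genotypes <- do.call(rbind, geno)
  rownames(genotypes) <- NULL
  common <- !is.na(variants$af_global) & variants$af_global >= 0.02
  structure(list(
    pedigree = pedigree, variants = variants, genotypes = genotypes,
    truth = truth, panels = panels,
    backbone_ids = variants$variant_id[common &
                                         startsWith(variants$gene, "BG")],
    samples = c(rbind(pedigree$proband_id, pedigree$father_id,
                      pedigree$mother_id))
  ), class = "TrioCohortSim")
}
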