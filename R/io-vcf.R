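# VCF input/output. Reading goes through vcfR; records are flattened into
# two data.frames: one variant row per alternate allele (multi-allelic
# sites are decomposed) and one genotype row per (variant, sample).
# Positions are 1-based, fully closed, as in VCF.

VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
  "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
  "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Global allele frequency\">",
  "##INFO=<ID=AF_EAS,Number=A,Type=Float,Description=\"East-Asian allele frequency\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
)

#' Read a multi-sample VCF into variant and genotype tables
#'
#' Multi-allelic rows are decomposed into one record per alternate allele;
#' genotype allele indices are remapped so each record is biallelic (other
#' alternate alleles count as reference for that record). `GENE`, `CSQ`,
#' `AF` and `AF_EAS` INFO keys are parsed when present, else left absent.
#' The per-sample VAF is `ad_alt / (ad_ref + ad_alt)` where the
#' denominator is positive, else absent.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional character vector restricting to these sample
#'   ids; a sample missing from the VCF is a hard error naming it.
#' @return list with `variants` (data.frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `consequence`, `af_global`, `af_eas`) and
#'   `genotypes` (data.frame: `variant_id`, `sample_id`, `gt`, `ad_ref`,
#'   `ad_alt`, `dp`, `gq`, `vaf`).
#' @export
read_cohort_vcf <- function(path, samples = NULL) {
  validate_vcf_lines(path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop_("failed to parse VCF '", path, "': ",
                              conditionMessage(e))
  )
  all_samples <- colnames(v@gt)[-1L]
  if (is.null(samples)) samples <- all_samples
  absent <- setdiff(samples, all_samples)
  if (length(absent) > 0L) {
    stop_("sample(s) not present in VCF '", basename(path), "': ",
          paste(absent, collapse = ", "))
  }
  fix <- v@fix
  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    return(list(variants = empty_variants(), genotypes = empty_genotypes()))
  }
  gt_m <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  ad_m <- vcfR::extract.gt(v, element = "AD")[, samples, drop = FALSE]
  dp_m <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  )[, samples, drop = FALSE]
  gq_m <- suppressWarnings(
    vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  )[, samples, drop = FALSE]

  var_list <- vector("list", n)
  gt_list <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    info <- fix[i, "INFO"]
    af_g <- split_info_numeric(info, "AF", length(alts))
    af_e <- split_info_numeric(info, "AF_EAS", length(alts))
    recs <- lapply(seq_along(alts), function(j) {
      data.frame(
        variant_id = variant_key(fix[i, "CHROM"], fix[i, "POS"],
                                 fix[i, "REF"], alts[j]),
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[j],
        gene = parse_info(info, "GENE"),
        consequence = parse_info(info, "CSQ"),
        af_global = af_g[j], af_eas = af_e[j],
        stringsAsFactors = FALSE
      )
    })
    var_list[[i]] <- do.call(rbind, recs)
    grows <- lapply(seq_along(alts), function(j) {
      decompose_genotypes(
        variant_id = recs[[j]]$variant_id, alt_index = j,
        samples = samples, gt = gt_m[i, ], ad = ad_m[i, ],
        dp = dp_m[i, ], gq = gq_m[i, ]
      )
    })
    gt_list[[i]] <- do.call(rbind, grows)
  }
  variants <- do.call(rbind, var_list)
  rownames(variants) <- NULL
  genotypes <- do.call(rbind, gt_list)
  rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}

#' Read one trio's records from a VCF
#'
#' @param path VCF containing the three pedigree samples.
#' @param trio single-row trio record as produced by [read_ped()].
#' @return as [read_cohort_vcf()], restricted to proband/father/mother.
#' @export
read_trio_vcf <- function(path, trio) {
  stopifnot(nrow(trio) == 1L)
  read_cohort_vcf(path, samples = c(trio$proband_id, trio$father_id,
                                    trio$mother_id))
}

# Cheap structural validation so a malformed body line is reported with
# its line number rather than surfacing as an opaque parser failure.
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1L) stop_("VCF '", path, "': no #CHROM header line")
  n_fields <- length(strsplit(lines[header_i], "\t", fixed = TRUE)[[1L]])
  body <- seq_len(length(lines))[-seq_len(header_i)]
  for (i in body) {
    if (!nzchar(lines[i])) next
    k <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    if (k != n_fields) {
      stop_("malformed VCF line ", i, " in '", basename(path), "': ",
            k, " fields, expected ", n_fields)
    }
  }
  invisible(TRUE)
}

parse_info <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info))
  if (length(m) == 0L || is.na(info)) return(NA_character_)
  sub(paste0("^;?", key, "="), "", m)
}

split_info_numeric <- function(info, key, n_alt) {
  val <- parse_info(info, key)
  if (is.na(val)) return(rep(NA_real_, n_alt))
  out <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]]))
  length(out) <- n_alt
  out
}

# Remap one site's genotype strings onto a single alternate allele:
# allele index == alt_index -> 1, any other index -> 0, missing -> NA.
decompose_genotypes <- function(variant_id, alt_index, samples, gt, ad,
                                dp, gq) {
  parse_one <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_character_)
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1L]]
    if (any(alleles == ".")) return(NA_character_)
    mapped <- ifelse(alleles == as.character(alt_index), "1", "0")
    paste(sort(mapped), collapse = "/")
  }
  gt_new <- vapply(gt, parse_one, character(1), USE.NAMES = FALSE)
  ad_ref <- ad_alt <- rep(NA_real_, length(samples))
  for (s in seq_along(samples)) {
    if (is.na(ad[s]) || ad[s] == ".") next
    depths <- suppressWarnings(
      as.numeric(strsplit(ad[s], ",", fixed = TRUE)[[1L]])
    )
    ad_ref[s] <- depths[1L]
    ad_alt[s] <- if (length(depths) > alt_index) depths[alt_index + 1L] else NA_real_
  }
  denom <- ad_ref + ad_alt
  vaf <- ifelse(!is.na(denom) & denom > 0, ad_alt / denom, NA_real_)
  data.frame(
    variant_id = variant_id, sample_id = samples, gt = gt_new,
    ad_ref = ad_ref, ad_alt = ad_alt,
    dp = as.numeric(dp), gq = as.numeric(gq), vaf = vaf,
    stringsAsFactors = FALSE
  )
}

empty_variants <- function() {
  data.frame(variant_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             consequence = character(), af_global = numeric(),
             af_eas = numeric(), stringsAsFactors = FALSE)
}

empty_genotypes <- function() {
  data.frame(variant_id = character(), sample_id = character(),
             gt = character(), ad_ref = numeric(), ad_alt = numeric(),
             dp = numeric(), gq = numeric(), vaf = numeric(),
             stringsAsFactors = FALSE)
}

#' Write variant and genotype tables as a VCF 4.2 file
#'
#' The inverse of [read_cohort_vcf()] for biallelic records: one row per
#' variant, FORMAT `GT:AD:DP:GQ`, with `GENE`/`CSQ`/`AF`/`AF_EAS` INFO
#' keys taken from the variant table when present.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `gene`, `consequence`, `af_global`, `af_eas`, `dbsnp`.
#' @param genotypes long data.frame with `variant_id`, `sample_id`, `gt`,
#'   `ad_ref`, `ad_alt`, `dp`, `gq`.
#' @param samples sample column order.
#' @param path output path.
#' @export
write_vcf <- function(variants, genotypes, samples, path) {
  ord <- order(suppressWarnings(as.integer(variants$chrom)), variants$chrom,
               variants$pos)
  variants <- variants[ord, , drop = FALSE]
  vid <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  info <- vcf_info_string(variants)
  id <- if ("dbsnp" %in% names(variants)) {
    ifelse(is.na(variants$dbsnp), ".", variants$dbsnp)
  } else rep(".", nrow(variants))

  fmt <- sprintf("%s:%d,%d:%d:%d",
                 ifelse(is.na(genotypes$gt), "./.", genotypes$gt),
                 as.integer(round(genotypes$ad_ref)),
                 as.integer(round(genotypes$ad_alt)),
                 as.integer(round(genotypes$dp)),
                 as.integer(round(genotypes$gq)))
  m <- matrix("./.:0,0:0:0", nrow = nrow(variants), ncol = length(samples))
  ri <- match(genotypes$variant_id, vid)
  ci <- match(genotypes$sample_id, samples)
  keep <- !is.na(ri) & !is.na(ci)
  m[cbind(ri[keep], ci[keep])] <- fmt[keep]

  body <- paste(variants$chrom, variants$pos, id, variants$ref, variants$alt,
                ".", "PASS", info, "GT:AD:DP:GQ", sep = "\t")
  body <- paste(body, apply(m, 1L, paste, collapse = "\t"), sep = "\t")
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t")
  writeLines(c(VCF_HEADER, col_line, body), path)
  invisible(path)
}

vcf_info_string <- function(variants) {
  n <- nrow(variants)
  parts <- list()
  add <- function(key, vals, fmtfun = identity) {
    out <- rep(NA_character_, n)
    ok <- !is.na(vals)
    out[ok] <- paste0(key, "=", fmtfun(vals[ok]))
    out
  }
  if ("gene" %in% names(variants)) parts$gene <- add("GENE", variants$gene)
  if ("consequence" %in% names(variants)) {
    parts$csq <- add("CSQ", variants$consequence)
  }
  if ("af_global" %in% names(variants)) {
    parts$af <- add("AF", variants$af_global, function(x) format(x, digits = 6))
  }
  if ("af_eas" %in% names(variants)) {
    parts$afe <- add("AF_EAS", variants$af_eas,
                     function(x) format(x, digits = 6))
  }
  if (length(parts) == 0L) return(rep(".", n))
  joined <- apply(do.call(cbind, parts), 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) "." else paste(r, collapse = ";")
  })
  joined
}
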