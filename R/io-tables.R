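# Readers and writers for the tabular formats around the VCFs: PED
# pedigrees, gene panels (TSV), gene-set collections (GMT), variant
# annotation tables and gene-by-cell-type expression matrices.

ANNOTATION_COLS <- c(
  "chrom", "pos", "ref", "alt", "gene", "consequence", "af_global",
  "af_eas", "polyphen", "sift", "cadd_phred", "clinvar", "dbsnp"
)

#' Read a 6-column PED pedigree into trio records
#'
#' Standard PED columns: family, individual, father, mother, sex
#' (1 = male, 2 = female, 0 = unknown), phenotype (2 = affected). One trio
#' is emitted per offspring whose two parents are both declared (non-`"0"`)
#' and present as individuals in the file; offspring with an incomplete
#' parental pair are reported and skipped with a warning.
#'
#' @param path PED file path.
#' @return data.frame with columns `family_id`, `proband_id`, `father_id`,
#'   `mother_id`, `proband_sex` (`female`/`male`/`unknown`), `affected`.
#' @export
read_ped <- function(path) {
  ped <- read.table(path, header = FALSE, sep = "", colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(ped) < 6L) stop_("PED file must have 6 columns, found ", ncol(ped))
  names(ped)[1:6] <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  if (anyDuplicated(ped$iid)) stop_("duplicate individual ids in PED")
  check_ped_cycles(ped)
  has_parents <- ped$pat != "0" & ped$mat != "0"
  present <- ped$pat %in% ped$iid & ped$mat %in% ped$iid
  incomplete <- has_parents & !present
  if (any(incomplete)) {
    warn_("skipping ", sum(incomplete),
          " offspring with missing parent record(s): ",
          paste(head(ped$iid[incomplete], 5L), collapse = ", "))
  }
  keep <- ped[has_parents & present, , drop = FALSE]
  trios <- data.frame(
    family_id = keep$fid,
    proband_id = keep$iid,
    father_id = keep$pat,
    mother_id = keep$mat,
    proband_sex = c("0" = "unknown", "1" = "male", "2" = "female")[keep$sex],
    affected = keep$pheno == "2",
    stringsAsFactors = FALSE
  )
  rownames(trios) <- NULL
  trios
}

# Circular parentage (an individual among its own ancestors) is malformed.
check_ped_cycles <- function(ped) {
  parent_of <- setNames(Map(c, ped$pat, ped$mat), ped$iid)
  for (iid in ped$iid) {
    seen <- character()
    frontier <- iid
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(parent_of[frontier], use.names = FALSE))
      nxt <- nxt[!is.na(nxt) & nxt != "0"]
      if (iid %in% nxt) stop_("circular parentage involving '", iid, "'")
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
  }
  invisible(TRUE)
}

#' Write trios to a PED file
#'
#' @param trios data.frame as returned by [read_ped()].
#' @param path output path.
#' @export
write_ped <- function(trios, path) {
  sex_code <- c(female = "2", male = "1", unknown = "0")
  rows <- rbind(
    data.frame(fid = trios$family_id, iid = trios$father_id, pat = "0",
               mat = "0", sex = "1", pheno = "1"),
    data.frame(fid = trios$family_id, iid = trios$mother_id, pat = "0",
               mat = "0", sex = "2", pheno = "1"),
    data.frame(fid = trios$family_id, iid = trios$proband_id,
               pat = trios$father_id, mat = trios$mother_id,
               sex = sex_code[trios$proband_sex],
               pheno = ifelse(trios$affected, "2", "1"))
  )
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene panel from TSV
#'
#' Accepts one symbol per line, or a two-column `name<TAB>symbol` layout.
#' Symbols are normalized (uppercase, trimmed) and duplicates collapsed
#' with a warning. Lines starting with `#` are comments.
#'
#' @param path panel file.
#' @param name panel name; defaults to the file stem.
#' @return a `GenePanel`.
#' @export
read_panel <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_("panel file '", path, "' is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(fields, function(f) f[[length(f)]], character(1))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_panel(name, genes)
}

#' Read several panels at once
#'
#' @param paths named character vector of panel file paths; names become
#'   panel names.
#' @return named list of `GenePanel` objects.
#' @export
read_panels <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  Map(read_panel, paths, names(paths))
}

#' Write a gene panel to TSV (one symbol per line)
#' @param panel a `GenePanel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel$genes, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#' Symbols are normalized and deduplicated per set.
#'
#' @param path GMT file.
#' @return named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop_("malformed GMT line: fewer than 3 fields")
    unique(normalize_symbols(f[-(1:2)]))
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop_("duplicate term ids in GMT")
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-cell-type expression matrix from TSV
#'
#' First column gene symbols, remaining columns cell types; values must be
#' finite and non-negative. Duplicate gene rows are an error.
#'
#' @param path TSV file with a header row.
#' @return numeric matrix, genes in rows (normalized symbols), cell types
#'   in columns.
#' @export
read_expression <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- normalize_symbols(tab[[1L]])
  if (anyDuplicated(genes)) stop_("duplicate gene rows in expression matrix")
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) stop_("non-finite expression values")
  if (any(mat < 0)) stop_("negative expression values")
  rownames(mat) <- genes
  mat
}

#' Write an expression matrix to TSV
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant annotation table
#'
#' TSV with columns `chrom, pos, ref, alt, gene, consequence, af_global,
#' af_eas, polyphen, sift, cadd_phred, clinvar, dbsnp`. Empty strings and
#' `NA` mark absent annotations; absent allele frequencies stay absent
#' (they are never coerced to 0, so novel variants pass MAF filters).
#'
#' @param path TSV file with header.
#' @return data.frame with a `variant_id` key column prepended.
#' @export
read_annotation <- function(path) {
  ann <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), quote = "",
                    colClasses = c(chrom = "character", ref = "character",
                                   alt = "character", gene = "character",
                                   consequence = "character",
                                   polyphen = "character",
                                   sift = "character",
                                   clinvar = "character",
                                   dbsnp = "character"))
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols) > 0L) {
    stop_("annotation table missing column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  ann$gene <- normalize_symbols(ann$gene)
  ann$af_global <- as.numeric(ann$af_global)
  ann$af_eas <- as.numeric(ann$af_eas)
  ann$cadd_phred <- as.numeric(ann$cadd_phred)
  bad_af <- function(x) any(!is.na(x) & (x < 0 | x > 1))
  if (bad_af(ann$af_global) || bad_af(ann$af_eas)) {
    stop_("allele frequencies must lie in [0, 1]")
  }
  ann$variant_id <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann[, c("variant_id", ANNOTATION_COLS)]
}

#' Write a variant annotation table
#' @param ann data.frame with the annotation columns.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  write.table(ann[, ANNOTATION_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
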