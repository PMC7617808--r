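# Constructed prioritization inputs with known truth. The cohort-scale
# pathway/expression intersection needs a gene-set collection and an
# expression matrix; this builds synthetic ones whose enrichment and
# expression structure is fixed by construction, so the whole
# prioritization path (ORA -> top-pathway selection -> expression
# criterion -> Venn intersection) can be verified against known counts.

#' Build a synthetic prioritization fixture
#'
#' Constructs a de novo gene list of size `n_denovo` together with a GMT
#' collection and an expression matrix arranged so that: exactly
#' `n_pathway` of the genes belong to the `n_top_sets` strongly enriched
#' pathway sets (every enriched set holds at least four of them, keeping
#' its hypergeometric `-log10(p)` well above the selection floor, while
#' decoy sets hold none); exactly `n_expression` genes are
#' argmax-expressed in the ABC or plasma-cell columns; and exactly
#' `n_both` genes satisfy both criteria. The first pathway gene is placed
#' in exactly 7 of the enriched sets and the next five in 5, 5, 5, 4 and
#' 4, giving known cluster-membership counts. The remaining background is
#' filler genes absent from the query.
#'
#' @param seed RNG seed for the filler draws.
#' @param n_denovo query size; default 50 (ignored when `genes` is
#'   supplied).
#' @param n_pathway genes in top pathways; default 21.
#' @param n_expression genes passing the expression criterion; default 31.
#' @param n_both genes in both sets; default 12.
#' @param n_top_sets enriched pathway sets; default 20.
#' @param n_background total background universe size; default 2000
#'   (ignored when `filler` is supplied).
#' @param genes optional character vector used as the de novo gene
#'   universe instead of generated placeholder symbols — lets the fixture
#'   wrap around an existing cohort's de novo genes.
#' @param filler optional character vector of background filler genes.
#' @param base_multiplicity sets per pathway gene beyond the six with
#'   fixed counts; default 4. Raise it when the query is dense relative
#'   to the background (a small simulated gene universe) so each
#'   enriched set still clears the `-log10(p)` selection floor.
#' @return list with `denovo_genes`, `gmt`, `expr`, `background`, and
#'   `truth` (list of `pathway_genes`, `expression_genes`, `both`,
#'   `cluster_counts`).
#' @export
make_prioritization_fixture <- function(seed = 1L, n_denovo = 50L,
                                        n_pathway = 21L,
                                        n_expression = 31L, n_both = 12L,
                                        n_top_sets = 20L,
                                        n_background = 2000L,
                                        genes = NULL, filler = NULL,
                                        base_multiplicity = 4L) {
  if (!is.null(genes)) {
    genes <- unique(normalize_symbols(genes))
    n_denovo <- length(genes)
  }
  stopifnot(n_both <= n_pathway, n_both <= n_expression,
            n_pathway + n_expression - n_both <= n_denovo)
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("DNG%03d", seq_len(n_denovo))
  pathway_genes <- genes[seq_len(n_pathway)]
  expr_start <- n_pathway - n_both + 1L
  expression_genes <- genes[seq(expr_start,
                                expr_start + n_expression - 1L)]
  both <- intersect(pathway_genes, expression_genes)
  if (is.null(filler)) {
    filler <- sprintf("FIL%04d", seq_len(n_background - n_denovo))
  } else {
    filler <- setdiff(unique(normalize_symbols(filler)), genes)
    stopifnot(length(filler) >= 10L)
  }
  background <- c(genes, filler)

  # Round-robin membership: known multiplicities for the first six
  # pathway genes, four sets for the rest; every enriched set ends up
  # with >= 4 query members.
  mult <- c(7L, 5L, 5L, 5L, 4L, 4L,
            rep(as.integer(base_multiplicity),
                max(0L, n_pathway - 6L)))[seq_len(n_pathway)]
  slots <- rep(pathway_genes, mult)
  set_of <- ((seq_along(slots) - 1L) %% n_top_sets) + 1L
  gmt <- lapply(seq_len(n_top_sets), function(s) {
    c(slots[set_of == s], sample(filler, 1L))
  })
  names(gmt) <- sprintf("SLE_PATHWAY_%02d", seq_len(n_top_sets))
  decoys <- lapply(seq_len(5L), function(d) sample(filler, 10L))
  names(decoys) <- sprintf("DECOY_%02d", seq_len(5L))
  gmt <- c(gmt, decoys)

  cell_types <- c("ABC", "Plasma cell", "Naive B", "T cell", "Monocyte",
                  "NK")
  expr <- matrix(runif(n_denovo * length(cell_types), 1, 5),
                 nrow = n_denovo,
                 dimnames = list(genes, cell_types))
  pos <- genes %in% expression_genes
  expr[pos, c("ABC", "Plasma cell")] <- 0.5
  target_col <- ifelse(seq_len(n_denovo) %% 2L == 0L, "Plasma cell", "ABC")
  expr[cbind(which(pos), match(target_col[pos], cell_types))] <-
    10 + runif(sum(pos))
  # Non-positive genes must not peak in a target column.
  expr[!pos, "T cell"] <- 10 + runif(sum(!pos))

  list(
    denovo_genes = genes, gmt = gmt, expr = expr,
    background = background,
    truth = list(pathway_genes = pathway_genes,
                 expression_genes = expression_genes, both = both,
                 cluster_counts = setNames(mult, pathway_genes))
  )
}
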