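# Candidate-gene prioritization: hypergeometric over-representation
# analysis over a GMT collection, the B-cell expression criterion, and
# the intersection that yields the candidate list.

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against each set of a collection over a fixed
#' background. For a set with `K` background members, a query of size
#' `n` drawn from a background of size `N`, and `k` observed overlaps,
#' the enrichment p-value is the upper tail
#' `p = P(X >= k), X ~ Hypergeometric(N, K, n)`. Benjamini-Hochberg
#' correction is applied across the tested sets. Sets with fewer than
#' `min_set_size` background members are skipped. Gene symbols are
#' normalized; query genes outside the background are dropped with a
#' message (the test is conditional on the background universe).
#'
#' @param query character vector of query genes (non-empty after
#'   normalization, else an error).
#' @param genesets named list of character vectors (term -> genes), e.g.
#'   from [read_gmt()].
#' @param background character vector: the gene universe.
#' @param min_set_size minimum background members per set; default 3.
#' @return data.frame sorted by `p` (ties broken by term id): `term`,
#'   `term_genes` (K), `query_hits` (k), `query_size` (n),
#'   `background_size` (N), `p`, `q`, `overlap` (comma-joined genes).
#' @export
ora <- function(query, genesets, background, min_set_size = 3L) {
  query <- unique(normalize_symbols(query))
  background <- unique(normalize_symbols(background))
  dropped <- setdiff(query, background)
  if (length(dropped) > 0L) {
    message(length(dropped), " query gene(s) outside the background dropped")
  }
  query <- intersect(query, background)
  if (length(query) == 0L) stop_("empty query after background restriction")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(genesets), function(term) {
    set <- intersect(unique(normalize_symbols(genesets[[term]])), background)
    K <- length(set)
    if (K < min_set_size) return(NULL)
    hits <- intersect(set, query)
    k <- length(hits)
    data.frame(term = term, term_genes = K, query_hits = k, query_size = n,
               background_size = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               overlap = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop_("no gene set passed the size filter")
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term", "term_genes", "query_hits", "query_size",
          "background_size", "p", "q", "overlap")]
}

#' Select the top enriched pathways
#'
#' Keeps terms with `-log10(p)` above `min_neglog10_p` and returns the
#' `n_top` most significant, ranked by p with lexicographic tie-breaking
#' on the term id.
#'
#' @param res ORA result table from [ora()].
#' @param n_top number of pathways to keep; default 20.
#' @param min_neglog10_p significance floor on `-log10(p)`; default 4.
#' @return subset of `res`.
#' @export
select_top_pathways <- function(res, n_top = 20L, min_neglog10_p = 4) {
  keep <- res[-log10(res$p) > min_neglog10_p, , drop = FALSE]
  keep <- keep[order(keep$p, keep$term), , drop = FALSE]
  head(keep, n_top)
}

#' Count top-pathway memberships per gene
#'
#' For each gene, the number of selected pathway sets that contain it -
#' the support used to rank candidate genes.
#'
#' @param genes character vector of genes.
#' @param top_sets named list of character vectors (the selected pathway
#'   gene sets).
#' @return named integer vector.
#' @export
cluster_membership_count <- function(genes, top_sets) {
  genes <- normalize_symbols(genes)
  sets <- lapply(top_sets, normalize_symbols)
  vapply(setNames(genes, genes), function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1)))
  }, integer(1))
}

#' B-cell expression criterion
#'
#' Flags genes whose expression singles out the target B-cell subsets
#' (age-associated B cells and plasma cells). In `argmax` mode (default)
#' a gene qualifies when its maximum expression across cell types is
#' achieved in a target cell type, strictly above every non-target cell
#' type (constant or tied rows do not qualify). In `zscore` mode it
#' qualifies when its across-cell-type z-score in a target cell type
#' reaches `z_cut`; constant rows (zero variance) never qualify. Genes
#' absent from the matrix are `FALSE` and reported via a message.
#'
#' @param genes character vector of genes to evaluate.
#' @param expr expression matrix (genes x cell types), e.g. from
#'   [read_expression()].
#' @param targets patterns identifying target cell-type columns
#'   (case-insensitive fixed substrings); default `c("ABC", "plasma")`.
#' @param mode `"argmax"` (default) or `"zscore"`.
#' @param z_cut z-score threshold for `zscore` mode; default 1.5.
#' @return named logical vector over `genes`.
#' @export
expression_criterion <- function(genes, expr, targets = c("ABC", "plasma"),
                                 mode = c("argmax", "zscore"), z_cut = 1.5) {
  mode <- match.arg(mode)
  genes <- normalize_symbols(genes)
  cols <- colnames(expr)
  is_target <- Reduce(`|`, lapply(targets, function(t) {
    grepl(t, cols, ignore.case = TRUE, fixed = FALSE)
  }))
  if (!any(is_target)) stop_("no expression column matches the target cell types")
  if (all(is_target)) stop_("all expression columns match the target cell types")
  out <- setNames(rep(FALSE, length(genes)), genes)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0L) {
    message(length(absent), " gene(s) absent from the expression matrix: ",
            paste(head(absent, 5L), collapse = ", "))
  }
  for (g in intersect(genes, rownames(expr))) {
    x <- expr[g, ]
    if (mode == "argmax") {
      out[g] <- max(x[is_target]) > max(x[!is_target])
    } else {
      s <- stats::sd(x)
      out[g] <- s > 0 && any((x[is_target] - mean(x)) / s >= z_cut)
    }
  }
  out
}

#' Intersect pathway and expression evidence into candidate genes
#'
#' The prioritization scheme: among genes carrying de novo variants,
#' candidates are those both belonging to the top enriched pathways and
#' highly expressed in the target B-cell subsets. Emits the Venn counts
#' (pathway-only / expression-only / both) and the candidate table sorted
#' by the number of supporting pathway clusters.
#'
#' @param denovo_genes genes carrying de novo variants (the universe of
#'   the Venn diagram).
#' @param pathway_genes de novo genes belonging to the top pathways.
#' @param expression_genes de novo genes passing the expression criterion.
#' @param panels named list of `GenePanel`s; sets the `prior_sle_gene`
#'   flag from the monogenic/GWAS panels.
#' @param top_sets optional named list of top-pathway gene sets used to
#'   count supporting clusters for ranking.
#' @return list with `venn` (named counts `pathway_only`,
#'   `expression_only`, `both`) and `candidates` (data.frame: `gene`,
#'   `in_top_pathways`, `high_in_abc_or_plasma`, `prior_sle_gene`,
#'   `de_novo`, `n_clusters`, `candidate`).
#' @export
intersect_candidates <- function(denovo_genes, pathway_genes,
                                 expression_genes, panels,
                                 top_sets = NULL) {
  denovo_genes <- sort(unique(normalize_symbols(denovo_genes)))
  pathway_genes <- intersect(denovo_genes, normalize_symbols(pathway_genes))
  expression_genes <- intersect(denovo_genes,
                                normalize_symbols(expression_genes))
  both <- intersect(pathway_genes, expression_genes)
  prior <- panel_union(panels, intersect(names(panels),
                                         c("monogenic", "gwas")))
  n_clusters <- if (!is.null(top_sets)) {
    cluster_membership_count(denovo_genes, top_sets)
  } else setNames(rep(NA_integer_, length(denovo_genes)), denovo_genes)
  tab <- data.frame(
    gene = denovo_genes,
    in_top_pathways = denovo_genes %in% pathway_genes,
    high_in_abc_or_plasma = denovo_genes %in% expression_genes,
    prior_sle_gene = denovo_genes %in% prior,
    de_novo = TRUE,
    n_clusters = unname(n_clusters[denovo_genes]),
    stringsAsFactors = FALSE
  )
  tab$candidate <- tab$in_top_pathways & tab$high_in_abc_or_plasma
  ord <- order(-tab$candidate,
               -ifelse(is.na(tab$n_clusters), -1L, tab$n_clusters), tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(
    venn = c(pathway_only = length(setdiff(pathway_genes, both)),
             expression_only = length(setdiff(expression_genes, both)),
             both = length(both)),
    candidates = tab
  )
}
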