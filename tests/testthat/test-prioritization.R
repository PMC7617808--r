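# Independent oracle for the hypergeometric upper tail: exhaustive
# enumeration of all equally likely query draws from a small background.
enum_upper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

test_that("ORA matches exhaustive enumeration on small universes", {
  # The 2-of-2 draw from a 4-gene background: 1 favourable of C(4,2)=6.
  bg <- c("A", "B", "C", "D")
  sets <- list(S = c("A", "B"))
  res <- ora(c("A", "B"), sets, bg, min_set_size = 2L)
  expect_equal(res$p, 1 / 6)
  expect_equal(res$p, enum_upper_tail(4, 2, 2, 2))

  set.seed(701)
  for (rep in 1:20) {
    N <- sample(5:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    bg <- sprintf("G%02d", seq_len(N))
    sets <- list(S = bg[seq_len(K)])
    query <- sample(bg, n)
    k <- sum(query %in% sets$S)
    res <- ora(query, sets, bg, min_set_size = 2L)
    expect_equal(res$p, enum_upper_tail(N, K, n, k), tolerance = 1e-12)
    expect_equal(res$query_hits, k)
  }
})

test_that("zero overlap gives p = 1 and small sets are skipped", {
  bg <- sprintf("G%02d", 1:20)
  sets <- list(S = bg[1:5], TINY = bg[6:7])
  res <- ora(bg[10:15], sets, bg)
  expect_equal(res$term, "S")  # TINY skipped (K < 3)
  expect_equal(res$p, 1)
  expect_error(ora(c("ZZZ"), sets, bg), "empty query")
})

test_that("BH adjustment reproduces the hand step-up and stays monotone", {
  bg <- sprintf("G%03d", 1:100)
  # Three sets engineered to give p ~= (0.01, 0.02, 0.03)-ordered values
  # is overkill; the BH contract is checked directly on the q column of
  # an ORA run plus the hand case via p.adjust equivalence.
  q <- p.adjust(c(0.01, 0.02, 0.03), method = "BH")
  expect_equal(q, c(0.03, 0.03, 0.03))

  set.seed(702)
  sets <- lapply(1:8, function(i) sample(bg, sample(3:20, 1)))
  names(sets) <- paste0("S", 1:8)
  res <- ora(sample(bg, 25), sets, bg)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_true(all(diff(res$q) >= -1e-12))  # monotone in rank order
})

test_that("top-pathway selection applies the -log10 p floor and tie-breaks", {
  res <- data.frame(term = c("B", "A", "C"), p = c(1e-6, 1e-6, 1e-3),
                    stringsAsFactors = FALSE)
  top <- select_top_pathways(res, n_top = 2, min_neglog10_p = 4)
  expect_equal(top$term, c("A", "B"))  # C fails the floor; ties by term id
})

test_that("cluster membership counts are exact on the constructed fixture", {
  fx <- make_prioritization_fixture(seed = 3)
  res <- ora(fx$denovo_genes, fx$gmt, fx$background)
  top <- select_top_pathways(res)
  top_sets <- lapply(setNames(top$term, top$term), function(t) fx$gmt[[t]])
  cc <- cluster_membership_count(names(fx$truth$cluster_counts)[1:6],
                                 top_sets)
  expect_equal(unname(cc), c(7L, 5L, 5L, 5L, 4L, 4L))
  expect_equal(unname(cluster_membership_count("FIL0001", top_sets)[1]),
               sum(vapply(top_sets, function(s) "FIL0001" %in% s,
                          logical(1))))
  all20 <- cluster_membership_count(fx$denovo_genes[1], fx$gmt[1:20])
  expect_lte(unname(all20), 20L)
})

test_that("the expression criterion flags target-cell argmax genes exactly", {
  expr <- rbind(
    ABCMAX = c(10, 1, 1, 1),
    UNIFORM = c(2, 2, 2, 2),
    TMAX = c(1, 2, 9, 1),
    PLASMAX = c(3, 8, 2, 1)
  )
  colnames(expr) <- c("ABC", "Plasma cell", "T cell", "NK")
  flags <- expression_criterion(rownames(expr), expr)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE, TRUE))
  # z-score mode: constant rows never qualify.
  zf <- expression_criterion(rownames(expr), expr, mode = "zscore")
  expect_false(zf[["UNIFORM"]])
  expect_true(zf[["ABCMAX"]])
  # Absent genes are FALSE with a message.
  expect_message(ab <- expression_criterion("MISSING", expr), "absent")
  expect_false(ab[["MISSING"]])
})

test_that("a matrix with 19 implanted ABC-max genes yields exactly 19 flags", {
  set.seed(703)
  genes <- sprintf("G%02d", 1:50)
  expr <- matrix(runif(50 * 5, 1, 5), 50,
                 dimnames = list(genes, c("ABC", "Plasma cell", "Naive B",
                                          "T cell", "NK")))
  expr[, "T cell"] <- 10  # default peak outside the targets
  implanted <- genes[1:19]
  expr[implanted, "ABC"] <- 20
  flags <- expression_criterion(genes, expr)
  expect_equal(sum(flags), 19L)
  expect_setequal(names(flags)[flags], implanted)
})

test_that("candidate intersection reproduces set algebra and panel flags", {
  panels <- make_default_panels()
  ic <- intersect_candidates(c("A", "B", "C", "D", "TYK2"),
                             pathway_genes = c("A", "B", "C", "TYK2"),
                             expression_genes = c("B", "C", "D", "TYK2"),
                             panels = panels)
  expect_equal(unname(ic$venn["both"]), 3L)
  both_genes <- ic$candidates$gene[ic$candidates$candidate]
  expect_setequal(both_genes, c("B", "C", "TYK2"))
  expect_true(ic$candidates$prior_sle_gene[ic$candidates$gene == "TYK2"])
  expect_false(any(ic$candidates$prior_sle_gene[ic$candidates$gene %in%
                                                  c("A", "B")]))
})

test_that("the full prioritization fixture reproduces the 9/19/12 Venn", {
  fx <- make_prioritization_fixture(seed = 3)
  res <- ora(fx$denovo_genes, fx$gmt, fx$background)
  top <- select_top_pathways(res)
  expect_equal(nrow(top), 20L)
  top_sets <- lapply(setNames(top$term, top$term), function(t) fx$gmt[[t]])
  in_top <- vapply(fx$denovo_genes, function(g) {
    any(vapply(top_sets, function(s) g %in% s, logical(1)))
  }, logical(1))
  path_genes <- fx$denovo_genes[in_top]
  expr_flags <- expression_criterion(fx$denovo_genes, fx$expr)
  ic <- intersect_candidates(fx$denovo_genes, path_genes,
                             names(expr_flags)[expr_flags],
                             make_default_panels(), top_sets)
  expect_equal(unname(ic$venn),
               c(9L, 19L, 12L))
  # Order invariance of the intersection.
  set.seed(704)
  ic2 <- intersect_candidates(sample(fx$denovo_genes), sample(path_genes),
                              sample(names(expr_flags)[expr_flags]),
                              make_default_panels(), top_sets)
  expect_equal(ic, ic2)
})
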