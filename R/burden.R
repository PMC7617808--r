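# Case-control burden statistics: per-proband/per-panel variant counts,
# the binned chi-square comparison, per-gene carrier-frequency ratios,
# the de novo rate comparison and the qPCR 2^-ddCt utility.

#' Per-proband qualifying variant counts by panel
#'
#' Counts distinct qualifying rare variants per proband in each panel,
#' in the combined SLE panel (monogenic or GWAS) and overall. Medians use
#' the midpoint-of-central-pair convention for even n (the convention
#' needed to report half-integer medians such as 4.5).
#'
#' @param filtered cascade-surviving carrier table with `proband_id`,
#'   `variant_id`, and `in_<panel>` membership columns.
#' @param proband_ids all probands (zero rows still yield zero counts).
#' @param panels named list of `GenePanel`s (defines the columns).
#' @return list with `table` (data.frame, one row per proband, one count
#'   column per panel plus `sle` and `all`), `medians` and `ranges`
#'   (named per column).
#' @export
per_proband_counts <- function(filtered, proband_ids, panels) {
  cols <- c(names(panels), "sle", "all")
  tab <- data.frame(proband_id = proband_ids, stringsAsFactors = FALSE)
  for (cl in cols) tab[[cl]] <- 0L
  if (nrow(filtered) > 0L) {
    filtered <- filtered[!duplicated(paste(filtered$proband_id,
                                           filtered$variant_id)), ,
                         drop = FALSE]
    member <- function(row, cl) {
      if (cl == "all") return(rep(TRUE, nrow(row)))
      if (cl == "sle") return(row$in_monogenic | row$in_gwas)
      row[[paste0("in_", cl)]]
    }
    for (cl in cols) {
      cnt <- tapply(member(filtered, cl), filtered$proband_id, sum)
      idx <- match(names(cnt), tab$proband_id)
      ok <- !is.na(idx)
      tab[[cl]][idx[ok]] <- as.integer(cnt[ok])
    }
  }
  medians <- vapply(cols, function(cl) median(tab[[cl]]), numeric(1))
  ranges <- lapply(setNames(cols, cols), function(cl) range(tab[[cl]]))
  list(table = tab, medians = medians, ranges = ranges)
}

#' Binned chi-square burden comparison
#'
#' Compares per-individual variant-count distributions between cases and
#' controls. In `binned` mode counts are binned (default 0, 1, 2, 3, 4,
#' >=5) into a groups x bins contingency table tested with Pearson's
#' chi-square without continuity correction; in `carrier` mode a 2x2
#' carrier/non-carrier table is used. Expected counts are returned, with
#' a warning when any expected cell falls below 5.
#'
#' @param case_counts,control_counts integer vectors of per-individual
#'   counts.
#' @param max_bin counts at or above this value share the top bin;
#'   default 5.
#' @param mode `"binned"` (default) or `"carrier"`.
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
burden_chisq <- function(case_counts, control_counts, max_bin = 5L,
                         mode = c("binned", "carrier")) {
  mode <- match.arg(mode)
  if (length(case_counts) == 0L || length(control_counts) == 0L) {
    stop_("both groups must be non-empty")
  }
  if (mode == "binned") {
    lv <- 0:max_bin
    bin <- function(x) factor(pmin(x, max_bin), levels = lv)
    obs <- rbind(case = table(bin(case_counts)),
                 control = table(bin(control_counts)))
    colnames(obs)[ncol(obs)] <- paste0(">=", max_bin)
    obs <- obs[, colSums(obs) > 0, drop = FALSE]
  } else {
    obs <- rbind(case = table(factor(case_counts > 0, c(FALSE, TRUE))),
                 control = table(factor(control_counts > 0, c(FALSE, TRUE))))
    colnames(obs) <- c("non_carrier", "carrier")
    obs <- obs[, colSums(obs) > 0, drop = FALSE]
  }
  if (ncol(obs) < 2L) {
    stop_("degenerate contingency table: a single occupied bin")
  }
  ht <- suppressWarnings(chisq.test(obs, correct = FALSE))
  if (any(ht$expected < 5)) {
    warn_("expected cell count below 5; chi-square approximation may be poor")
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, observed = obs, expected = ht$expected)
}

#' Per-gene carrier-frequency comparison
#'
#' A carrier is an individual with at least one qualifying rare variant
#' in the gene. Reports per-gene case and control carrier proportions and
#' their ratio; genes absent from controls but carried by cases get an
#' infinite ratio and are retained. The selection list keeps genes with
#' carrier prevalence at least `min_ratio` times the control prevalence.
#'
#' @param case_carriers,control_carriers named integer vectors of
#'   carrier counts per gene.
#' @param n_case,n_control cohort sizes.
#' @param min_ratio selection threshold; default 2.
#' @return data.frame sorted by case proportion (descending): `gene`,
#'   `case_carriers`, `control_carriers`, `case_prop`, `control_prop`,
#'   `ratio`, `selected`.
#' @export
gene_carrier_comparison <- function(case_carriers, control_carriers,
                                    n_case, n_control, min_ratio = 2) {
  genes <- union(names(case_carriers), names(control_carriers))
  cc <- setNames(rep(0L, length(genes)), genes)
  cc[names(case_carriers)] <- case_carriers
  kk <- setNames(rep(0L, length(genes)), genes)
  kk[names(control_carriers)] <- control_carriers
  case_prop <- cc / n_case
  ctrl_prop <- kk / n_control
  ratio <- ifelse(ctrl_prop > 0, case_prop / ctrl_prop,
                  ifelse(case_prop > 0, Inf, NaN))
  out <- data.frame(gene = genes, case_carriers = unname(cc),
                    control_carriers = unname(kk),
                    case_prop = unname(case_prop),
                    control_prop = unname(ctrl_prop),
                    ratio = unname(ratio), stringsAsFactors = FALSE)
  out$selected <- !is.nan(out$ratio) & out$ratio >= min_ratio &
    out$case_prop > 0
  out <- out[order(-out$case_prop, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' De novo rate comparison between cohorts
#'
#' Compares per-sample de novo counts between a case cohort and a control
#' cohort: mean counts and their ratio, a two-sided Mann-Whitney test on
#' the per-sample counts, and a sensitivity re-run excluding flagged
#' outlier probands (candidate somatic-mosaicism cases whose inflated
#' counts could drive the signal on their own).
#'
#' @param case_counts named vector of per-proband counts.
#' @param control_counts vector of per-control counts.
#' @param exclude proband ids to drop in the sensitivity re-run; default
#'   the outliers found by [flag_outlier_probands()].
#' @return list with `mean_case`, `mean_control`, `rate_ratio`,
#'   `p_value`, `excluded`, and `sensitivity` (same statistics after
#'   exclusion, `NULL` when nothing is excluded).
#' @export
denovo_rate_comparison <- function(case_counts, control_counts,
                                   exclude = NULL) {
  if (length(case_counts) == 0L || length(control_counts) == 0L) {
    stop_("both cohorts must be non-empty")
  }
  base_stats <- function(x) {
    mc <- mean(x); mk <- mean(control_counts)
    list(mean_case = mc, mean_control = mk,
         rate_ratio = if (mk > 0) mc / mk else Inf,
         p_value = suppressWarnings(
           wilcox.test(x, control_counts, alternative = "two.sided")$p.value
         ))
  }
  out <- base_stats(case_counts)
  if (is.null(exclude)) {
    exclude <- suppressWarnings(flag_outlier_probands(case_counts)$flagged)
  }
  out$excluded <- exclude
  out$sensitivity <- if (length(exclude) > 0L && !is.null(names(case_counts))) {
    base_stats(case_counts[!names(case_counts) %in% exclude])
  } else NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `fold = 2 ^ -((Ct_target,case - Ct_ref,case) -
#'               (Ct_target,control - Ct_ref,control))`
#' where the reference gene (for instance GAPDH) normalizes input amounts.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl finite
#'   cycle-threshold values (vectors recycle as usual).
#' @return fold change(s) relative to control.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_case), is.finite(ct_ref_case),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
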