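#' @name qpcr
#' @title Relative expression by the 2^-ddCt method
#'
#' @description
#' The Livak method: per replicate, the target gene's cycle threshold is
#' normalized to an internal reference gene (dCt = Ct_target - Ct_ref);
#' the treatment group's mean dCt is then referenced to the control group's
#' mean dCt (ddCt), and relative expression is `2^-ddCt`.  Replicates whose
#' Ct reaches the cycle limit (45 cycles by default) are treated as
#' non-detects and excluded with a warning.
NULL

#' Read a qPCR Ct table
#'
#' @param path TSV with columns gene, group, replicate, ct_target,
#'   ct_reference (optional `#` comments, optional header).
#' @return A typed `data.frame` with those columns.
#' @export
read_qpcr_table <- function(path) {
  read_tsv_table(path, c(gene = "character", group = "character",
                         replicate = "integer", ct_target = "numeric",
                         ct_reference = "numeric"))
}

#' Fold change of one gene between two groups
#'
#' @param samples a `data.frame` as from [read_qpcr_table()].
#' @param gene gene to analyse.
#' @param treatment_group,control_group group labels.
#' @param ct_limit cycle limit; Ct values at or above it are non-detects
#'   (default 45).
#' @return A list: `fold_change` (`2^-ddCt` from group-mean dCt), `ddct`,
#'   `per_replicate` (list of per-replicate fold changes in each group,
#'   computed against the control-mean dCt, for dispersion reporting).
#' @export
ddct_fold_change <- function(samples, gene, treatment_group, control_group,
                             ct_limit = 45) {
  stopifnot(all(c("gene", "group", "ct_target", "ct_reference") %in%
                  names(samples)))
  x <- samples[samples$gene == gene, , drop = FALSE]
  nd <- x$ct_target >= ct_limit | x$ct_reference >= ct_limit
  if (any(nd)) {
    warning(sprintf("%s: excluded %d non-detect replicate(s)", gene, sum(nd)))
    x <- x[!nd, , drop = FALSE]
  }
  grab <- function(grp) {
    g <- x[x$group == grp, , drop = FALSE]
    if (!nrow(g)) stop(sprintf("gene '%s' has no replicates in group '%s'",
                               gene, grp))
    g$ct_target - g$ct_reference
  }
  dct_t <- grab(treatment_group)
  dct_c <- grab(control_group)
  ddct <- mean(dct_t) - mean(dct_c)
  list(fold_change = 2^(-ddct),
       ddct = ddct,
       per_replicate = list(
         treatment = 2^(-(dct_t - mean(dct_c))),
         control = 2^(-(dct_c - mean(dct_c)))))
}

#' Two-group comparison of per-replicate fold changes
#'
#' @param folds_a,folds_b numeric vectors of per-replicate fold changes
#'   (at least 2 each).
#' @param alpha significance level (default 0.01).
#' @param var_equal pooled-variance t-test when `TRUE` (default), Welch
#'   otherwise.
#' @return A list: `statistic`, `p_value`, `significant` (`p < alpha`).
#' @export
compare_groups <- function(folds_a, folds_b, alpha = 0.01,
                           var_equal = TRUE) {
  if (length(folds_a) < 2L || length(folds_b) < 2L) {
    stop("at least 2 replicates per group are required")
  }
  tt <- stats::t.test(folds_a, folds_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic),
       p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Fold-change and significance table over genes
#'
#' @inheritParams ddct_fold_change
#' @inheritParams compare_groups
#' @param genes genes to analyse (default: all in `samples`).
#' @return A `data.frame`: gene, fold_change, ddct, statistic, p_value,
#'   significant.
#' @export
qpcr_analysis <- function(samples, treatment_group, control_group,
                          genes = unique(samples$gene), alpha = 0.01,
                          var_equal = TRUE, ct_limit = 45) {
  rows <- lapply(genes, function(g) {
    fc <- ddct_fold_change(samples, g, treatment_group, control_group,
                           ct_limit = ct_limit)
    cmp <- compare_groups(fc$per_replicate$treatment,
                          fc$per_replicate$control,
                          alpha = alpha, var_equal = var_equal)
    data.frame(gene = g, fold_change = fc$fold_change, ddct = fc$ddct,
               statistic = cmp$statistic, p_value = cmp$p_value,
               significant = cmp$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
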