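## Comparative statistics on feature-defined transcript subsets:
## CDF/Wilcoxon comparison of TE log2FC distributions and condition-wise
## feature-share tests.

#' Compare the TE log2FC distribution of a gene subset against a reference
#'
#' Restricts the TE results to the subset (e.g. genes with uORFs or stall
#' sites) and compares its log2FC distribution against the complement (or
#' an explicit second gene set) with a two-sided Wilcoxon rank-sum test
#' (exact for groups of <= 20 untied values, normal approximation with tie
#' and continuity correction otherwise). CDF points for both groups are
#' exported for plotting.
#'
#' @param teResults data.frame from [differentialTE()]/[classifyTE()].
#' @param subset character vector of gene ids (group A).
#' @param reference `"complement"` (default), `"all"`, or a character
#'   vector of gene ids (group B).
#' @param subsetName label for the comparison.
#' @param lfcColumn column holding the log2FC (default `"te_lfc"`).
#' @return list of class `"subsetComparison"`: `subset_name`, `n_a`, `n_b`,
#'   `lfc_a`, `lfc_b`, `wilcoxon_W`, `p_value`, `median_shift` (median A -
#'   median B), `cdf` (data.frame `group`, `lfc`, `cdf`).
#' @export
teCdfComparison <- function(teResults, subset, reference = "complement",
                            subsetName = "subset", lfcColumn = "te_lfc") {
  lfc <- setNames(teResults[[lfcColumn]], teResults$gene_id)
  lfc <- lfc[!is.na(lfc)]
  a <- lfc[names(lfc) %in% subset]
  b <- if (identical(reference, "complement")) {
    lfc[!names(lfc) %in% subset]
  } else if (identical(reference, "all")) {
    lfc
  } else {
    lfc[names(lfc) %in% reference]
  }
  if (!length(a) || !length(b)) stop("empty subset group")
  wt <- .wilcoxonRankSum(unname(a), unname(b))
  cdf <- rbind(
    data.frame(group = "subset", lfc = sort(unname(a)),
               cdf = seq_along(a) / length(a)),
    data.frame(group = "reference", lfc = sort(unname(b)),
               cdf = seq_along(b) / length(b)))
  out <- list(subset_name = subsetName, n_a = length(a), n_b = length(b),
              lfc_a = unname(a), lfc_b = unname(b),
              wilcoxon_W = wt$W, p_value = wt$p,
              median_shift = stats::median(a) - stats::median(b),
              cdf = cdf)
  class(out) <- "subsetComparison"
  out
}

#' @export
print.subsetComparison <- function(x, ...) {
  cat(sprintf("subsetComparison '%s': n=%d vs %d, W=%.0f, p=%.3g, median shift %+.3f\n",
              x$subset_name, x$n_a, x$n_b, x$wilcoxon_W, x$p_value,
              x$median_shift))
  invisible(x)
}

#' Condition-wise feature-share test
#'
#' Given per-replicate feature counts (e.g. number of transcripts carrying
#' uORFs) in two conditions, computes each replicate pair's share of the
#' total and compares the shares with a two-sample Student's t-test.
#' Replicates are paired by position.
#'
#' @param condCounts,ctrlCounts integer vectors of per-replicate feature
#'   counts (same length >= 1).
#' @return list: `shares` (data.frame `condition`, `replicate`, `count`,
#'   `share`), `t_statistic`, `p_value` (NA with a warning when a test is
#'   impossible: single replicate or no features).
#' @export
featureShareTest <- function(condCounts, ctrlCounts) {
  stopifnot(length(condCounts) == length(ctrlCounts))
  tot <- condCounts + ctrlCounts
  shareA <- ifelse(tot > 0, condCounts / tot, 0)
  shareB <- ifelse(tot > 0, ctrlCounts / tot, 0)
  shares <- rbind(
    data.frame(condition = "condition", replicate = seq_along(condCounts),
               count = condCounts, share = shareA),
    data.frame(condition = "control", replicate = seq_along(ctrlCounts),
               count = ctrlCounts, share = shareB))
  if (length(condCounts) < 2L) {
    warning("single replicate: shares reported, p omitted")
    return(list(shares = shares, t_statistic = NA_real_,
                p_value = NA_real_))
  }
  if (all(tot == 0)) {
    warning("no features in any replicate: p omitted")
    return(list(shares = shares, t_statistic = NA_real_,
                p_value = NA_real_))
  }
  tt <- .studentT(shareA, shareB)
  list(shares = shares, t_statistic = tt$t, p_value = tt$p)
}
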