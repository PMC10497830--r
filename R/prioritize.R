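## Internal gene-set enrichment with a directionality consensus, network
## connections-per-gene, and the importance score S that ranks genes by
## TE evidence, pathway evidence, effect size and connectivity.

#' Gene-set enrichment of TE results
#'
#' Default mode: one-sided hypergeometric over-representation of
#' significant TE genes within each set (universe = tested genes).
#' Alternative `"rank"` mode: Wilcoxon rank-sum of the set members' TE
#' log2FC against the complement. Directionality is the sign of the mean
#' TE log2FC over the set's universe members, and the combined score
#' `-log10(p) * direction` is defined only for sets with more than 5
#' universe members.
#'
#' @param teResults classified results from [classifyTE()].
#' @param sets A [GeneSetCollection-class].
#' @param universe optional universe (default: tested genes).
#' @param mode `"hypergeometric"` or `"rank"`.
#' @return data.frame: `set_name`, `size` (universe members), `n_sig`,
#'   `p_value`, `mean_lfc`, `direction` (+1/-1), `combined_score` (NA for
#'   sets of 5 or fewer genes).
#' @export
geneSetEnrichment <- function(teResults, sets,
                              universe = teResults$gene_id,
                              mode = c("hypergeometric", "rank")) {
  mode <- match.arg(mode)
  if (is.null(teResults$significant))
    stop("teResults must be classified (run classifyTE)")
  te <- teResults[teResults$gene_id %in% universe, , drop = FALSE]
  N <- nrow(te)
  sigGenes <- te$gene_id[te$significant]
  K <- length(sigGenes)
  lfc <- setNames(te$te_lfc, te$gene_id)
  rows <- list(); droppedSets <- character(0)
  for (nm in names(sets@sets)) {
    members <- intersect(sets@sets[[nm]], te$gene_id)
    n <- length(members)
    if (n == 0L) { droppedSets <- c(droppedSets, nm); next }
    k <- length(intersect(members, sigGenes))
    p <- if (mode == "hypergeometric") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      inSet <- lfc[members]
      outSet <- lfc[setdiff(te$gene_id, members)]
      if (!length(outSet)) 1 else .wilcoxonRankSum(inSet, outSet)$p
    }
    ml <- mean(lfc[members], na.rm = TRUE)
    dir <- if (ml < 0) -1L else 1L
    rows[[nm]] <- data.frame(
      set_name = nm, size = n, n_sig = k, p_value = p, mean_lfc = ml,
      direction = dir,
      combined_score = if (n > 5L) -log10(p) * dir else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(droppedSets))
    warning(length(droppedSets), " set(s) with no universe members dropped")
  if (!length(rows))
    return(data.frame(set_name = character(), size = integer(),
                      n_sig = integer(), p_value = numeric(),
                      mean_lfc = numeric(), direction = integer(),
                      combined_score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$p_value), , drop = FALSE]
}

#' Connections per gene
#'
#' The gene's edge count divided by the total number of network edges;
#' genes absent from the network get 0.
#'
#' @param network A [NetworkGraph-class].
#' @param genes character vector of gene ids.
#' @return named numeric vector in \[0, 1\].
#' @export
connectionsPerGene <- function(network, genes) {
  e <- network@edges
  if (!nrow(e)) stop("empty network")
  deg <- table(c(e$a, e$b))
  out <- setNames(numeric(length(genes)), genes)
  hit <- genes %in% names(deg)
  out[hit] <- as.numeric(deg[genes[hit]]) / nrow(e)
  out
}

#' Importance score S: rank genes by combined evidence
#'
#' Combines the TE evidence, the evidence of the gene's most significant
#' containing pathway, the TE effect size and the gene's network
#' connectivity:
#' \deqn{S = -\log_{10} p_{TE} + (-\log_{10} p_{pathway}) \times |log2FC_{TE}| \times c_g}
#' where `c_g` is the gene's connections-per-gene. Genes in no significant
#' pathway take `p_pathway = 1`, so the pathway term vanishes. The
#' `"literal"` mode instead evaluates the product term with the signed
#' log2FC (`S = -log10 p_TE - log10(p_pathway) * log2FC * c_g`).
#'
#' @param teResults classified TE results.
#' @param pathwayStats data.frame from [geneSetEnrichment()].
#' @param sets the [GeneSetCollection-class] used for enrichment.
#' @param network A [NetworkGraph-class].
#' @param mode `"monotone"` (default) or `"literal"`.
#' @param pathwayAlpha significance level defining "significant pathway".
#' @return data.frame sorted by `S` descending (ties by gene id):
#'   `gene_id`, `p_te`, `te_lfc`, `p_pathway`, `pathway`, `c_g`, `S`.
#' @export
importanceScore <- function(teResults, pathwayStats, sets, network,
                            mode = c("monotone", "literal"),
                            pathwayAlpha = 0.05) {
  mode <- match.arg(mode)
  if (any(teResults$p_value <= 0, na.rm = TRUE))
    stop("non-positive p-values in teResults")
  cg <- connectionsPerGene(network, teResults$gene_id)
  sig <- pathwayStats[pathwayStats$p_value < pathwayAlpha, , drop = FALSE]
  pPath <- setNames(rep(1, nrow(teResults)), teResults$gene_id)
  bestPath <- setNames(rep(NA_character_, nrow(teResults)),
                       teResults$gene_id)
  if (nrow(sig)) {
    for (i in order(sig$p_value, decreasing = TRUE)) {
      members <- intersect(sets@sets[[sig$set_name[i]]], teResults$gene_id)
      pPath[members] <- sig$p_value[i]
      bestPath[members] <- sig$set_name[i]
    }
  }
  lfc <- teResults$te_lfc
  pte <- teResults$p_value
  S <- if (mode == "monotone") {
    -log10(pte) + (-log10(pPath)) * abs(lfc) * cg
  } else {
    -log10(pte) - log10(pPath) * lfc * cg
  }
  out <- data.frame(gene_id = teResults$gene_id, p_te = pte,
                    te_lfc = lfc, p_pathway = unname(pPath),
                    pathway = unname(bestPath), c_g = unname(cg), S = S,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$S, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
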