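## Gene-level counting with the abundance/biotype filters, and differential
## translation efficiency via a negative binomial interaction model:
## TE log2FC is the modality x condition interaction, so transcriptional
## change is removed from the ribosome-footprint change.

#' Count reads per gene and apply the abundance and biotype filters
#'
#' Ribosome counts are the total P-sites per transcript, summed to genes;
#' RNA counts are supplied as a gene x sample matrix. A gene is eliminated
#' when its per-sample mean total is below `minReads` (strict `< minReads`)
#' in either modality, or when its biotype is excluded (non-coding classes
#' are removed before testing). Exclusion reasons are recorded.
#'
#' @param riboTrackSets list of [PsiteTrackSet-class], one per ribosome
#'   sample.
#' @param rnaCounts gene x sample integer matrix.
#' @param index A [TranscriptomeIndex-class].
#' @param minReads abundance threshold (default 10).
#' @param excludedBiotypes biotypes removed before testing.
#' @return list with `ribo` (gene x sample matrix), `rna` (subset of
#'   `rnaCounts` on the same genes), `excluded` (data.frame `gene_id`,
#'   `reason`).
#' @export
countAndFilter <- function(riboTrackSets, rnaCounts, index, minReads = 10,
                           excludedBiotypes = c("rRNA", "tRNA", "miRNA",
                                                "snoRNA", "lncRNA",
                                                "ncRNA", "misc_RNA")) {
  anno <- index@anno
  geneOf <- setNames(anno$gene_id, anno$transcript_id)
  riboTx <- vapply(riboTrackSets,
                   function(ts) vapply(ts@tracks, sum, numeric(1)),
                   numeric(nrow(anno)))
  if (is.null(dim(riboTx))) riboTx <- matrix(riboTx, nrow = nrow(anno))
  colnames(riboTx) <- vapply(riboTrackSets, function(ts) ts@sampleId, "")
  ribo <- rowsum(riboTx, geneOf[rownames(riboTx)])

  genes <- intersect(rownames(ribo), rownames(rnaCounts))
  if (!length(genes)) stop("no genes shared between ribo and rna data")
  ribo <- ribo[genes, , drop = FALSE]
  rna <- rnaCounts[genes, , drop = FALSE]

  biotypeOf <- vapply(index@geneMap[genes], function(txs)
    anno$biotype[match(txs[1], anno$transcript_id)], "")

  excluded <- data.frame(gene_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  bad <- biotypeOf %in% excludedBiotypes
  lowRibo <- !bad & rowMeans(ribo) < minReads
  lowRna <- !bad & !lowRibo & rowMeans(rna) < minReads
  addEx <- function(sel, reason)
    if (any(sel)) data.frame(gene_id = genes[sel], reason = reason,
                             stringsAsFactors = FALSE)
  excluded <- do.call(rbind, c(list(excluded),
                               Filter(Negate(is.null),
                                      list(addEx(bad, "excluded_biotype"),
                                           addEx(lowRibo, "low_ribo"),
                                           addEx(lowRna, "low_rna")))))
  keep <- !(bad | lowRibo | lowRna)
  if (!any(keep))
    stop("all genes filtered out (", nrow(excluded), " exclusions: ",
         paste(unique(excluded$reason), collapse = ", "), ")")
  list(ribo = ribo[keep, , drop = FALSE], rna = rna[keep, , drop = FALSE],
       excluded = excluded)
}

# DESeq-style median-of-ratios size factors for one modality
.sizeFactors <- function(m) {
  lg <- rowMeans(log(m))
  use <- is.finite(lg)
  if (!any(use)) return(setNames(rep(1, ncol(m)), colnames(m)))
  apply(m, 2, function(col) exp(stats::median(log(col[use]) - lg[use])))
}

#' Differential translation efficiency (NB interaction model)
#'
#' Normalizes each modality's libraries by median-of-ratios, estimates a
#' per-gene negative binomial dispersion by the method of moments (floored
#' at 1e-4), and fits one NB GLM per gene:
#' `count ~ modality * condition + offset(log sizeFactor)`. The TE log2
#' fold change is the modality x condition interaction divided by log(2) -
#' equivalently the ribosome-footprint condition log2FC minus the RNA
#' condition log2FC. The Wald statistic of the interaction is referred to a
#' t distribution on the residual degrees of freedom, and q-values are
#' Benjamini-Hochberg.
#'
#' @param ribo,rna gene x sample count matrices from [countAndFilter()].
#' @param design data.frame with columns `sample_id`, `modality`,
#'   `condition` covering all columns of both matrices.
#' @param reference reference condition (default: first in `design`).
#' @return data.frame: `gene_id`, `rna_lfc`, `ribo_lfc`, `te_lfc`,
#'   `p_value`, `q_value`; attribute `"excluded"` lists genes with a whole
#'   modality at zero (TE undefined).
#' @export
differentialTE <- function(ribo, rna, design, reference = NULL) {
  stopifnot(all(colnames(ribo) %in% design$sample_id),
            all(colnames(rna) %in% design$sample_id))
  cond <- setNames(design$condition, design$sample_id)
  if (is.null(reference)) reference <- design$condition[1]
  lev <- c(reference, setdiff(unique(design$condition), reference))
  if (length(lev) != 2L) stop("exactly two conditions required")
  for (cc in lev)
    if (sum(cond[colnames(ribo)] == cc) < 2L ||
        sum(cond[colnames(rna)] == cc) < 2L)
      stop("need >= 2 replicates per condition per modality")

  sfRibo <- .sizeFactors(ribo)
  sfRna <- .sizeFactors(rna)
  y <- cbind(ribo, rna)
  sf <- c(sfRibo, sfRna)
  mod <- factor(rep(c("ribo", "rna"), c(ncol(ribo), ncol(rna))),
                levels = c("rna", "ribo"))
  cnd <- factor(cond[colnames(y)], levels = lev)
  X <- stats::model.matrix(~ mod * cnd)
  offs <- log(sf)
  dfResid <- ncol(y) - ncol(X)

  # per-gene method-of-moments dispersion on normalized counts, averaged
  # over the four modality x condition groups, floored at 1e-4
  norm <- sweep(y, 2, sf, "/")
  grp <- interaction(mod, cnd)
  disp <- apply(norm, 1, function(v) {
    ests <- tapply(v, grp, function(g) {
      m <- mean(g)
      if (m <= 0 || length(g) < 2) return(NA_real_)
      (stats::var(g) - m) / m^2
    })
    d <- mean(ests, na.rm = TRUE)
    if (!is.finite(d)) d <- 0
    min(max(d, 1e-4), 10)
  })

  genes <- rownames(y)
  res <- data.frame(gene_id = genes, rna_lfc = NA_real_,
                    ribo_lfc = NA_real_, te_lfc = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    stringsAsFactors = FALSE)
  zeroRibo <- rowSums(ribo) == 0
  zeroRna <- rowSums(rna) == 0
  excluded <- data.frame(
    gene_id = genes[zeroRibo | zeroRna],
    reason = ifelse(zeroRibo[zeroRibo | zeroRna], "zero_ribo", "zero_rna"),
    stringsAsFactors = FALSE)

  iInt <- ncol(X)                 # interaction coefficient
  iCnd <- grep("^cnd", colnames(X))[1]
  for (g in which(!(zeroRibo | zeroRna))) {
    fit <- suppressWarnings(
      stats::glm.fit(X, y[g, ], offset = offs,
                     family = MASS::negative.binomial(theta = 1 / disp[g])))
    beta <- fit$coefficients
    R <- qr.R(fit$qr)
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(cov) || anyNA(beta)) next
    se <- sqrt(diag(cov))
    res$rna_lfc[g] <- beta[iCnd] / log(2)
    res$te_lfc[g] <- beta[iInt] / log(2)
    res$ribo_lfc[g] <- res$rna_lfc[g] + res$te_lfc[g]
    tstat <- beta[iInt] / se[iInt]
    res$p_value[g] <- 2 * stats::pt(-abs(tstat), df = dfResid)
  }
  res <- res[!(zeroRibo | zeroRna), , drop = FALSE]
  res$p_value[res$p_value <= 0 & !is.na(res$p_value)] <- .Machine$double.xmin
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Classify TE results with the printed cutoffs
#'
#' A gene is significant when `p < pCut` and `|te_lfc| >= lfcCut`
#' (defaults: p < 0.05 and |log2FC| >= 0.65). The summary reports what
#' fraction of significant genes are under- vs over-translated.
#'
#' @param results data.frame from [differentialTE()].
#' @param pCut,lfcCut the cutoffs.
#' @return The results with `significant` and `direction` columns; the
#'   attribute `"summary"` holds `n_significant`, `frac_up`, `frac_down`.
#' @export
classifyTE <- function(results, pCut = 0.05, lfcCut = 0.65) {
  sig <- !is.na(results$p_value) & results$p_value < pCut &
    abs(results$te_lfc) >= lfcCut
  results$significant <- sig
  results$direction <- ifelse(!sig, "none",
                              ifelse(results$te_lfc > 0, "up", "down"))
  nSig <- sum(sig)
  attr(results, "summary") <- c(
    n_significant = nSig,
    frac_up = if (nSig) sum(results$direction == "up") / nSig else NA_real_,
    frac_down = if (nSig) sum(results$direction == "down") / nSig
                else NA_real_)
  results
}
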