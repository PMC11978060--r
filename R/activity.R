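#' Median-of-ratios size factors for a promoter count matrix
#'
#' Per-sample normalization factors computed with the DESeq2
#' median-of-ratios estimator on the quantifiable promoters: the reference
#' is the per-promoter geometric mean across samples (promoters with any
#' zero count are excluded from the reference set) and each sample's factor
#' is the median count/reference ratio.
#'
#' @param counts a `SummarizedExperiment` from [countPromoterReads()] or a
#'   numeric count matrix (promoters x samples; `NA` rows are ignored).
#' @param fallback `"none"` (error when no promoter is positive in every
#'   sample) or `"poscounts"` (geometric means over positive counts only,
#'   for sparse matrices).
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 40, 20, 40, 80), nrow = 3)
#' promoterSizeFactors(m)  # c(1, 2) / sqrt(2)
#' @export
promoterSizeFactors <- function(counts, fallback = c("none", "poscounts")) {
  fallback <- match.arg(fallback)
  m <- if (methods::is(counts, "SummarizedExperiment")) {
    SummarizedExperiment::assay(counts, "counts")
  } else as.matrix(counts)
  if (ncol(m) < 2L) stop("size factors need at least 2 samples")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!nrow(m)) stop("no quantifiable promoters with complete counts")
  allPos <- rowSums(m > 0) == ncol(m)
  if (!any(allPos) && fallback == "none") {
    stop("no promoter has positive counts in every sample; ",
         "consider fallback = \"poscounts\" (pseudo-reference over ",
         "positive counts)")
  }
  if (fallback == "poscounts" && !any(allPos)) {
    lm0 <- log(m)
    lm0[!is.finite(lm0)] <- NA
    geo <- exp(rowMeans(lm0, na.rm = TRUE)) *
      rowMeans(m > 0)  # damp promoters observed in few samples
    sf <- DESeq2::estimateSizeFactorsForMatrix(m, geoMeans = geo)
  } else {
    sf <- DESeq2::estimateSizeFactorsForMatrix(m)
  }
  sf
}

#' Absolute and relative promoter activity
#'
#' Computes, per promoter and sample: normalized counts `count / sizeFactor`,
#' absolute activity `log2(normalized + 1)`, and relative activity
#' (the promoter's fraction of its gene's total normalized count; `NA` when
#' the gene total is zero). Gene expression is `log2(1 + sum of normalized
#' linear counts over the gene's quantifiable promoters)` and is stored in
#' `metadata(.)$geneExpression` (genes x samples; linear totals in
#' `metadata(.)$geneTotals`). Non-quantifiable promoters stay `NA`
#' throughout.
#'
#' @param se `SummarizedExperiment` from [countPromoterReads()].
#' @param sizeFactors optional precomputed factors; default
#'   [promoterSizeFactors()] on `se`.
#' @param fallback passed to [promoterSizeFactors()].
#' @return `se` with added assays `absolute` and `relative`, a
#'   `sizeFactor` column in `colData`, and gene-level matrices in
#'   `metadata`.
#' @export
promoterActivity <- function(se, sizeFactors = NULL,
                             fallback = c("none", "poscounts")) {
  m <- SummarizedExperiment::assay(se, "counts")
  if (is.null(sizeFactors)) {
    sizeFactors <- promoterSizeFactors(se, fallback = match.arg(fallback))
  }
  if (length(sizeFactors) != ncol(m)) {
    stop("sizeFactors length does not match sample count")
  }
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  norm <- sweep(m, 2L, sizeFactors, "/")
  absolute <- log2(norm + 1)

  rd <- SummarizedExperiment::rowData(se)
  q <- rd$quantifiable
  gene <- rd$gene_id
  normQ <- norm[q, , drop = FALSE]
  geneTotals <- rowsum(normQ, gene[q])
  geneExpr <- log2(1 + geneTotals)

  totalsPerRow <- geneTotals[match(gene, rownames(geneTotals)), ,
                             drop = FALSE]
  relative <- norm / totalsPerRow
  relative[!is.finite(relative)] <- NA  # gene total 0 -> undefined
  relative[!q, ] <- NA

  SummarizedExperiment::assays(se)[["absolute"]] <- absolute
  SummarizedExperiment::assays(se)[["relative"]] <- relative
  SummarizedExperiment::colData(se)$sizeFactor <- unname(sizeFactors)
  S4Vectors::metadata(se)$geneExpression <- geneExpr
  S4Vectors::metadata(se)$geneTotals <- geneTotals
  se
}

#' Accessor for the gene-expression matrix of an activity object
#'
#' @param se `SummarizedExperiment` returned by [promoterActivity()].
#' @return genes x samples matrix of `log2(1 + total normalized counts)`.
#' @export
geneExpression <- function(se) {
  ge <- S4Vectors::metadata(se)$geneExpression
  if (is.null(ge)) stop("no gene expression; run promoterActivity() first")
  ge
}

#' Classify promoters as major, minor/alternative or inactive
#'
#' Mean absolute activity is taken across all samples. Promoters with mean
#' activity below `inactiveThreshold` are inactive. Among each gene's
#' promoters, the one with the highest mean activity is the major promoter
#' provided that maximum is at least the threshold (ties broken toward the
#' 5'-most promoter, i.e. lowest TSS rank); remaining non-inactive
#' promoters are minor/alternative. Only quantifiable promoters are
#' classified.
#'
#' @param se activity object from [promoterActivity()].
#' @param inactiveThreshold log2-scale activity cutoff (default 0.25).
#' @return data.frame `promoter_id`, `gene_id`, `tss_rank`,
#'   `mean_activity`, `mean_relative`, `label`.
#' @export
classifyPromoters <- function(se, inactiveThreshold = 0.25) {
  rd <- SummarizedExperiment::rowData(se)
  q <- rd$quantifiable
  absolute <- SummarizedExperiment::assay(se, "absolute")[q, , drop = FALSE]
  relative <- SummarizedExperiment::assay(se, "relative")[q, , drop = FALSE]
  out <- data.frame(
    promoter_id = rd$promoter_id[q], gene_id = rd$gene_id[q],
    tss_rank = rd$tss_rank[q],
    mean_activity = rowMeans(absolute, na.rm = TRUE),
    mean_relative = rowMeans(relative, na.rm = TRUE),
    stringsAsFactors = FALSE)
  out$mean_relative[is.nan(out$mean_relative)] <- NA
  out$label <- ifelse(out$mean_activity < inactiveThreshold, "inactive",
                      "minor")
  # one major per gene when its top mean activity reaches the threshold;
  # ties at the maximum go to the lowest tss_rank
  ord <- order(out$gene_id, -out$mean_activity, out$tss_rank)
  o <- out[ord, ]
  topOfGene <- !duplicated(o$gene_id)
  major <- o$promoter_id[topOfGene & o$mean_activity >= inactiveThreshold]
  out$label[out$promoter_id %in% major] <- "major"
  rownames(out) <- NULL
  out
}

#' Genes driven by multiple active promoters
#'
#' Returns genes with at least two non-inactive promoters whose mean
#' relative activity each exceeds `contribution` of the gene's total
#' expression.
#'
#' @param classes classification table from [classifyPromoters()].
#' @param contribution minimum mean fractional contribution (default 0.10).
#' @return character vector of gene identifiers.
#' @export
multiActiveGenes <- function(classes, contribution = 0.10) {
  hit <- classes$label != "inactive" &
    !is.na(classes$mean_relative) & classes$mean_relative > contribution
  n <- table(classes$gene_id[hit])
  sort(names(n)[n >= 2L])
}

#' Promoters ranked by across-sample activity variance
#'
#' @param se activity object from [promoterActivity()].
#' @param n number of top-variance promoters to return (all, with a
#'   warning, when `n` exceeds the number of quantifiable promoters).
#' @return data.frame `promoter_id`, `variance`, sorted descending.
#' @export
topVariancePromoters <- function(se, n) {
  rd <- SummarizedExperiment::rowData(se)
  absolute <- SummarizedExperiment::assay(se, "absolute")
  absolute <- absolute[rd$quantifiable, , drop = FALSE]
  if (ncol(absolute) < 2L) stop("variance ranking needs at least 2 samples")
  v <- apply(absolute, 1L, stats::var, na.rm = TRUE)
  if (n > length(v)) {
    warning("n = ", n, " exceeds the ", length(v),
            " quantifiable promoters; returning all")
    n <- length(v)
  }
  ord <- order(-v, names(v))
  out <- data.frame(promoter_id = names(v)[ord], variance = unname(v[ord]),
                    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
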