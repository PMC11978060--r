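#' Eight-category taxonomy of paired promoter dynamics
#'
#' Maps a (major trend, minor trend) pair to one of the eight switching
#' categories: `Up_Up`, `Up_Flat`, `Flat_Up`, `Down_Down`, `Down_Flat`,
#' `Flat_Down`, `Up_Down`, `Down_Up` — or `Unclassified` when both
#' promoters are flat (no DDP in the pair). Vectorized.
#'
#' @param major,minor character vectors in `c("Up", "Down", "Flat")`.
#' @return character vector of categories.
#' @examples
#' pairCategory("Up", "Down")   # antagonistic switch
#' pairCategory("Flat", "Flat") # no dynamic promoter in the pair
#' @export
pairCategory <- function(major, minor) {
  ok <- c("Up", "Down", "Flat")
  if (!all(major %in% ok) || !all(minor %in% ok)) {
    stop("trends must be one of ", paste(ok, collapse = ", "))
  }
  ifelse(major == "Flat" & minor == "Flat", "Unclassified",
         paste(major, minor, sep = "_"))
}

#' @rdname pairCategory
#' @format NULL
#' @export
PAIR_CATEGORIES <- c("Up_Up", "Up_Flat", "Flat_Up", "Down_Down",
                     "Down_Flat", "Flat_Down", "Up_Down", "Down_Up",
                     "Unclassified")

# gene-level trend each pair category is expected to accompany
.expectedGeneTrend <- c(
  Up_Up = "Up", Up_Flat = "Up", Flat_Up = "Up",
  Down_Down = "Down", Down_Flat = "Down", Flat_Down = "Down",
  Up_Down = "Flat", Down_Up = "Flat", Unclassified = "Flat")

#' Gene-level temporal trends
#'
#' Applies the same machinery as promoter DDP calling (cubic fit, BH FDR,
#' R-squared cutoff, fitted endpoint sign) to the gene expression matrix,
#' classifying genes as upregulated, downregulated or unchanged
#' (`Up`/`Down`/`Flat`).
#'
#' @param geneExpr genes x samples matrix (one organ), e.g. organ columns
#'   of [geneExpression()].
#' @param times numeric time per sample.
#' @param degree,alpha,r2Min see [fitPromoterTrends()] and [callDdps()].
#' @return [callDdps()]-style table with a `gene_id` column.
#' @export
geneTrends <- function(geneExpr, times, degree = 3L, alpha = 0.05,
                       r2Min = 0.3) {
  fits <- fitPromoterTrends(geneExpr, times, degree = degree)
  calls <- callDdps(fits, alpha = alpha, r2Min = r2Min)
  names(calls)[names(calls) == "promoter_id"] <- "gene_id"
  calls
}

#' Pair major and minor promoters and assign switching categories
#'
#' Pairs each gene's major promoter with every non-inactive minor promoter
#' and assigns the eight-category taxonomy from the two DDP trend
#' directions. Promoters absent from `promoterCalls` (skipped fits) count
#' as `Flat`. When gene-level calls are supplied, each pair carries the
#' gene trend and a consistency flag (whether the observed gene trend
#' matches the trend its category implies: `Up_*` categories with gene
#' `Up`, `Down_*` with gene `Down`, antagonistic and unclassified pairs
#' with gene `Flat`); incoherent combinations are flagged, never
#' reassigned.
#'
#' @param classes classification table from [classifyPromoters()].
#' @param promoterCalls [callDdps()] table for one organ.
#' @param geneCalls optional [geneTrends()] table for the same organ.
#' @return data.frame with one row per major-minor pair: `gene_id`,
#'   `major_promoter_id`, `minor_promoter_id`, `major_trend`,
#'   `minor_trend`, `category`, `gene_trend`, `consistent`.
#' @export
classifyPromoterPairs <- function(classes, promoterCalls, geneCalls = NULL) {
  trendOf <- function(ids) {
    d <- promoterCalls$direction[match(ids, promoterCalls$promoter_id)]
    ifelse(is.na(d), "Flat", d)
  }
  majors <- classes[classes$label == "major", , drop = FALSE]
  minors <- classes[classes$label == "minor", , drop = FALSE]
  minors <- minors[minors$gene_id %in% majors$gene_id, , drop = FALSE]
  if (!nrow(minors)) {
    return(data.frame(gene_id = character(), major_promoter_id = character(),
                      minor_promoter_id = character(),
                      major_trend = character(), minor_trend = character(),
                      category = character(), gene_trend = character(),
                      consistent = logical(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    gene_id = minors$gene_id,
    major_promoter_id = majors$promoter_id[match(minors$gene_id,
                                                 majors$gene_id)],
    minor_promoter_id = minors$promoter_id,
    stringsAsFactors = FALSE)
  out$major_trend <- trendOf(out$major_promoter_id)
  out$minor_trend <- trendOf(out$minor_promoter_id)
  out$category <- pairCategory(out$major_trend, out$minor_trend)
  if (!is.null(geneCalls)) {
    g <- geneCalls$direction[match(out$gene_id, geneCalls$gene_id)]
    out$gene_trend <- ifelse(is.na(g), "Flat", g)
    out$consistent <- out$gene_trend ==
      unname(.expectedGeneTrend[out$category])
  } else {
    out$gene_trend <- NA_character_
    out$consistent <- NA
  }
  ord <- order(out$gene_id, out$minor_promoter_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count pairs and genes per switching category
#'
#' Pair-level counts tally every major-minor pair; gene-level counts tally
#' distinct genes per category (a gene with several minors can contribute
#' to different categories).
#'
#' @param calls pair table from [classifyPromoterPairs()].
#' @return data.frame `category`, `n_pairs`, `n_genes` covering all nine
#'   categories (zeros included).
#' @export
aggregateCategories <- function(calls) {
  cat <- factor(calls$category, levels = PAIR_CATEGORIES)
  nPairs <- table(cat)
  nGenes <- vapply(PAIR_CATEGORIES, function(k) {
    length(unique(calls$gene_id[calls$category == k]))
  }, integer(1L))
  data.frame(category = PAIR_CATEGORIES,
             n_pairs = as.integer(nPairs[PAIR_CATEGORIES]),
             n_genes = unname(nGenes), stringsAsFactors = FALSE)
}

#' Mean relative major and minor promoter usage per stage
#'
#' For each stage, the mean over genes (and replicates) of the major
#' promoter's relative activity and of the summed relative activity of all
#' other quantifiable promoters of the gene. The two means sum to 1 at
#' every stage, since per gene-sample the fractions partition the gene's
#' expression. Restricted to genes with at least two quantifiable
#' promoters; gene-samples with zero total expression (undefined
#' fractions) are excluded.
#'
#' @param se activity object from [promoterActivity()].
#' @param classes classification table from [classifyPromoters()].
#' @param design design rows matching the columns of `se` (needs
#'   `stage_label`, `time_ordinal`).
#' @param genes optional gene subset (default: all genes with >= 2
#'   quantifiable promoters and a major promoter).
#' @return data.frame `stage_label`, `time_ordinal`, `major_mean`,
#'   `minor_mean`, `n_gene_samples`; zero rows when no gene qualifies.
#' @export
relativeUsageTrajectory <- function(se, classes, design, genes = NULL) {
  rel <- SummarizedExperiment::assay(se, "relative")
  nProm <- table(classes$gene_id)
  elig <- names(nProm)[nProm >= 2L]
  elig <- intersect(elig,
                    classes$gene_id[classes$label == "major"])
  if (!is.null(genes)) elig <- intersect(elig, genes)
  out <- data.frame(stage_label = character(), time_ordinal = numeric(),
                    major_mean = numeric(), minor_mean = numeric(),
                    n_gene_samples = integer(), stringsAsFactors = FALSE)
  if (!length(elig)) return(out)
  majors <- classes$promoter_id[classes$label == "major" &
                                  classes$gene_id %in% elig]
  geneOf <- classes$gene_id[match(majors, classes$promoter_id)]
  majRel <- rel[majors, , drop = FALSE]  # genes x samples, may be NA
  stageKey <- unique(design[, c("stage_label", "time_ordinal")])
  stageKey <- stageKey[order(stageKey$time_ordinal), , drop = FALSE]
  for (i in seq_len(nrow(stageKey))) {
    cols <- which(design$stage_label == stageKey$stage_label[i])
    v <- as.vector(majRel[, cols, drop = FALSE])
    v <- v[!is.na(v)]
    out <- rbind(out, data.frame(
      stage_label = stageKey$stage_label[i],
      time_ordinal = stageKey$time_ordinal[i],
      major_mean = mean(v), minor_mean = mean(1 - v),
      n_gene_samples = length(v), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Fraction of protein-coding transcripts from minor promoters
#'
#' Per switching category, the fraction of member transcripts of the
#' category's minor promoters annotated as `protein_coding`.
#'
#' @param catalog a [PromoterCatalog-class] (provides transcript biotypes).
#' @param calls pair table from [classifyPromoterPairs()].
#' @return data.frame `category`, `n_transcripts`, `coding_fraction`
#'   (`NA` for categories without minor-promoter transcripts).
#' @export
codingFraction <- function(catalog, calls) {
  tm <- transcriptMap(catalog)
  res <- lapply(PAIR_CATEGORIES, function(k) {
    minors <- unique(calls$minor_promoter_id[calls$category == k])
    tr <- tm[tm$promoter_id %in% minors, , drop = FALSE]
    data.frame(category = k, n_transcripts = nrow(tr),
               coding_fraction = if (nrow(tr)) {
                 mean(tr$biotype == "protein_coding")
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
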