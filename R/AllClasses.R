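#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps reduce strand start end
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols queryHits subjectHits DataFrame metadata
NULL

#' PromoterCatalog: promoters inferred from overlapping first exons
#'
#' A catalog groups every transcript of a gene into promoters: transcripts
#' whose first exons overlap by at least one base (single-linkage closure)
#' share a promoter, and the promoter TSS is the 5'-most member TSS. Each
#' promoter carries the union span of its member first exons, its 5'-to-3'
#' rank within the gene, an internal flag (first-exon span overlaps a
#' non-first exon of the same gene), and the first-intron junctions of its
#' member transcripts.
#'
#' @slot promoters [GenomicRanges::GRanges] of first-exon spans with metadata
#'   columns `promoter_id`, `gene_id`, `tss`, `tss_rank`, `internal`,
#'   `n_transcripts`.
#' @slot transcripts data.frame mapping `transcript_id` to `gene_id`,
#'   `promoter_id`, `biotype` and `n_exons`; every transcript of a gene maps
#'   to exactly one promoter.
#' @slot junctions data.frame of first-intron junctions (`promoter_id`,
#'   `gene_id`, `chrom`, `intron_start`, `intron_end`, `strand`), 1-based
#'   inclusive intron coordinates.
#'
#' @seealso [buildPromoterCatalog()], [flagInternalPromoters()],
#'   [junctionIndex()]
#' @export
setClass("PromoterCatalog",
  slots = c(
    promoters   = "GRanges",
    transcripts = "data.frame",
    junctions   = "data.frame"
  )
)

setValidity("PromoterCatalog", function(object) {
  p <- object@promoters
  need <- c("promoter_id", "gene_id", "tss", "tss_rank", "internal",
            "n_transcripts")
  miss <- setdiff(need, colnames(S4Vectors::mcols(p)))
  if (length(miss)) {
    return(paste("missing promoter metadata columns:",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(p$promoter_id)) return("duplicated promoter_id")
  if (length(p)) {
    # tss within first-exon span
    if (any(p$tss < GenomicRanges::start(p) | p$tss > GenomicRanges::end(p))) {
      return("tss outside first-exon span")
    }
    # ranks are 1..K without gaps within each gene
    byGene <- split(p$tss_rank, p$gene_id)
    ok <- vapply(byGene, function(r) identical(sort(r), seq_along(r)),
                 logical(1L))
    if (!all(ok)) return("tss_rank not contiguous 1..K within a gene")
  }
  tr <- object@transcripts
  if (nrow(tr)) {
    if (anyDuplicated(tr$transcript_id)) {
      return("a transcript maps to more than one promoter")
    }
    if (!all(tr$promoter_id %in% p$promoter_id)) {
      return("transcript mapped to unknown promoter")
    }
    # partition: per-promoter membership sums to the gene's transcript count
    nt <- table(tr$promoter_id)[p$promoter_id]
    nt[is.na(nt)] <- 0L
    if (!all(as.integer(nt) == p$n_transcripts)) {
      return("n_transcripts inconsistent with transcript map")
    }
  }
  TRUE
})

#' @describeIn PromoterCatalog number of promoters in the catalog
#' @param x a `PromoterCatalog`
#' @export
setMethod("length", "PromoterCatalog", function(x) length(x@promoters))

#' Accessors for PromoterCatalog
#'
#' `promoterRanges()` returns the promoter-level GRanges (first-exon spans
#' with TSS, rank, internal flag), `transcriptMap()` the transcript-to-
#' promoter assignment, and `promoterJunctions()` the table of first-intron
#' junctions.
#'
#' @param object a `PromoterCatalog`
#' @return a `GRanges` or data.frame (see above)
#' @export
setGeneric("promoterRanges", function(object) standardGeneric("promoterRanges"))

#' @rdname promoterRanges
#' @export
setGeneric("transcriptMap", function(object) standardGeneric("transcriptMap"))

#' @rdname promoterRanges
#' @export
setGeneric("promoterJunctions",
           function(object) standardGeneric("promoterJunctions"))

#' @rdname promoterRanges
#' @export
setMethod("promoterRanges", "PromoterCatalog", function(object) {
  object@promoters
})

#' @rdname promoterRanges
#' @export
setMethod("transcriptMap", "PromoterCatalog", function(object) {
  object@transcripts
})

#' @rdname promoterRanges
#' @export
setMethod("promoterJunctions", "PromoterCatalog", function(object) {
  object@junctions
})

setMethod("show", "PromoterCatalog", function(object) {
  p <- object@promoters
  cat("PromoterCatalog with", length(p), "promoters for",
      length(unique(p$gene_id)), "genes\n")
  if (length(p)) {
    cat("  internal promoters:", sum(p$internal), "\n")
    cat("  transcripts mapped:", nrow(object@transcripts), "\n")
    cat("  first-intron junctions:", nrow(object@junctions), "\n")
  }
  invisible(NULL)
})
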