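#' Read transcript models from a GTF annotation
#'
#' Parses `exon` features of an Ensembl-dialect GTF (attributes `gene_id`,
#' `transcript_id`, optionally `transcript_biotype`) into a long-format
#' transcript model table, one row per exon. Coordinates are kept 1-based
#' inclusive as in the GTF. Exons are sorted by genomic coordinate within
#' each transcript; the first exon in transcription order is the
#' lowest-coordinate exon on `+` and the highest-coordinate exon on `-`.
#'
#' @param path path to a GTF file.
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype` (from `transcript_biotype`, or
#'   `"unknown"` when absent).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "100", "200", ".", "+", ".",
#'   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' readTranscriptModels(gtf)
#' @export
readTranscriptModels <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  emptyModel <- data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    biotype = character(), stringsAsFactors = FALSE)
  if (!any(body)) return(emptyModel)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(nfield < 9L)) {
    bad <- which(body)[which(nfield < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path,
         " (expected 9 tab-separated fields)")
  }

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  ex <- gr[mc$type == "exon"]
  if (!length(ex)) return(emptyModel)
  exm <- S4Vectors::mcols(ex)
  bt <- if ("transcript_biotype" %in% colnames(exm)) {
    ifelse(is.na(exm$transcript_biotype), "unknown",
           as.character(exm$transcript_biotype))
  } else rep("unknown", length(ex))
  out <- data.frame(
    transcript_id = as.character(exm$transcript_id),
    gene_id = as.character(exm$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    biotype = bt,
    stringsAsFactors = FALSE)
  if (any(!out$strand %in% c("+", "-"))) {
    stop("exon with undefined strand in ", path)
  }

  # transcripts declared but with zero exon features are excluded with warning
  declared <- unique(as.character(mc$transcript_id[mc$type == "transcript"]))
  declared <- declared[!is.na(declared)]
  zero <- setdiff(declared, unique(out$transcript_id))
  if (length(zero)) {
    warning("excluding ", length(zero),
            " transcript(s) with zero exons: ",
            paste(utils::head(zero, 5L), collapse = ", "))
  }
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# order exons of each transcript in transcription order and index them;
# returns data.table with exon_index (1 = first exon in transcription order)
.orderExons <- function(transcripts) {
  ex <- data.table::as.data.table(transcripts)
  ex[, `:=`(ord = ifelse(strand == "+", start, -start))]
  data.table::setorder(ex, transcript_id, ord)
  ex[, exon_index := seq_len(.N), by = transcript_id]
  ex[, ord := NULL]
  ex
}

#' Build a promoter catalog from transcript models
#'
#' Within each gene, transcripts whose first exons overlap by at least one
#' base are merged (single-linkage closure over pairwise overlaps) into one
#' promoter. The promoter TSS is the 5'-most member TSS (minimum first-exon
#' start on `+`, maximum first-exon end on `-`); promoters are ranked 1..K
#' from 5' to 3' in transcription order. Each member transcript with at
#' least two exons contributes its first-intron junction
#' (`upstream exon end + 1`, `downstream exon start - 1` in genomic
#' coordinates). Internal promoters (first-exon span overlapping a
#' non-first exon of the same gene) are flagged via
#' [flagInternalPromoters()].
#'
#' @param transcripts transcript model table from [readTranscriptModels()].
#' @param flagInternal flag internal promoters (default TRUE).
#' @return a [PromoterCatalog-class] object.
#' @export
buildPromoterCatalog <- function(transcripts, flagInternal = TRUE) {
  if (!nrow(transcripts)) {
    emptyGr <- GenomicRanges::GRanges()
    S4Vectors::mcols(emptyGr) <- S4Vectors::DataFrame(
      promoter_id = character(), gene_id = character(), tss = integer(),
      tss_rank = integer(), internal = logical(), n_transcripts = integer())
    cat0 <- methods::new("PromoterCatalog",
      promoters = emptyGr,
      transcripts = data.frame(transcript_id = character(),
        gene_id = character(), promoter_id = character(),
        biotype = character(), n_exons = integer(),
        stringsAsFactors = FALSE),
      junctions = .emptyJunctions())
    return(cat0)
  }
  ex <- .orderExons(transcripts)

  # all transcripts of a gene must share chromosome and strand
  cons <- ex[, list(nchr = length(unique(chrom)),
                    nstr = length(unique(strand))), by = gene_id]
  bad <- cons[nchr > 1L | nstr > 1L]
  if (nrow(bad)) {
    stop("gene(s) with transcripts on conflicting strand/chromosome: ",
         paste(utils::head(bad$gene_id, 5L), collapse = ", "))
  }

  first <- ex[exon_index == 1L]
  second <- ex[exon_index == 2L]
  first[, tss := ifelse(strand == "+", start, end)]
  nEx <- ex[, list(n_exons = .N), by = transcript_id]

  # single-linkage merge of overlapping first exons within each gene: reduce()
  # on per-gene coordinate space (reduced runs are gap-free unions of their
  # members, so this equals the transitive closure of pairwise >=1bp overlap)
  fgr <- GenomicRanges::GRanges(first$gene_id,
                                IRanges::IRanges(first$start, first$end))
  red <- GenomicRanges::reduce(fgr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(fgr, red)
  stopifnot(length(hit) == nrow(first))
  first[, group := S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]]

  prom <- first[, list(
    gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
    span_start = min(start), span_end = max(end),
    tss = if (strand[1L] == "+") min(tss) else max(tss),
    n_transcripts = .N), by = group]
  # rank 5'->3' in transcription order within each gene
  prom[, tss_rank := if (strand[1L] == "+") rank(tss, ties.method = "first")
       else rank(-tss, ties.method = "first"), by = gene_id]
  prom[, promoter_id := sprintf("%s_p%d", gene_id, tss_rank)]

  first[, promoter_id := prom$promoter_id[match(group, prom$group)]]
  trMap <- merge(
    first[, list(transcript_id, gene_id, promoter_id, biotype)],
    nEx, by = "transcript_id")
  trMap <- as.data.frame(trMap[order(transcript_id)])

  # first-intron junctions from (first exon, second exon) pairs
  jx <- .emptyJunctions()
  if (nrow(second)) {
    j <- merge(second[, list(transcript_id, chrom, strand,
                             e2_start = start, e2_end = end)],
               first[, list(transcript_id, promoter_id, gene_id,
                            e1_start = start, e1_end = end)],
               by = "transcript_id")
    j[, intron_start := ifelse(strand == "+", e1_end + 1L, e2_end + 1L)]
    j[, intron_end := ifelse(strand == "+", e2_start - 1L, e1_start - 1L)]
    jx <- unique(as.data.frame(
      j[, list(promoter_id, gene_id, chrom, intron_start, intron_end,
               strand)]))
    jx <- jx[order(jx$promoter_id, jx$intron_start), , drop = FALSE]
    rownames(jx) <- NULL
    if (any(jx$intron_start > jx$intron_end)) {
      stop("degenerate first intron (adjacent exons) in transcript model")
    }
  }

  prom <- prom[order(gene_id, tss_rank)]
  pgr <- GenomicRanges::GRanges(
    prom$chrom, IRanges::IRanges(prom$span_start, prom$span_end),
    strand = prom$strand,
    promoter_id = prom$promoter_id, gene_id = prom$gene_id,
    tss = as.integer(prom$tss), tss_rank = as.integer(prom$tss_rank),
    internal = rep(FALSE, nrow(prom)),
    n_transcripts = as.integer(prom$n_transcripts))
  names(pgr) <- prom$promoter_id

  catalog <- methods::new("PromoterCatalog", promoters = pgr,
                          transcripts = trMap, junctions = jx)
  if (flagInternal) catalog <- flagInternalPromoters(catalog, transcripts)
  catalog
}

.emptyJunctions <- function() {
  data.frame(promoter_id = character(), gene_id = character(),
             chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Flag internal promoters
#'
#' A promoter is internal when its first-exon span overlaps any non-first
#' exon (in transcription order) of any transcript of the same gene.
#' Internal promoters produce junction signal indistinguishable from
#' splicing of longer isoforms and are excluded from quantification
#' downstream.
#'
#' @param catalog a [PromoterCatalog-class].
#' @param transcripts the transcript model table the catalog was built from.
#' @return the catalog with the `internal` metadata column updated.
#' @export
flagInternalPromoters <- function(catalog, transcripts) {
  p <- catalog@promoters
  if (!length(p) || !nrow(transcripts)) return(catalog)
  ex <- .orderExons(transcripts)
  nonfirst <- ex[exon_index > 1L]
  if (!nrow(nonfirst)) {
    p$internal <- rep(FALSE, length(p))
  } else {
    # per-gene coordinate space so only same-gene exons are considered
    pg <- GenomicRanges::GRanges(
      p$gene_id,
      IRanges::IRanges(GenomicRanges::start(p), GenomicRanges::end(p)))
    ng <- GenomicRanges::GRanges(
      nonfirst$gene_id,
      IRanges::IRanges(nonfirst$start, nonfirst$end))
    p$internal <- IRanges::overlapsAny(pg, ng)
  }
  methods::initialize(catalog, promoters = p)
}

#' Export a promoter catalog
#'
#' Writes `promoters.tsv` (one row per promoter with its junction list) and
#' `promoter_tss.bed` (BED6, 0-based half-open, one record per promoter TSS)
#' into `dir`.
#'
#' @param catalog a [PromoterCatalog-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportCatalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- catalog@promoters
  jx <- catalog@junctions
  jlist <- vapply(p$promoter_id, function(id) {
    j <- jx[jx$promoter_id == id, , drop = FALSE]
    if (!nrow(j)) return("")
    paste(sprintf("%s:%d-%d:%s", j$chrom, j$intron_start, j$intron_end,
                  j$strand), collapse = ",")
  }, character(1L))
  tab <- data.frame(
    promoter_id = p$promoter_id, gene_id = p$gene_id,
    chrom = as.character(GenomicRanges::seqnames(p)),
    strand = as.character(GenomicRanges::strand(p)),
    tss = p$tss, tss_rank = p$tss_rank, internal = p$internal,
    n_transcripts = p$n_transcripts, junctions = unname(jlist),
    stringsAsFactors = FALSE)
  tsv <- file.path(dir, "promoters.tsv")
  writeTsv(tab, tsv)
  bed <- file.path(dir, "promoter_tss.bed")
  if (length(p)) {
    tssGr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(p), IRanges::IRanges(p$tss, width = 1L),
      strand = GenomicRanges::strand(p))
    names(tssGr) <- p$promoter_id
    tssGr$score <- rep(0L, length(tssGr))
    rtracklayer::export(tssGr, bed, format = "BED")
  } else {
    file.create(bed)
  }
  invisible(c(tsv, bed))
}
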