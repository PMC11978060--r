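#' Read a STAR SJ.out.tab splice-junction file
#'
#' Parses the nine-column STAR junction convention: chromosome, 1-based
#' intron start, 1-based intron end, strand code (0 undefined / 1 `+` /
#' 2 `-`), intron motif, annotation flag, unique-mapping read count,
#' multi-mapping read count, maximum spliced overhang.
#'
#' @param path path to an SJ.out.tab file.
#' @return data.frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand` (`"+"`, `"-"` or `"*"` for undefined), `motif`, `annotated`,
#'   `unique_reads`, `multi_reads`, `max_overhang`.
#' @export
readStarJunctions <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  if (file.size(path) == 0L) return(.emptyJunctionRecords())
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (any(nf != 9L)) {
    stop("malformed STAR junction line ", which(nf != 9L)[1L], " in ", path,
         " (expected 9 tab-separated columns, found ", nf[nf != 9L][1L], ")")
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
    col.names = c("chrom", "intron_start", "intron_end", "strand_code",
                  "motif", "annotated", "unique_reads", "multi_reads",
                  "max_overhang"),
    colClasses = list(character = 1L))
  if (!all(dt$strand_code %in% 0:2)) {
    stop("invalid strand code in ", path, " (expected 0, 1 or 2)")
  }
  if (any(dt$unique_reads < 0L) || any(dt$multi_reads < 0L)) {
    stop("negative read count in ", path)
  }
  if (any(dt$intron_start > dt$intron_end)) {
    stop("intron start greater than intron end in ", path)
  }
  out <- data.frame(
    chrom = dt$chrom,
    intron_start = as.integer(dt$intron_start),
    intron_end = as.integer(dt$intron_end),
    strand = c("*", "+", "-")[dt$strand_code + 1L],
    motif = as.integer(dt$motif),
    annotated = dt$annotated != 0L,
    unique_reads = as.integer(dt$unique_reads),
    multi_reads = as.integer(dt$multi_reads),
    max_overhang = as.integer(dt$max_overhang),
    stringsAsFactors = FALSE)
  out
}

.emptyJunctionRecords <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(), motif = integer(),
             annotated = logical(), unique_reads = integer(),
             multi_reads = integer(), max_overhang = integer(),
             stringsAsFactors = FALSE)
}

#' Read a six-column junction BED dialect
#'
#' Accepts `chrom, start0, end0, name, unique_reads, strand` with 0-based
#' half-open coordinates covering the intron; converted to the same 1-based
#' inclusive record layout as [readStarJunctions()].
#'
#' @param path path to the BED file.
#' @return data.frame in the layout of [readStarJunctions()] (`motif`,
#'   `annotated`, `multi_reads`, `max_overhang` filled with neutral values).
#' @export
readJunctionBed <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  if (file.size(path) == 0L) return(.emptyJunctionRecords())
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (any(nf != 6L)) {
    stop("malformed junction BED line ", which(nf != 6L)[1L], " in ", path,
         " (expected 6 tab-separated columns)")
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
    col.names = c("chrom", "start0", "end0", "name", "unique_reads",
                  "strand"),
    colClasses = list(character = c(1L, 4L, 6L)))
  if (any(dt$unique_reads < 0L)) stop("negative read count in ", path)
  if (!all(dt$strand %in% c("+", "-", "."))) {
    stop("invalid strand in ", path)
  }
  data.frame(
    chrom = dt$chrom,
    intron_start = as.integer(dt$start0) + 1L,
    intron_end = as.integer(dt$end0),
    strand = ifelse(dt$strand == ".", "*", dt$strand),
    motif = NA_integer_, annotated = NA,
    unique_reads = as.integer(dt$unique_reads),
    multi_reads = 0L, max_overhang = NA_integer_,
    stringsAsFactors = FALSE)
}

#' Index first-intron junctions by promoter
#'
#' Maps each first-intron junction of the catalog to the promoters that
#' contain it. A junction is promoter-unique when exactly one promoter
#' contains it; a promoter is quantifiable when it is not internal and has
#' at least one promoter-unique junction. Junctions shared between
#' promoters are excluded from counting entirely (never double-counted or
#' split).
#'
#' @param catalog a [PromoterCatalog-class].
#' @return list with `index` (data.frame `promoter_id`, `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `key`, `is_unique`) and
#'   `quantifiable` (named logical per promoter).
#' @export
junctionIndex <- function(catalog) {
  p <- promoterRanges(catalog)
  jx <- promoterJunctions(catalog)
  if (nrow(jx)) {
    jx$key <- junctionKey(jx$chrom, jx$intron_start, jx$intron_end,
                          jx$strand)
    nprom <- tapply(jx$promoter_id, jx$key,
                    function(x) length(unique(x)))
    jx$is_unique <- as.integer(nprom[jx$key]) == 1L
  } else {
    jx$key <- character(0)
    jx$is_unique <- logical(0)
  }
  hasUnique <- p$promoter_id %in% jx$promoter_id[jx$is_unique]
  quantifiable <- hasUnique & !p$internal
  names(quantifiable) <- p$promoter_id
  list(index = jx, quantifiable = quantifiable)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `organ`, `stage_label`,
#'   `time_ordinal`, `sex`, `replicate`, `path` (junction file per sample).
#' @return validated data.frame.
#' @export
readSampleDesign <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "stage_label", "time_ordinal", "sex",
            "replicate", "path")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) {
    stop("design table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(d$sample_id)) stop("duplicated sample_id in design")
  if (!is.numeric(d$time_ordinal)) stop("time_ordinal must be numeric")
  d
}

#' Count unique junction reads per promoter
#'
#' For every quantifiable promoter and sample, sums the unique-mapping read
#' counts over the promoter's promoter-unique first-intron junctions
#' (absent junctions contribute 0). Multi-mapping reads are never counted.
#' Junctions present in the input but absent from the catalog are ignored.
#' Undefined-strand records (STAR code 0) are resolved when their
#' coordinates match the catalog on exactly one strand and dropped with a
#' warning when both strands match. Non-quantifiable promoters (internal,
#' or without any promoter-unique junction) carry `NA`, not zero.
#'
#' @param catalog a [PromoterCatalog-class].
#' @param design design table (see [readSampleDesign()]); its `path` column
#'   locates one junction file per sample.
#' @param dir optional directory that `design$path` entries are relative to.
#' @param format `"star"` (SJ.out.tab) or `"bed"` (6-column dialect).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (promoters x samples), `rowData` columns `gene_id`,
#'   `tss_rank`, `internal`, `quantifiable`, and the design as `colData`.
#' @export
countPromoterReads <- function(catalog, design, dir = NULL,
                               format = c("star", "bed")) {
  format <- match.arg(format)
  idx <- junctionIndex(catalog)
  p <- promoterRanges(catalog)
  uniq <- idx$index[idx$index$is_unique &
                      idx$quantifiable[idx$index$promoter_id], ,
                    drop = FALSE]

  # per-coordinate strand availability for resolving undefined strands
  coordKey <- function(chrom, s, e) paste(chrom, s, e, sep = ":")
  uniqCoord <- coordKey(uniq$chrom, uniq$intron_start, uniq$intron_end)
  strandsAt <- tapply(uniq$strand, uniqCoord,
                      function(x) unique(x), simplify = FALSE)

  mat <- matrix(NA_integer_, nrow = length(p), ncol = nrow(design),
                dimnames = list(p$promoter_id, design$sample_id))
  mat[idx$quantifiable, ] <- 0L

  reader <- if (format == "star") readStarJunctions else readJunctionBed
  for (i in seq_len(nrow(design))) {
    f <- design$path[i]
    if (!is.null(dir)) f <- file.path(dir, f)
    if (!file.exists(f)) {
      stop("junction file for sample '", design$sample_id[i],
           "' not found: ", f)
    }
    rec <- reader(f)
    if (!nrow(rec)) next
    undef <- rec$strand == "*"
    if (any(undef)) {
      ck <- coordKey(rec$chrom[undef], rec$intron_start[undef],
                     rec$intron_end[undef])
      res <- strandsAt[ck]
      nmatch <- vapply(res, function(x) if (is.null(x)) 0L else length(x),
                       integer(1L))
      both <- nmatch == 2L
      if (any(both)) {
        warning(sum(both), " undefined-strand junction(s) in sample '",
                design$sample_id[i],
                "' match promoters on both strands; dropped")
      }
      one <- nmatch == 1L
      rec$strand[undef][one] <- vapply(res[one], `[`, character(1L), 1L)
      drop <- undef
      drop[undef] <- nmatch != 1L
      rec <- rec[!drop, , drop = FALSE]
    }
    key <- junctionKey(rec$chrom, rec$intron_start, rec$intron_end,
                       rec$strand)
    m <- match(uniq$key, key)
    got <- !is.na(m)
    if (any(got)) {
      sums <- rowsum(as.numeric(rec$unique_reads[m[got]]),
                     uniq$promoter_id[got])
      mat[rownames(sums), i] <- as.integer(sums[, 1L])
    }
  }

  rd <- S4Vectors::DataFrame(
    promoter_id = p$promoter_id, gene_id = p$gene_id,
    tss_rank = p$tss_rank, internal = p$internal,
    quantifiable = unname(idx$quantifiable), row.names = p$promoter_id)
  cd <- S4Vectors::DataFrame(design, row.names = design$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat), rowData = rd, colData = cd)
}
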