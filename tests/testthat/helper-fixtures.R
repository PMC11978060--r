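# shared fixture builders and independent oracles

# one GTF feature line in the Ensembl dialect the package reads
gtfLine <- function(feat, s, e, strand, gene, tx, bt = "protein_coding",
                    chrom = "chr1") {
  paste(chrom, "test", feat, s, e, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                gene, tx, bt),
        sep = "\t")
}

writeGtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

# transcript model rows without going through a file
modelRows <- function(tx, gene, strand, exons, bt = "protein_coding",
                      chrom = "chr1") {
  data.frame(transcript_id = tx, gene_id = gene, chrom = chrom,
             strand = strand, start = vapply(exons, `[`, 0, 1),
             end = vapply(exons, `[`, 0, 2), biotype = bt,
             stringsAsFactors = FALSE)
}

# independent grouping oracle: union-find over pairwise first-exon overlap
bruteForceGroups <- function(firstExons) {
  n <- nrow(firstExons)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && firstExons$gene[i] == firstExons$gene[j] &&
        firstExons$start[i] <= firstExons$end[j] &&
        firstExons$start[j] <= firstExons$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

# first exon (transcription order) of each transcript in a model table
firstExonTable <- function(transcripts) {
  do.call(rbind, lapply(split(transcripts, transcripts$transcript_id),
    function(d) {
      k <- if (d$strand[1] == "+") which.min(d$start) else which.max(d$start)
      data.frame(transcript_id = d$transcript_id[1], gene = d$gene_id[1],
                 strand = d$strand[1], start = d$start[k], end = d$end[k],
                 stringsAsFactors = FALSE)
    }))
}

# independent per-junction tally of promoter counts, following the stated
# rules (unique junctions only, internal promoters excluded, strand code 0
# resolved iff the coordinates match the catalog on exactly one strand)
bruteForceCounts <- function(catalog, sjTables) {
  p <- promoterRanges(catalog)
  jx <- promoterJunctions(catalog)
  key <- paste(jx$chrom, jx$intron_start, jx$intron_end, jx$strand)
  shared <- names(which(table(key)[key] > 1))
  mat <- matrix(NA_real_, length(p), length(sjTables),
                dimnames = list(p$promoter_id, names(sjTables)))
  for (pi in seq_along(p)) {
    pid <- p$promoter_id[pi]
    if (p$internal[pi]) next
    j <- jx[jx$promoter_id == pid, , drop = FALSE]
    k <- paste(j$chrom, j$intron_start, j$intron_end, j$strand)
    j <- j[!(k %in% shared), , drop = FALSE]
    if (!nrow(j)) next
    for (s in seq_along(sjTables)) {
      tab <- sjTables[[s]]
      total <- 0
      for (r in seq_len(nrow(j))) {
        hit <- tab$intron_start == j$intron_start[r] &
          tab$intron_end == j$intron_end[r] & tab$chrom == j$chrom[r]
        for (h in which(hit)) {
          st <- c("*", "+", "-")[tab$strand_code[h] + 1]
          if (st == "*") {
            # which catalog strands carry a unique junction here?
            u <- jx[!(key %in% shared) & jx$chrom == j$chrom[r] &
                      jx$intron_start == j$intron_start[r] &
                      jx$intron_end == j$intron_end[r], , drop = FALSE]
            st <- if (length(unique(u$strand)) == 1) u$strand[1] else "x"
          }
          if (st == j$strand[r]) total <- total + tab$unique_reads[h]
        }
      }
      mat[pi, s] <- total
    }
  }
  mat
}

# write a simulated dataset to disk and run it through catalog + counting
simulatedDataset <- function(cfg) {
  ann <- simulateAnnotation(cfg)
  cts <- simulateCounts(cfg, ann)
  dir <- tempfile("simfx")
  dir.create(dir)
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(ann$gtf, gtf)
  for (s in names(cts$sj)) {
    write.table(cts$sj[[s]], file.path(dir, paste0(s, ".SJ.out.tab")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  catalog <- buildPromoterCatalog(readTranscriptModels(gtf))
  se <- countPromoterReads(catalog, cts$design, dir = dir)
  list(dir = dir, gtf = gtf, ann = ann, cts = cts, catalog = catalog,
       se = se)
}

# activity object assembled directly from preset assay values
activitySe <- function(absolute, relative, geneId, tssRank = NULL,
                       quantifiable = NULL) {
  n <- nrow(absolute)
  rd <- S4Vectors::DataFrame(
    promoter_id = rownames(absolute), gene_id = geneId,
    tss_rank = tssRank %||% rep(1L, n),
    internal = rep(FALSE, n),
    quantifiable = quantifiable %||% rep(TRUE, n),
    row.names = rownames(absolute))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(absolute = absolute, relative = relative), rowData = rd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
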