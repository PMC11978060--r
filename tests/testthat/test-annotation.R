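test_that("GTF parsing maps exons with strand-aware transcription order", {
  gtf <- writeGtf(c(
    gtfLine("exon", 100, 200, "+", "gA", "tA1"),
    gtfLine("exon", 500, 600, "+", "gA", "tA1"),
    gtfLine("exon", 100, 200, "-", "gB", "tB1", bt = "retained_intron"),
    gtfLine("exon", 500, 600, "-", "gB", "tB1", bt = "retained_intron")))
  tr <- readTranscriptModels(gtf)
  expect_equal(nrow(tr), 4L)
  expect_setequal(tr$gene_id, c("gA", "gB"))
  expect_equal(tr$biotype[tr$gene_id == "gB"], rep("retained_intron", 2))

  catalog <- buildPromoterCatalog(tr)
  p <- promoterRanges(catalog)
  # '+' first exon is the lowest-coordinate exon, '-' the highest
  expect_equal(p$tss[p$gene_id == "gA"], 100L)
  expect_equal(p$tss[p$gene_id == "gB"], 600L)
  expect_equal(start(p[p$gene_id == "gB"]), 500L)
})

test_that("empty, malformed, and exonless-transcript GTF inputs are handled", {
  empty <- writeGtf(character(0))
  expect_equal(nrow(readTranscriptModels(empty)), 0L)
  comments <- writeGtf("#!genome-build test")
  expect_equal(nrow(readTranscriptModels(comments)), 0L)

  bad <- writeGtf(c(gtfLine("exon", 100, 200, "+", "g1", "t1"),
                    "chr1\tonly\tthree"))
  expect_error(readTranscriptModels(bad), "line 2")

  noexon <- writeGtf(c(
    gtfLine("transcript", 100, 600, "+", "g1", "t1"),
    gtfLine("exon", 100, 200, "+", "g1", "t1"),
    gtfLine("transcript", 100, 600, "+", "g1", "tEmpty")))
  expect_warning(tr <- readTranscriptModels(noexon), "tEmpty")
  expect_equal(unique(tr$transcript_id), "t1")
})

test_that("overlapping first exons merge with the 5'-most TSS and 5'->3' ranks", {
  # overlap forces a merge; tss is the minimum start on '+'
  tr <- rbind(modelRows("t1", "g1", "+", list(c(100, 200), c(500, 600))),
              modelRows("t2", "g1", "+", list(c(150, 250), c(500, 600))))
  p <- promoterRanges(buildPromoterCatalog(tr))
  expect_equal(length(p), 1L)
  expect_equal(p$tss, 100L)
  expect_equal(p$n_transcripts, 2L)

  # disjoint first exons stay apart, ranked 1 and 2 from 5' to 3'
  tr <- rbind(modelRows("t1", "g1", "+", list(c(100, 200), c(900, 950))),
              modelRows("t2", "g1", "+", list(c(300, 400), c(900, 950))))
  p <- promoterRanges(buildPromoterCatalog(tr))
  expect_equal(p$tss_rank[order(p$tss)], c(1L, 2L))

  # on '-', the 5'-most TSS is the maximum coordinate
  tr <- rbind(modelRows("t1", "g1", "-", list(c(100, 200), c(50, 80))),
              modelRows("t2", "g1", "-", list(c(150, 250), c(50, 80))))
  p <- promoterRanges(buildPromoterCatalog(tr))
  expect_equal(length(p), 1L)
  expect_equal(p$tss, 250L)

  # conflicting strands within a gene are rejected
  tr <- rbind(modelRows("t1", "g1", "+", list(c(100, 200))),
              modelRows("t2", "g1", "-", list(c(300, 400))))
  expect_error(buildPromoterCatalog(tr), "conflicting")
})

test_that("first-intron junctions derive from consecutive exons in transcription order", {
  tr <- rbind(modelRows("t1", "g1", "+", list(c(100, 200), c(500, 600))),
              modelRows("t2", "g2", "-", list(c(500, 600), c(100, 200))))
  jx <- promoterJunctions(buildPromoterCatalog(tr))
  plus <- jx[jx$strand == "+", ]
  minus <- jx[jx$strand == "-", ]
  expect_equal(c(plus$intron_start, plus$intron_end), c(201L, 499L))
  # '-' transcript: first exon is (500,600), so the first intron is the same
  # genomic interval approached from the other side
  expect_equal(c(minus$intron_start, minus$intron_end), c(201L, 499L))

  # single-exon transcripts contribute no junction
  tr <- modelRows("t1", "g1", "+", list(c(100, 200)))
  expect_equal(nrow(promoterJunctions(buildPromoterCatalog(tr))), 0L)
})

test_that("internal promoters are flagged by overlap with same-gene non-first exons", {
  tr <- rbind(
    modelRows("tA", "g1", "+", list(c(100, 200), c(500, 600), c(900, 1000))),
    modelRows("tB", "g1", "+", list(c(480, 620), c(900, 1000))))
  p <- promoterRanges(buildPromoterCatalog(tr))
  expect_true(p$internal[p$tss == 480])
  expect_false(p$internal[p$tss == 100])

  # overlap with another *first* exon does not make a promoter internal
  tr <- rbind(modelRows("tA", "g1", "+", list(c(100, 200), c(900, 1000))),
              modelRows("tB", "g1", "+", list(c(150, 250), c(900, 1000))))
  expect_false(any(promoterRanges(buildPromoterCatalog(tr))$internal))

  # cross-gene overlaps are ignored; single-transcript genes are never internal
  tr <- rbind(
    modelRows("tA", "g1", "+", list(c(100, 200), c(500, 600))),
    modelRows("tB", "g2", "+", list(c(480, 620), c(900, 1000))))
  expect_false(any(promoterRanges(buildPromoterCatalog(tr))$internal))
})

test_that("promoter grouping equals a brute-force union-find and partitions transcripts", {
  set.seed(42)
  for (rep in 1:5) {
    rows <- list()
    for (g in 1:12) {
      strand <- sample(c("+", "-"), 1)
      for (t in seq_len(sample(1:4, 1))) {
        s <- 1000 * g + sample(0:300, 1)
        first <- c(s, s + sample(30:150, 1))
        second <- c(1000 * g + 600, 1000 * g + 700)
        exons <- if (strand == "+") list(first, second) else
          list(first + 1000, second + 1000 - 1500)
        rows[[length(rows) + 1]] <- modelRows(
          sprintf("g%d_t%d", g, t), sprintf("g%02d", g), strand, exons)
      }
    }
    tr <- do.call(rbind, rows)
    catalog <- buildPromoterCatalog(tr)
    tm <- transcriptMap(catalog)
    p <- promoterRanges(catalog)

    # partition: per-gene promoter memberships sum to transcript counts
    expect_equal(sum(p$n_transcripts), length(unique(tr$transcript_id)))
    expect_false(anyDuplicated(tm$transcript_id) > 0)

    # oracle: same partition of transcripts into promoters
    fe <- firstExonTable(tr)
    grp <- bruteForceGroups(fe)
    oracle <- split(fe$transcript_id, grp)
    got <- split(tm$transcript_id, tm$promoter_id)
    norm <- function(l) sort(unname(vapply(l, function(x)
      paste(sort(x), collapse = "|"), character(1))))
    expect_equal(norm(oracle), norm(got))
  }
})

test_that("mirroring coordinates and flipping strand mirrors the catalog", {
  set.seed(7)
  rows <- list()
  for (g in 1:6) {
    for (t in 1:3) {
      s <- 1000 * g + sample(0:200, 1)
      rows[[length(rows) + 1]] <- modelRows(
        sprintf("m%d_t%d", g, t), sprintf("m%02d", g), "+",
        list(c(s, s + 100), c(1000 * g + 500, 1000 * g + 580)))
    }
  }
  tr <- do.call(rbind, rows)
  M <- 10^6
  mir <- tr
  mir$start <- M - tr$end
  mir$end <- M - tr$start
  mir$strand <- "-"
  p1 <- promoterRanges(buildPromoterCatalog(tr))
  p2 <- promoterRanges(buildPromoterCatalog(mir))
  ord1 <- order(p1$gene_id, p1$tss_rank)
  ord2 <- order(p2$gene_id, p2$tss_rank)
  expect_equal(p2$tss[ord2], M - p1$tss[ord1])
  expect_equal(p2$tss_rank[ord2], p1$tss_rank[ord1])
  expect_equal(p2$internal[ord2], p1$internal[ord1])
})

test_that("catalog export is deterministic for identical input", {
  tr <- rbind(modelRows("t1", "g1", "+", list(c(100, 200), c(500, 600))),
              modelRows("t2", "g1", "+", list(c(300, 400), c(500, 600))))
  d1 <- tempfile(); d2 <- tempfile()
  exportCatalog(buildPromoterCatalog(tr), d1)
  exportCatalog(buildPromoterCatalog(tr), d2)
  for (f in c("promoters.tsv", "promoter_tss.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
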