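test_that("median-of-ratios size factors match hand-computed references", {
  m <- matrix(c(10, 20, 40, 10, 20, 40), nrow = 3)
  expect_equal(unname(promoterSizeFactors(m)), c(1, 1))

  # doubled column: factors (1/sqrt(2), sqrt(2)) against the geometric mean
  m <- matrix(c(10, 20, 40, 20, 40, 80), nrow = 3)
  expect_equal(unname(promoterSizeFactors(m)), c(1 / sqrt(2), sqrt(2)))

  expect_error(promoterSizeFactors(matrix(1:3, ncol = 1)), "2 samples")

  # every promoter hits a zero somewhere: error points at the fallback
  m <- matrix(c(0, 5, 5, 0), nrow = 2)
  expect_error(promoterSizeFactors(m), "poscounts")
  sf <- promoterSizeFactors(m, fallback = "poscounts")
  expect_true(all(sf > 0))
})

test_that("absolute activity is log2(normalized + 1) and preserves missingness", {
  tr <- rbind(modelRows("t1", "g1", "+", list(c(100, 200), c(900, 950))),
              modelRows("t2", "g1", "+", list(c(300, 400), c(900, 950))))
  catalog <- buildPromoterCatalog(tr)
  dir <- tempfile(); dir.create(dir)
  writeLines(c("chr1\t201\t899\t1\t1\t1\t15\t0\t25",
               "chr1\t401\t899\t1\t1\t1\t16\t0\t25"),
             file.path(dir, "s1.tab"))
  writeLines(c("chr1\t201\t899\t1\t1\t1\t31\t0\t25",
               "chr1\t401\t899\t1\t1\t1\t0\t0\t25"),
             file.path(dir, "s2.tab"))
  design <- data.frame(sample_id = c("s1", "s2"), organ = "o",
                       stage_label = c("A", "B"), time_ordinal = 0:1,
                       sex = "F", replicate = 1,
                       path = c("s1.tab", "s2.tab"), stringsAsFactors = FALSE)
  se <- countPromoterReads(catalog, design, dir = dir)
  act <- promoterActivity(se, sizeFactors = c(1, 2))
  ab <- SummarizedExperiment::assay(act, "absolute")
  expect_equal(unname(ab["g1_p1", "s1"]), 4)              # log2(15/1 + 1)
  expect_equal(unname(ab["g1_p2", "s2"]), 0)              # zero count
  expect_equal(unname(ab["g1_p1", "s2"]), log2(16.5))     # 31/2 + 1

  # gene expression: log2(1 + sum of normalized linear counts)
  ge <- geneExpression(act)
  expect_equal(unname(ge["g1", "s1"]), 5)                 # log2(15+16+1)
  # relative activity: fractions of the gene's normalized total
  rel <- SummarizedExperiment::assay(act, "relative")
  expect_equal(unname(rel[, "s1"]), c(15, 16) / 31)
  expect_equal(unname(rel["g1_p1", "s2"]), 1)             # single expressed
})

test_that("relative activities sum to one per expressed gene-sample", {
  cfg <- simulationConfig(nGenes = 15, organs = "heart", nStages = 5,
                          replicates = 2, seed = 9)
  sim <- simulatedDataset(cfg)
  act <- promoterActivity(sim$se)
  rel <- SummarizedExperiment::assay(act, "relative")
  gene <- SummarizedExperiment::rowData(act)$gene_id
  tot <- S4Vectors::metadata(act)$geneTotals
  for (s in seq_len(ncol(rel))) {
    sums <- rowsum(rel[, s], gene, na.rm = TRUE)
    expressed <- rownames(tot)[tot[, s] > 0]
    expect_true(all(abs(sums[expressed, 1] - 1) < 1e-9))
  }
  # gene expression of a single-promoter gene equals its promoter activity
  ab <- SummarizedExperiment::assay(act, "absolute")
  counts1 <- table(gene[SummarizedExperiment::rowData(act)$quantifiable])
  singles <- names(counts1)[counts1 == 1]
  ge <- geneExpression(act)
  for (g in singles) {
    pid <- rownames(ab)[gene == g &
                          SummarizedExperiment::rowData(act)$quantifiable]
    expect_equal(unname(ab[pid, ]), unname(ge[g, ]))
  }
})

test_that("rescaling one sample's depth moves its size factor, not its activity", {
  # the geometric-mean reference itself contains the rescaled sample, so the
  # factor absorbs c^((n-1)/n) and the rest c^(-1/n); at a realistic sample
  # count the property holds within the stated 1%
  set.seed(31)
  n <- 100
  m <- matrix(rnbinom(60 * n, mu = 300, size = 20) + 100, nrow = 60,
              dimnames = list(sprintf("p%02d", 1:60),
                              sprintf("s%03d", seq_len(n))))
  sf1 <- promoterSizeFactors(m)
  m2 <- m
  m2[, 3] <- m[, 3] * 2
  sf2 <- promoterSizeFactors(m2)
  expect_equal(sf2[3] / sf1[3], 2, tolerance = 0.01, ignore_attr = TRUE)
  a1 <- log2(m[, 3] / sf1[3] + 1)
  a2 <- log2(m2[, 3] / sf2[3] + 1)
  expect_true(all(abs(a2 / a1 - 1) < 0.01))
})

test_that("classification yields one major per expressed gene with 5' tie-break", {
  ab <- matrix(c(5, 5, 1, 1, 0.1, 0.1,   # major / minor / inactive
                 0.2, 0.2, 0.1, 0.1,     # gene with no active promoter
                 3, 3, 3, 3),            # exact tie
               nrow = 7, byrow = TRUE,
               dimnames = list(c("a_p1", "a_p2", "a_p3", "b_p1", "b_p2",
                                 "c_p1", "c_p2"), c("s1", "s2")))
  rel <- matrix(c(0.8, 0.8, 0.15, 0.15, 0.05, 0.05, 0.7, 0.7, 0.3, 0.3,
                  0.5, 0.5, 0.5, 0.5), nrow = 7, byrow = TRUE,
                dimnames = dimnames(ab))
  se <- activitySe(ab, rel, geneId = c("a", "a", "a", "b", "b", "c", "c"),
                   tssRank = c(1L, 2L, 3L, 1L, 2L, 1L, 2L))
  cl <- classifyPromoters(se)
  expect_equal(cl$label[cl$promoter_id %in% c("a_p1", "a_p2", "a_p3")],
               c("major", "minor", "inactive"))
  # below threshold everywhere: both inactive, no major
  expect_equal(cl$label[cl$gene_id == "b"], c("inactive", "inactive"))
  # exact tie at the maximum goes to the 5'-most promoter (rank 1)
  expect_equal(cl$label[cl$gene_id == "c"], c("major", "minor"))
})

test_that("multi-active genes need two active promoters above 10% contribution", {
  cl <- data.frame(
    promoter_id = sprintf("p%d", 1:7),
    gene_id = c("a", "a", "b", "b", "c", "d", "d"),
    tss_rank = 1L, mean_activity = c(5, 2, 5, 2, 4, 5, 0.1),
    mean_relative = c(0.85, 0.15, 0.95, 0.05, 1, 0.88, 0.12),
    label = c("major", "minor", "major", "minor", "major", "major",
              "inactive"),
    stringsAsFactors = FALSE)
  # a: qualifies; b: minor below 10%; c: single promoter; d: second is inactive
  expect_equal(multiActiveGenes(cl), "a")
})

test_that("variance ranking matches an independent sort", {
  set.seed(12)
  ab <- matrix(rnorm(100 * 8, sd = rep(seq(0.1, 2, length.out = 100), 8)),
               nrow = 100,
               dimnames = list(sprintf("p%03d", 1:100), sprintf("s%d", 1:8)))
  ab[7, ] <- 3  # constant promoter: variance zero, ranked last
  se <- activitySe(ab, ab * 0 + 0.5, geneId = sprintf("g%03d", 1:100))
  top <- topVariancePromoters(se, 10)
  oracle <- sort(apply(ab, 1, var), decreasing = TRUE)
  expect_equal(top$variance, unname(oracle[1:10]))
  expect_equal(nrow(topVariancePromoters(se, 0)), 0L)
  expect_warning(all100 <- topVariancePromoters(se, 500), "returning all")
  expect_equal(nrow(all100), 100L)
  expect_equal(all100$promoter_id[100], "p007")
})
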