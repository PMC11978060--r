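test_that("the pair-category truth table is exhaustive and exclusive", {
  trends <- c("Up", "Down", "Flat")
  grid <- expand.grid(major = trends, minor = trends,
                      stringsAsFactors = FALSE)
  got <- pairCategory(grid$major, grid$minor)
  expect_equal(got[grid$major == "Up" & grid$minor == "Down"], "Up_Down")
  expect_equal(got[grid$major == "Down" & grid$minor == "Up"], "Down_Up")
  expect_equal(got[grid$major == "Flat" & grid$minor == "Flat"],
               "Unclassified")
  # every combination maps to exactly one of the nine categories
  expect_true(all(got %in% PAIR_CATEGORIES))
  expect_equal(sort(unique(got)), sort(PAIR_CATEGORIES))
  expect_error(pairCategory("Sideways", "Up"), "must be one of")
})

test_that("pairs inherit trends, with skipped or absent fits treated as flat", {
  classes <- data.frame(
    promoter_id = c("a_p1", "a_p2", "a_p3", "b_p1", "b_p2", "c_p1"),
    gene_id = c("a", "a", "a", "b", "b", "c"),
    tss_rank = c(1L, 2L, 3L, 1L, 2L, 1L),
    mean_activity = c(6, 4, 3, 5, 2, 4), mean_relative = 0.5,
    label = c("major", "minor", "minor", "major", "minor", "major"),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    promoter_id = c("a_p1", "a_p2", "b_p1"),
    is_ddp = c(TRUE, TRUE, TRUE),
    direction = c("Up", "Flat", "Down"),
    skipped = NA_character_, stringsAsFactors = FALSE)
  calls$direction[2] <- "Flat"  # significant but flat endpoints
  pairs <- classifyPromoterPairs(classes, calls)
  expect_equal(nrow(pairs), 3L)  # two minors for a, one for b; c has none
  # gene a: one minor flat (listed), one minor absent from calls (flat too)
  expect_equal(pairs$category[pairs$gene_id == "a"],
               c("Up_Flat", "Up_Flat"))
  expect_equal(pairs$category[pairs$gene_id == "b"], "Down_Flat")

  # gene-level trend attaches a consistency flag without reassigning
  gcalls <- data.frame(gene_id = c("a", "b"), direction = c("Down", "Down"),
                       stringsAsFactors = FALSE)
  pairs2 <- classifyPromoterPairs(classes, calls, gcalls)
  expect_equal(pairs2$gene_trend[pairs2$gene_id == "a"], c("Down", "Down"))
  expect_false(any(pairs2$consistent[pairs2$gene_id == "a"]))  # Up_Flat vs Down
  expect_true(all(pairs2$consistent[pairs2$gene_id == "b"]))
  expect_equal(pairs2$category, pairs$category)
})

test_that("category aggregation counts pairs and genes separately", {
  calls <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g4"),
    minor_promoter_id = c("g1_p2", "g2_p2", "g3_p2", "g4_p2", "g4_p3"),
    category = c("Up_Up", "Up_Up", "Up_Up", "Up_Up", "Up_Flat"),
    stringsAsFactors = FALSE)
  agg <- aggregateCategories(calls)
  expect_equal(agg$n_pairs[agg$category == "Up_Up"], 4L)
  expect_equal(agg$n_genes[agg$category == "Up_Up"], 4L)
  # a gene with two minors contributes pairs to two categories
  expect_equal(agg$n_pairs[agg$category == "Up_Flat"], 1L)
  expect_equal(agg$n_genes[agg$category == "Up_Flat"], 1L)
  expect_equal(sum(agg$n_pairs), nrow(calls))

  empty <- aggregateCategories(calls[0, ])
  expect_equal(sum(empty$n_pairs), 0L)
  expect_equal(nrow(empty), 9L)
})

test_that("gene trends run the DDP machinery on gene expression", {
  set.seed(44)
  times <- rep(0:15, each = 2)
  ge <- rbind(
    up = 2 + 1.5 * times / 15 + rnorm(32, sd = 0.2),
    flat = 3 + rnorm(32, sd = 0.2),
    # antagonistic switch with offsetting magnitudes: near-constant total
    offset = 5 + rnorm(32, sd = 0.2))
  g <- geneTrends(ge, times)
  expect_equal(g$gene_id, c("up", "flat", "offset"))
  expect_equal(g$direction, c("Up", "Flat", "Flat"))
})

test_that("stage-wise major and minor usage means always sum to one", {
  # construct relative activities directly: two genes x 3 stages x 2 reps
  samples <- sprintf("s%d", 1:6)
  rel <- rbind(
    matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4), nrow = 1),   # g1 major
    matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), nrow = 1),   # g1 minor
    matrix(rep(0.5, 6), nrow = 1),                        # g2 major
    matrix(rep(0.5, 6), nrow = 1),                        # g2 minor
    matrix(rep(1, 6), nrow = 1))                          # g3 single
  rownames(rel) <- c("g1_p1", "g1_p2", "g2_p1", "g2_p2", "g3_p1")
  colnames(rel) <- samples
  ab <- rel * 0 + 5
  se <- activitySe(ab, rel,
                   geneId = c("g1", "g1", "g2", "g2", "g3"),
                   tssRank = c(1L, 2L, 1L, 2L, 1L))
  classes <- data.frame(
    promoter_id = rownames(rel),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    tss_rank = c(1L, 2L, 1L, 2L, 1L), mean_activity = 5,
    mean_relative = rowMeans(rel),
    label = c("major", "minor", "major", "minor", "major"),
    stringsAsFactors = FALSE)
  design <- data.frame(sample_id = samples, organ = "o",
                       stage_label = rep(c("A", "B", "C"), each = 2),
                       time_ordinal = rep(0:2, each = 2), sex = "F",
                       replicate = rep(1:2, 3), stringsAsFactors = FALSE)
  u <- relativeUsageTrajectory(se, classes, design)
  expect_equal(u$major_mean + u$minor_mean, rep(1, 3), tolerance = 1e-9)
  # planted rising minor usage shows up as a monotone stage trend
  expect_true(all(diff(u$minor_mean) > 0))
  # single-promoter genes are excluded: dropping g3 changes nothing
  u2 <- relativeUsageTrajectory(se, classes, design,
                                genes = c("g1", "g2"))
  expect_equal(u, u2)

  # no eligible genes -> empty result
  u3 <- relativeUsageTrajectory(se, classes, design, genes = "g3")
  expect_equal(nrow(u3), 0L)
})

test_that("coding fractions summarize minor-promoter transcript biotypes", {
  tr <- rbind(
    modelRows("t1", "g1", "+", list(c(100, 200), c(900, 950))),
    modelRows("t2a", "g1", "+", list(c(300, 400), c(900, 950))),
    modelRows("t2b", "g1", "+", list(c(310, 410), c(900, 950)),
              bt = "retained_intron"),
    modelRows("t2c", "g1", "+", list(c(320, 420), c(900, 950))))
  catalog <- buildPromoterCatalog(tr)
  calls <- data.frame(gene_id = "g1", major_promoter_id = "g1_p1",
                      minor_promoter_id = "g1_p2", category = "Up_Up",
                      stringsAsFactors = FALSE)
  cf <- codingFraction(catalog, calls)
  expect_equal(cf$coding_fraction[cf$category == "Up_Up"], 2 / 3)
  expect_equal(cf$n_transcripts[cf$category == "Up_Up"], 3L)
  expect_true(is.na(cf$coding_fraction[cf$category == "Down_Up"]))
})
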