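#' Configuration for the synthetic junction-count simulator
#'
#' The simulator emulates a multi-organ developmental RNA-seq design at toy
#' scale: multi-promoter gene architectures with distinct first-intron
#' junctions, negative-binomial unique junction read counts whose means
#' follow planted temporal trajectories on a log2 scale, per-sample
#' sequencing-depth factors, and replicate noise. Defaults describe two
#' organs sampled over 16 developmental stages (embryonic through
#' postnatal labels) with 2 replicates each.
#'
#' @param nGenes number of simulated genes (default 40).
#' @param promoterWeights probabilities for 1..4 promoters per gene.
#' @param organs organ names (default `c("heart", "liver")`).
#' @param nStages number of developmental stages (default 16; ordinal
#'   times `0..nStages-1`).
#' @param stageLabels stage names; default mouse-style E/P labels for 16
#'   stages.
#' @param replicates replicates per stage (default 2).
#' @param baselineMean mean unique junction reads of a major promoter at
#'   trajectory baseline (default 100).
#' @param minorBaselineFrac minor promoter baseline as a fraction of the
#'   major baseline (default 0.4).
#' @param dispersion negative-binomial dispersion (Var = mu + disp * mu^2;
#'   default 0.05).
#' @param effect planted trajectory amplitude in log2 units from first to
#'   last stage (default 2).
#' @param patternMix named probabilities over the eight switching
#'   categories planted for genes with active minor promoters (default
#'   uniform). A `Flat_Flat` entry may be used to plant fully flat pairs.
#' @param singleTrajMix trajectory probabilities (`flat`, `up`, `down`)
#'   for majors without an active minor.
#' @param inactiveFraction probability that a minor promoter is planted
#'   inactive (near-zero baseline, default 0.1).
#' @param inactiveBaseline mean counts of an inactive promoter (default
#'   0.05).
#' @param sizeFactorRange range of per-sample depth factors; drawn
#'   log-uniformly and renormalized to geometric mean 1 (default
#'   `c(0.5, 2)`, i.e. 4x depth span).
#' @param junctionSplit fixed proportions splitting a promoter's reads
#'   across its two member junctions (default `c(0.7, 0.3)`).
#' @param internalPromoterGenes number of genes carrying an extra planted
#'   internal promoter (default 2).
#' @param sharedJunctionPairs number of overlapping gene pairs sharing a
#'   first-intron junction, exercising the shared-junction exclusion
#'   (default 1).
#' @param codingFrac probability that a simulated transcript is
#'   `protein_coding` (default 0.75, within the 60-90% range typical of
#'   alternative-promoter transcripts).
#' @param seed integer seed fixing all randomness (default 1).
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    nGenes = 40L,
    promoterWeights = c(`1` = 0.25, `2` = 0.35, `3` = 0.25, `4` = 0.15),
    organs = c("heart", "liver"),
    nStages = 16L,
    stageLabels = NULL,
    replicates = 2L,
    baselineMean = 100,
    minorBaselineFrac = 0.4,
    dispersion = 0.05,
    effect = 2,
    patternMix = NULL,
    singleTrajMix = c(flat = 1 / 3, up = 1 / 3, down = 1 / 3),
    inactiveFraction = 0.1,
    inactiveBaseline = 0.05,
    sizeFactorRange = c(0.5, 2),
    junctionSplit = c(0.7, 0.3),
    internalPromoterGenes = 2L,
    sharedJunctionPairs = 1L,
    codingFrac = 0.75,
    seed = 1L) {
  if (is.null(stageLabels)) {
    full <- c("E10.5", "E11.5", "E12.5", "E13.5", "E14.5", "E15.5",
              "E16.5", "E17.5", "E18.5", "P0", "P3", "P7", "P14", "P28",
              "P35", "P63")
    stageLabels <- if (nStages <= length(full)) full[seq_len(nStages)]
    else sprintf("S%02d", seq_len(nStages))
  }
  if (is.null(patternMix)) {
    eight <- setdiff(PAIR_CATEGORIES, "Unclassified")
    patternMix <- stats::setNames(rep(1 / 8, 8L), eight)
  }
  cfg <- list(
    nGenes = as.integer(nGenes), promoterWeights = promoterWeights,
    organs = organs, nStages = as.integer(nStages),
    stageLabels = stageLabels, replicates = as.integer(replicates),
    baselineMean = baselineMean, minorBaselineFrac = minorBaselineFrac,
    dispersion = dispersion, effect = effect, patternMix = patternMix,
    singleTrajMix = singleTrajMix, inactiveFraction = inactiveFraction,
    inactiveBaseline = inactiveBaseline,
    sizeFactorRange = sizeFactorRange, junctionSplit = junctionSplit,
    internalPromoterGenes = as.integer(internalPromoterGenes),
    sharedJunctionPairs = as.integer(sharedJunctionPairs),
    codingFrac = codingFrac, seed = as.integer(seed))
  stopifnot(
    cfg$nGenes >= 1L, cfg$nStages >= 4L, cfg$replicates >= 1L,
    cfg$baselineMean > 0, cfg$minorBaselineFrac > 0, cfg$dispersion > 0,
    cfg$inactiveBaseline > 0, all(cfg$sizeFactorRange > 0),
    length(cfg$sizeFactorRange) == 2L,
    abs(sum(cfg$promoterWeights) - 1) < 1e-8,
    abs(sum(cfg$patternMix) - 1) < 1e-8,
    abs(sum(cfg$junctionSplit) - 1) < 1e-8,
    cfg$internalPromoterGenes <= cfg$nGenes,
    length(cfg$stageLabels) == cfg$nStages,
    cfg$codingFrac >= 0, cfg$codingFrac <= 1)
  allowed <- c(setdiff(PAIR_CATEGORIES, "Unclassified"), "Flat_Flat")
  if (!all(names(cfg$patternMix) %in% allowed)) {
    stop("patternMix names must be switching categories")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

# gene geometry constants (bases); exon widths small relative to spacing so
# promoter first exons never collide across ranks
.GENE_SPACING <- 20000L
.PROM_SPACING <- 1000L
.EXON_W <- 200L

#' Simulate a toy genome annotation with planted promoter architecture
#'
#' Generates GTF text for `nGenes` genes on alternating strands, each with
#' 1-4 promoters (non-overlapping first exons, shared downstream exons, a
#' distinct pair of first-intron junctions per promoter from an
#' exon-skipping second transcript), plus optional planted internal
#' promoters (first exon overlapping a downstream exon) and overlapping
#' gene pairs sharing a first-intron junction, to exercise the exclusion
#' rules.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `gtf` (character vector of GTF lines), `promoters`
#'   (truth table: `promoter_id`, `gene_id`, `tss_rank`, `strand`,
#'   `internal`, `shared_junction`), `junctions` (truth junction table with
#'   split weights) and `transcripts` (`transcript_id`, `promoter_id`,
#'   `biotype`).
#' @export
simulateAnnotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(cfg$seed, .simulateAnnotationImpl(cfg))
}

.simulateAnnotationImpl <- function(cfg) {
  nProm <- sample(seq_along(cfg$promoterWeights), cfg$nGenes,
                  replace = TRUE, prob = cfg$promoterWeights)
  internalGene <- seq_len(cfg$internalPromoterGenes)
  gtf <- character(0)
  promTruth <- list()
  jxTruth <- list()
  trTruth <- list()

  attr9 <- function(g, t, bt) {
    sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                   'gene_biotype "protein_coding"; ',
                   'transcript_biotype "%s";'), g, t, bt)
  }
  featLine <- function(chrom, feat, s, e, strand, attrs) {
    paste("chr1", "promdyn_sim", feat, s, e, ".", strand, ".", attrs,
          sep = "\t")
  }
  drawBiotype <- function() {
    if (stats::runif(1L) < cfg$codingFrac) "protein_coding"
    else "retained_intron"
  }

  for (i in seq_len(cfg$nGenes)) {
    gid <- sprintf("g%04d", i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    base <- i * .GENE_SPACING
    K <- nProm[i]
    hasInternal <- i %in% internalGene

    if (strand == "+") {
      fe <- cbind(start = base + (seq_len(K) - 1L) * .PROM_SPACING,
                  end = base + (seq_len(K) - 1L) * .PROM_SPACING + .EXON_W)
      e2 <- c(base + K * .PROM_SPACING + 500L,
              base + K * .PROM_SPACING + 500L + .EXON_W)
      e3 <- c(base + K * .PROM_SPACING + 1500L,
              base + K * .PROM_SPACING + 1500L + .EXON_W)
    } else {
      # transcription right-to-left: first exons at high coordinates,
      # rank 1 (5'-most) has the highest coordinates
      fe <- cbind(start = base + 2000L + (K - seq_len(K)) * .PROM_SPACING,
                  end = base + 2000L + (K - seq_len(K)) * .PROM_SPACING +
                    .EXON_W)
      e2 <- c(base + 1000L, base + 1000L + .EXON_W)
      e3 <- c(base, base + .EXON_W)
    }

    geneLines <- character(0)
    for (k in seq_len(K)) {
      pid <- sprintf("%s_p%d", gid, k)
      # transcript 1: first exon -> e2 -> e3; transcript 2 skips e2
      for (v in 1:2) {
        tid <- sprintf("%s_t%d", pid, v)
        bt <- drawBiotype()
        ex <- if (v == 1L) list(fe[k, ], e2, e3) else list(fe[k, ], e3)
        exs <- do.call(rbind, ex)
        geneLines <- c(geneLines,
          featLine("chr1", "transcript", min(exs[, 1L]), max(exs[, 2L]),
                   strand, attr9(gid, tid, bt)),
          vapply(seq_len(nrow(exs)), function(r) {
            featLine("chr1", "exon", exs[r, 1L], exs[r, 2L], strand,
                     attr9(gid, tid, bt))
          }, character(1L)))
        trTruth[[length(trTruth) + 1L]] <- data.frame(
          transcript_id = tid, promoter_id = pid, gene_id = gid,
          biotype = bt, stringsAsFactors = FALSE)
      }
      # first-intron junctions of the two transcripts
      if (strand == "+") {
        j1 <- c(fe[k, "end"] + 1L, e2[1L] - 1L)
        j2 <- c(fe[k, "end"] + 1L, e3[1L] - 1L)
      } else {
        j1 <- c(e2[2L] + 1L, fe[k, "start"] - 1L)
        j2 <- c(e3[2L] + 1L, fe[k, "start"] - 1L)
      }
      jxTruth[[length(jxTruth) + 1L]] <- data.frame(
        promoter_id = pid, chrom = "chr1",
        intron_start = c(j1[1L], j2[1L]), intron_end = c(j1[2L], j2[2L]),
        strand = strand, weight = cfg$junctionSplit,
        stringsAsFactors = FALSE)
      promTruth[[length(promTruth) + 1L]] <- data.frame(
        promoter_id = pid, gene_id = gid, tss_rank = k, strand = strand,
        internal = FALSE, shared_junction = FALSE, stringsAsFactors = FALSE)
    }

    if (hasInternal) {
      # extra promoter whose first exon overlaps the shared exon e2; its
      # TSS is 3'-most, so the catalog ranks it K + 1
      pid <- sprintf("%s_p%d", gid, K + 1L)
      tid <- sprintf("%s_t1", pid)
      if (strand == "+") {
        ie <- c(e2[1L] - 50L, e2[1L] + 50L)
        jx <- c(ie[2L] + 1L, e3[1L] - 1L)
      } else {
        ie <- c(e2[2L] - 50L, e2[2L] + 50L)
        jx <- c(e3[2L] + 1L, ie[1L] - 1L)
      }
      exs <- if (strand == "+") rbind(ie, e3) else rbind(e3, ie)
      bt <- drawBiotype()
      geneLines <- c(geneLines,
        featLine("chr1", "transcript", min(exs[, 1L]), max(exs[, 2L]),
                 strand, attr9(gid, tid, bt)),
        vapply(seq_len(nrow(exs)), function(r) {
          featLine("chr1", "exon", exs[r, 1L], exs[r, 2L], strand,
                   attr9(gid, tid, bt))
        }, character(1L)))
      trTruth[[length(trTruth) + 1L]] <- data.frame(
        transcript_id = tid, promoter_id = pid, gene_id = gid,
        biotype = bt, stringsAsFactors = FALSE)
      jxTruth[[length(jxTruth) + 1L]] <- data.frame(
        promoter_id = pid, chrom = "chr1", intron_start = jx[1L],
        intron_end = jx[2L], strand = strand, weight = 1,
        stringsAsFactors = FALSE)
      promTruth[[length(promTruth) + 1L]] <- data.frame(
        promoter_id = pid, gene_id = gid, tss_rank = K + 1L,
        strand = strand, internal = TRUE, shared_junction = FALSE,
        stringsAsFactors = FALSE)
    }
    gtf <- c(gtf, geneLines)
  }

  # overlapping gene pairs sharing one first-intron junction: both genes'
  # single transcripts have identical first exons, so each gene gets one
  # promoter and the junction maps to both (promoter-unique in neither)
  if (cfg$sharedJunctionPairs > 0L) {
    for (s in seq_len(cfg$sharedJunctionPairs)) {
      base <- (cfg$nGenes + s) * .GENE_SPACING
      fe <- c(base, base + .EXON_W)
      jx <- c(fe[2L] + 1L, base + 999L)
      for (half in c("a", "b")) {
        gid <- sprintf("gshare%02d%s", s, half)
        pid <- sprintf("%s_p1", gid)
        tid <- sprintf("%s_t1", pid)
        e2 <- if (half == "a") c(base + 1000L, base + 1000L + .EXON_W) else
          c(base + 1000L, base + 1000L + .EXON_W + 40L)
        bt <- drawBiotype()
        gtf <- c(gtf,
          featLine("chr1", "transcript", fe[1L], e2[2L], "+",
                   attr9(gid, tid, bt)),
          featLine("chr1", "exon", fe[1L], fe[2L], "+", attr9(gid, tid, bt)),
          featLine("chr1", "exon", e2[1L], e2[2L], "+", attr9(gid, tid, bt)))
        trTruth[[length(trTruth) + 1L]] <- data.frame(
          transcript_id = tid, promoter_id = pid, gene_id = gid,
          biotype = bt, stringsAsFactors = FALSE)
        jxTruth[[length(jxTruth) + 1L]] <- data.frame(
          promoter_id = pid, chrom = "chr1", intron_start = jx[1L],
          intron_end = jx[2L], strand = "+", weight = 1,
          stringsAsFactors = FALSE)
        promTruth[[length(promTruth) + 1L]] <- data.frame(
          promoter_id = pid, gene_id = gid, tss_rank = 1L, strand = "+",
          internal = FALSE, shared_junction = TRUE, stringsAsFactors = FALSE)
      }
    }
  }

  list(gtf = c("#!genome-build promdyn-sim", gtf),
       promoters = do.call(rbind, promTruth),
       junctions = do.call(rbind, jxTruth),
       transcripts = do.call(rbind, trTruth))
}

# planted log2 trajectory evaluated at t01 in [0, 1]
.trajValue <- function(kind, t01, effect) {
  switch(kind,
         flat = rep(0, length(t01)),
         up = effect * t01,
         down = effect * (1 - t01),
         hump = effect * 4 * t01 * (1 - t01),
         stop("unknown trajectory: ", kind))
}

.trendOfTraj <- function(kind) {
  switch(kind, flat = "Flat", up = "Up", down = "Down", hump = "Flat")
}

#' Simulate per-sample junction counts with planted dynamics
#'
#' For each organ, every gene is assigned planted temporal trajectories:
#' genes with at least one active minor promoter draw a switching category
#' from `patternMix` (the major trend applies to the major promoter, the
#' minor trend to every active minor), other majors draw from
#' `singleTrajMix`. Mean unique junction reads are
#' `sizeFactor * baseline * 2^trajectory(t)`, counts are negative binomial
#' with the configured dispersion, and each promoter's reads are split
#' across its junctions by the fixed `junctionSplit` proportions. Planted
#' internal promoters receive flat counts (they must be excluded by
#' quantification, not starved of signal).
#'
#' @param cfg a [simulationConfig()].
#' @param ann annotation truth from [simulateAnnotation()].
#' @return list with `sj` (named list of STAR SJ.out.tab data.frames, one
#'   per sample), `design` (sample design table), `sizeFactors` (truth),
#'   `classes` (planted promoter class per promoter), `trajectories`
#'   (planted per-organ trend per promoter) and `pairs` (planted per-organ
#'   switching category per gene).
#' @export
simulateCounts <- function(cfg, ann) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(cfg$seed + 1L, .simulateCountsImpl(cfg, ann))
}

.simulateCountsImpl <- function(cfg, ann) {
  prom <- ann$promoters
  jx <- ann$junctions

  # sample sheet
  design <- expand.grid(
    replicate = seq_len(cfg$replicates),
    stage_i = seq_len(cfg$nStages),
    organ = cfg$organs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("%s_%s_r%d", design$organ,
                        cfg$stageLabels[design$stage_i], design$replicate),
    organ = design$organ,
    stage_label = cfg$stageLabels[design$stage_i],
    time_ordinal = design$stage_i - 1L,
    sex = ifelse(design$replicate %% 2L == 1L, "F", "M"),
    replicate = design$replicate,
    stringsAsFactors = FALSE)
  design$path <- paste0(design$sample_id, ".SJ.out.tab")
  nS <- nrow(design)

  lo <- log(cfg$sizeFactorRange[1L])
  hi <- log(cfg$sizeFactorRange[2L])
  sf <- exp(stats::runif(nS, lo, hi))
  sf <- sf / exp(mean(log(sf)))  # geometric mean 1 (identifiability)
  sfTruth <- data.frame(sample_id = design$sample_id, size_factor = sf,
                        stringsAsFactors = FALSE)

  # planted promoter classes: one major per gene among non-internal,
  # non-shared promoters; minors inactive with prob inactiveFraction
  classes <- prom
  classes$class <- NA_character_
  classes$baseline <- NA_real_
  for (g in unique(prom$gene_id)) {
    rows <- which(prom$gene_id == g)
    ok <- rows[!prom$internal[rows]]
    major <- ok[sample.int(length(ok), 1L)]
    classes$class[major] <- "major"
    classes$baseline[major] <- cfg$baselineMean
    for (r in setdiff(ok, major)) {
      if (stats::runif(1L) < cfg$inactiveFraction) {
        classes$class[r] <- "inactive"
        classes$baseline[r] <- cfg$inactiveBaseline
      } else {
        classes$class[r] <- "minor"
        classes$baseline[r] <- cfg$baselineMean * cfg$minorBaselineFrac
      }
    }
    int <- rows[prom$internal[rows]]
    classes$class[int] <- "internal"
    classes$baseline[int] <- cfg$baselineMean * 0.5
  }

  # planted trajectories per organ
  trajRows <- list()
  pairRows <- list()
  trendToKind <- c(Up = "up", Down = "down", Flat = "flat")
  for (org in cfg$organs) {
    kind <- stats::setNames(rep("flat", nrow(prom)), prom$promoter_id)
    for (g in unique(prom$gene_id)) {
      rows <- which(prom$gene_id == g)
      major <- rows[classes$class[rows] %in% "major"]
      minors <- rows[classes$class[rows] %in% "minor"]
      if (length(minors)) {
        cat8 <- sample(names(cfg$patternMix), 1L, prob = cfg$patternMix)
        tr <- strsplit(cat8, "_", fixed = TRUE)[[1L]]
        kind[major] <- trendToKind[[tr[1L]]]
        kind[minors] <- trendToKind[[tr[2L]]]
        planted <- if (cat8 == "Flat_Flat") "Unclassified" else cat8
        pairRows[[length(pairRows) + 1L]] <- data.frame(
          organ = org, gene_id = g,
          major_promoter_id = prom$promoter_id[major],
          minor_promoter_id = prom$promoter_id[minors],
          category = planted, stringsAsFactors = FALSE)
      } else if (length(major)) {
        k <- sample(names(cfg$singleTrajMix), 1L,
                    prob = cfg$singleTrajMix)
        kind[major] <- k
      }
    }
    trajRows[[length(trajRows) + 1L]] <- data.frame(
      organ = org, promoter_id = prom$promoter_id,
      trajectory = unname(kind[prom$promoter_id]),
      trend = vapply(unname(kind[prom$promoter_id]), .trendOfTraj,
                     character(1L)),
      stringsAsFactors = FALSE)
  }
  traj <- do.call(rbind, trajRows)
  pairs <- do.call(rbind, pairRows)

  # counts: per sample, NB draws per junction, aggregated by junction key
  t01 <- design$time_ordinal / max(design$time_ordinal)
  jx$key <- junctionKey(jx$chrom, jx$intron_start, jx$intron_end, jx$strand)
  sjList <- vector("list", nS)
  names(sjList) <- design$sample_id
  # mark a deterministic subset of genes whose junction strand code is
  # emitted as 0 (undefined), exercising strand resolution
  undefGene <- unique(prom$gene_id)[seq_along(unique(prom$gene_id)) %% 7L == 0L]
  for (s in seq_len(nS)) {
    org <- design$organ[s]
    tk <- stats::setNames(
      traj$trajectory[traj$organ == org], traj$promoter_id[traj$organ == org])
    mu <- vapply(seq_len(nrow(jx)), function(r) {
      p <- jx$promoter_id[r]
      b <- classes$baseline[match(p, classes$promoter_id)]
      f <- .trajValue(tk[[p]], t01[s], cfg$effect)
      sf[s] * b * 2^f * jx$weight[r]
    }, numeric(1L))
    cnt <- stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    tab <- data.frame(key = jx$key, chrom = jx$chrom,
                      intron_start = jx$intron_start,
                      intron_end = jx$intron_end, strand = jx$strand,
                      gene_id = prom$gene_id[match(jx$promoter_id,
                                                   prom$promoter_id)],
                      unique_reads = cnt, stringsAsFactors = FALSE)
    sums <- rowsum(tab$unique_reads, tab$key)
    agg <- tab[!duplicated(tab$key), , drop = FALSE]
    agg$unique_reads <- sums[agg$key, 1L]
    code0Keys <- unique(tab$key[tab$gene_id %in% undefGene])
    agg <- agg[order(agg$chrom, agg$intron_start, agg$intron_end), ,
               drop = FALSE]
    code <- ifelse(agg$strand == "+", 1L, 2L)
    code[agg$key %in% code0Keys] <- 0L
    sjList[[s]] <- data.frame(
      chrom = agg$chrom, intron_start = agg$intron_start,
      intron_end = agg$intron_end, strand_code = code,
      motif = 1L, annotated = 1L, unique_reads = agg$unique_reads,
      multi_reads = stats::rpois(nrow(agg), 2),
      max_overhang = 50L, stringsAsFactors = FALSE)
  }

  list(sj = sjList, design = design, sizeFactors = sfTruth,
       classes = classes[, c("promoter_id", "gene_id", "class",
                             "baseline")],
       trajectories = traj, pairs = pairs)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits a self-contained directory: `annotation.gtf`, one STAR
#' `SJ.out.tab` per sample, `design.tsv`, and ground-truth tables
#' (`truth_promoters.tsv`, `truth_classes.tsv`, `truth_trajectories.tsv`,
#' `truth_pairs.tsv`, `truth_size_factors.tsv`). All files are plain text
#' and reproducible: the same configuration yields byte-identical output.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory (default FALSE: refuse).
#' @return invisibly, a named list of the paths written plus the
#'   simulation objects (`annotation`, `counts`).
#' @export
endToEndFixture <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory exists and is not empty: ", dir,
         " (use force = TRUE to overwrite)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulateAnnotation(cfg)
  cts <- simulateCounts(cfg, ann)

  gtf <- file.path(dir, "annotation.gtf")
  writeLines(ann$gtf, gtf)
  for (s in names(cts$sj)) {
    utils::write.table(cts$sj[[s]], file.path(dir, paste0(s, ".SJ.out.tab")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  designPath <- file.path(dir, "design.tsv")
  writeTsv(cts$design, designPath)
  writeTsv(ann$promoters, file.path(dir, "truth_promoters.tsv"))
  writeTsv(cts$classes, file.path(dir, "truth_classes.tsv"))
  writeTsv(cts$trajectories, file.path(dir, "truth_trajectories.tsv"))
  if (!is.null(cts$pairs)) {
    writeTsv(cts$pairs, file.path(dir, "truth_pairs.tsv"))
  }
  writeTsv(cts$sizeFactors, file.path(dir, "truth_size_factors.tsv"))
  invisible(list(gtf = gtf, design = designPath, dir = dir,
                 annotation = ann, counts = cts))
}
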