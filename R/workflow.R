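#' Default pipeline configuration
#'
#' Threshold constants of the analysis: inactive-promoter cutoff 0.25
#' (log2 activity), minimum per-promoter contribution 0.10 for
#' multi-active genes, cubic polynomial degree 3, minimum goodness of fit
#' R-squared 0.3, FDR level 0.05 and 1000 bootstrap resamples.
#'
#' @param gtf path to the annotation GTF.
#' @param design path to the sample design TSV.
#' @param outdir output directory.
#' @param ... overrides for `thresholds`, `relatedGroups` or `seed`.
#' @return configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(gtf, design, outdir, ...) {
  cfg <- list(
    paths = list(gtf = gtf, design = design, outdir = outdir),
    thresholds = list(inactive = 0.25, contribution = 0.10, degree = 3L,
                      r2_min = 0.3, alpha = 0.05, bootstrap = 1000L),
    relatedGroups = list(c("brain", "cerebellum")),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "thresholds") {
      cfg$thresholds[names(dots$thresholds)] <- dots$thresholds
    } else cfg[[nm]] <- dots[[nm]]
  }
  th <- cfg$thresholds
  stopifnot(th$inactive >= 0, th$contribution >= 0, th$contribution <= 1,
            th$degree >= 1L, th$r2_min >= 0, th$r2_min <= 1,
            th$alpha > 0, th$alpha <= 1, th$bootstrap >= 1L)
  cfg
}

#' Run the full promoter-dynamics pipeline
#'
#' Executes annotation -> quantification -> activity/classification ->
#' per-organ DDP detection -> pattern assignment -> cross-organ labeling
#' on one configuration, writing every stage's tables as TSV into the
#' output directory together with a JSON manifest (package version, seed,
#' per-file MD5 digests). Stages are pure functions of their inputs, so a
#' rerun with identical inputs reproduces identical outputs. A stage
#' failure halts the run with the stage name attached to the error.
#'
#' @param config configuration list from [pipelineConfig()], or the path
#'   of a YAML file with the same structure.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- config$thresholds
  out <- config$paths$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(x, name) {
    path <- file.path(out, name)
    writeTsv(x, path)
    files <<- c(files, path)
    path
  }

  # annotate
  catalog <- stage("annotate", {
    tr <- readTranscriptModels(config$paths$gtf)
    buildPromoterCatalog(tr)
  })
  files <- c(files, exportCatalog(catalog, out))

  # quantify
  se <- stage("quantify", {
    design <- readSampleDesign(config$paths$design)
    countPromoterReads(catalog, design,
                       dir = dirname(config$paths$design))
  })
  counts <- SummarizedExperiment::assay(se, "counts")
  emit(data.frame(promoter_id = rownames(counts), counts,
                  check.names = FALSE), "counts.tsv")

  # classify
  se <- stage("classify", promoterActivity(se))
  classes <- stage("classify",
                   classifyPromoters(se, inactiveThreshold = th$inactive))
  multiActive <- multiActiveGenes(classes, contribution = th$contribution)
  absolute <- SummarizedExperiment::assay(se, "absolute")
  relative <- SummarizedExperiment::assay(se, "relative")
  emit(data.frame(promoter_id = rownames(absolute), absolute,
                  check.names = FALSE), "absolute_activity.tsv")
  emit(data.frame(promoter_id = rownames(relative), relative,
                  check.names = FALSE), "relative_activity.tsv")
  ge <- geneExpression(se)
  emit(data.frame(gene_id = rownames(ge), ge, check.names = FALSE),
       "gene_expression.tsv")
  emit(classes, "promoter_classes.tsv")
  emit(data.frame(gene_id = multiActive), "multi_active_genes.tsv")
  emit(data.frame(
    sample_id = colnames(counts),
    size_factor = SummarizedExperiment::colData(se)$sizeFactor),
    "size_factors.tsv")

  # ddp per organ, then patterns per organ
  design <- as.data.frame(SummarizedExperiment::colData(se))
  organs <- unique(design$organ)
  quantifiable <- SummarizedExperiment::rowData(se)$quantifiable
  callsByOrgan <- list()
  for (org in organs) {
    cols <- which(design$organ == org)
    times <- design$time_ordinal[cols]
    calls <- stage(paste0("ddp:", org), {
      fits <- fitPromoterTrends(
        absolute[quantifiable, cols, drop = FALSE], times,
        degree = th$degree)
      callDdps(fits, alpha = th$alpha, r2Min = th$r2_min)
    })
    callsByOrgan[[org]] <- calls
    emit(calls, sprintf("ddp_%s.tsv", org))

    stage(paste0("patterns:", org), {
      gcalls <- geneTrends(ge[, cols, drop = FALSE], times,
                           degree = th$degree, alpha = th$alpha,
                           r2Min = th$r2_min)
      pairs <- classifyPromoterPairs(classes, calls, gcalls)
      emit(pairs, sprintf("pattern_calls_%s.tsv", org))
      emit(aggregateCategories(pairs),
           sprintf("category_counts_%s.tsv", org))
      usage <- relativeUsageTrajectory(
        se[, cols], classes, design[cols, , drop = FALSE])
      emit(usage, sprintf("relative_usage_%s.tsv", org))
      emit(codingFraction(catalog, pairs),
           sprintf("coding_fraction_%s.tsv", org))
    })
  }

  # crossorgan
  stage("crossorgan", {
    ddpGenes <- lapply(callsByOrgan, function(calls) {
      ids <- calls$promoter_id[calls$is_ddp]
      unique(classes$gene_id[match(ids, classes$promoter_id)])
    })
    labels <- labelCommonSpecific(ddpGenes,
                                  relatedGroups = config$relatedGroups,
                                  organs = organs)
    emit(labels, "cross_organ_labels.tsv")
    emit(splitByDirection(labels, callsByOrgan, classes),
         "cross_organ_directions.tsv")
  })

  manifest <- list(
    package = "promdyn",
    version = as.character(utils::packageVersion("promdyn")),
    seed = config$seed,
    thresholds = th,
    organs = organs,
    outputs = as.list(tools::md5sum(sort(unique(files)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
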