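#' Label DDP genes as common or organ-specific
#'
#' A gene is a common DDP when it harbors a DDP in at least two organs,
#' except when those organs are exactly a related-organ group (by default
#' the brain/cerebellum pair, whose close functional relationship would
#' otherwise inflate the common set): such genes are labeled
#' `excluded_pair`. Genes dynamic in a single organ are
#' `organ_specific:<organ>`. Matching across organs is by gene identifier.
#'
#' @param ddpGenes named list, one character vector of DDP gene identifiers
#'   per organ.
#' @param relatedGroups list of character vectors of organ names treated as
#'   one functional unit (default `list(c("brain", "cerebellum"))`).
#' @param organs optional vector of valid organ names (e.g. from the design
#'   table); unknown names in `ddpGenes` raise an error.
#' @return data.frame `gene_id`, `organs` (comma-separated, sorted),
#'   `n_organs`, `label`.
#' @export
labelCommonSpecific <- function(ddpGenes,
                                relatedGroups = list(c("brain",
                                                       "cerebellum")),
                                organs = NULL) {
  if (is.null(names(ddpGenes)) || any(!nzchar(names(ddpGenes)))) {
    stop("ddpGenes must be a named list (one entry per organ)")
  }
  if (!is.null(organs)) {
    unknown <- setdiff(names(ddpGenes), organs)
    if (length(unknown)) {
      stop("unknown organ(s) not in design: ",
           paste(unknown, collapse = ", "))
    }
  }
  ddpGenes <- ddpGenes[sort(names(ddpGenes))]  # order-invariant labels
  long <- data.frame(
    gene_id = unlist(ddpGenes, use.names = FALSE),
    organ = rep(names(ddpGenes), lengths(ddpGenes)),
    stringsAsFactors = FALSE)
  if (!nrow(long)) {
    return(data.frame(gene_id = character(), organs = character(),
                      n_organs = integer(), label = character(),
                      stringsAsFactors = FALSE))
  }
  sets <- tapply(long$organ, long$gene_id,
                 function(x) sort(unique(x)), simplify = FALSE)
  lab <- vapply(sets, function(os) {
    if (length(os) == 1L) return(paste0("organ_specific:", os))
    inGroup <- vapply(relatedGroups, function(g) all(os %in% g), logical(1L))
    if (any(inGroup)) "excluded_pair" else "common"
  }, character(1L))
  out <- data.frame(
    gene_id = names(sets),
    organs = vapply(sets, paste, character(1L), collapse = ","),
    n_organs = lengths(sets), label = unname(lab),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-organ label by trend direction
#'
#' Per-organ contingency counts of common versus organ-specific DDP
#' promoters among up- and downregulated directions (for reporting the
#' balance of early- versus late-activated promoters).
#'
#' @param labels table from [labelCommonSpecific()].
#' @param callsByOrgan named list of [callDdps()] tables, one per organ.
#' @param geneMap data.frame mapping `promoter_id` to `gene_id` (e.g. the
#'   classification table).
#' @return data.frame `organ`, `label_class` (`common`, `organ_specific`,
#'   `excluded_pair`), `direction` (`Up`/`Down`), `n`.
#' @export
splitByDirection <- function(labels, callsByOrgan, geneMap) {
  classOf <- function(gene) {
    l <- labels$label[match(gene, labels$gene_id)]
    ifelse(is.na(l), NA_character_,
           ifelse(startsWith(l, "organ_specific"), "organ_specific", l))
  }
  grid <- expand.grid(
    organ = names(callsByOrgan),
    label_class = c("common", "organ_specific", "excluded_pair"),
    direction = c("Up", "Down"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- 0L
  for (org in names(callsByOrgan)) {
    calls <- callsByOrgan[[org]]
    ddp <- calls[calls$is_ddp & calls$direction %in% c("Up", "Down"), ,
                 drop = FALSE]
    if (!nrow(ddp)) next
    gene <- geneMap$gene_id[match(ddp$promoter_id, geneMap$promoter_id)]
    cls <- classOf(gene)
    keep <- !is.na(cls)
    tab <- table(cls[keep], ddp$direction[keep])
    for (lc in rownames(tab)) for (dd in colnames(tab)) {
      sel <- grid$organ == org & grid$label_class == lc &
        grid$direction == dd
      grid$n[sel] <- as.integer(tab[lc, dd])
    }
  }
  grid[order(grid$organ, grid$label_class, grid$direction), ,
       drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
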