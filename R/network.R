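#' Surface proteins from an annotation table
#'
#' A protein counts as cell-surface when at least one reliable (approved or
#' supported) location among \emph{cell junctions}, \emph{focal adhesion
#' sites}, \emph{plasma membrane} is annotated. Surface terms carried only
#' at a non-reliable status do not qualify.
#'
#' @param annotation data.frame from \code{\link{readAnnotationTable}}
#'   (columns protein, locations).
#' @return character vector of surface protein labels.
#' @export
surfaceProteins <- function(annotation) {
  if (!nrow(annotation)) stop("empty annotation table")
  terms <- c("plasma membrane", "cell junctions", "focal adhesion sites")
  u <- annotation[!duplicated(annotation$protein),
                  c("protein", "locations")]
  ok <- vapply(u$locations, function(loc) {
    parts <- strsplit(strsplit(loc, ";", fixed = TRUE)[[1]], "|",
                      fixed = TRUE)
    any(vapply(parts, function(p)
      length(p) >= 2L && trimws(p[1]) %in% terms &&
        trimws(p[2]) %in% c("approved", "supported"), logical(1)))
  }, logical(1))
  u$protein[ok]
}

#' Per-population surface protein sets
#'
#' For each immune population, the surface proteins whose normalized
#' expression score is strictly greater than \code{scoreThreshold}.
#'
#' @param annotation data.frame (protein, locations, population, score,
#'   activation_status).
#' @param scoreThreshold strict lower bound on the normalized score
#'   (default 1.5; a score of exactly 1.5 is excluded).
#' @param populations optional population labels to restrict to; an
#'   unknown label is an error.
#' @param surface optional precomputed surface set (defaults to
#'   \code{surfaceProteins(annotation)}).
#' @return data.frame (population, protein, score, activationStatus), one
#'   row per expressed surface protein per population.
#' @export
populationSurfaceSets <- function(annotation, scoreThreshold = 1.5,
                                  populations = NULL, surface = NULL) {
  if (is.null(surface)) surface <- surfaceProteins(annotation)
  if (!is.null(populations)) {
    unknown <- setdiff(populations, unique(annotation$population))
    if (length(unknown))
      stop("unknown population label(s): ", paste(unknown, collapse = ", "))
    annotation <- annotation[annotation$population %in% populations, ,
                             drop = FALSE]
  }
  keep <- annotation$score > scoreThreshold &
    annotation$protein %in% surface
  out <- data.frame(population = annotation$population[keep],
                    protein = annotation$protein[keep],
                    score = annotation$score[keep],
                    activationStatus = annotation$activation_status[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' MYCN-regulated surface gene lists from knockdown differential expression
#'
#' Genes down on knockdown (logFC <= -threshold, i.e. MYCN positively
#' regulated) and up on knockdown (logFC >= +threshold, negatively
#' regulated), intersected with the surface protein set.
#'
#' @param knockDE data.frame with columns \code{gene} and \code{logFC}
#'   (knockdown vs control).
#' @param surfaceSet character vector of surface proteins.
#' @param lfcThreshold absolute logFC threshold (default 1).
#' @return list with disjoint character vectors \code{positive} and
#'   \code{negative}.
#' @export
knockdownGeneLists <- function(knockDE, surfaceSet, lfcThreshold = 1) {
  pos <- knockDE$gene[knockDE$logFC <= -lfcThreshold]
  neg <- knockDE$gene[knockDE$logFC >= lfcThreshold]
  list(positive = intersect(pos, surfaceSet),
       negative = intersect(neg, surfaceSet))
}

#' Build the bipartite tumor-gene / immune-population surface network
#'
#' Keeps interactions with combined score strictly greater than
#' \code{minScore} (after undirected deduplication and self-loop removal)
#' whose one endpoint lies in the tumor-side gene set (restricted to
#' surface proteins when \code{surfaceSet} is given) and whose other
#' endpoint is an expressed surface protein of some immune population. One
#' output row per (edge orientation, population).
#'
#' @param tumorSet character vector of tumor-side genes.
#' @param populationTable data.frame from
#'   \code{\link{populationSurfaceSets}}.
#' @param edges data.frame (protein1, protein2, combined_score), e.g. from
#'   \code{\link{readEdgeTable}}.
#' @param minScore strict lower bound on the combined score (default 400;
#'   an edge scored exactly 400 is excluded).
#' @param surfaceSet optional surface protein set used to restrict the
#'   tumor side.
#' @return an \linkS4class{ImmuneNetwork} (empty, with a warning, when no
#'   edge survives).
#' @export
buildBipartiteNetwork <- function(tumorSet, populationTable, edges,
                                  minScore = 400, surfaceSet = NULL) {
  if (!length(tumorSet) || !nrow(populationTable) || !nrow(edges))
    stop("tumorSet, populationTable and edges must be non-empty")
  edges <- dedupeEdges(edges)
  edges <- edges[edges$combined_score > minScore, , drop = FALSE]
  if (!is.null(surfaceSet)) tumorSet <- intersect(tumorSet, surfaceSet)

  both <- rbind(
    data.frame(tumorGene = edges$protein1, immuneProtein = edges$protein2,
               score = edges$combined_score, stringsAsFactors = FALSE),
    data.frame(tumorGene = edges$protein2, immuneProtein = edges$protein1,
               score = edges$combined_score, stringsAsFactors = FALSE))
  both <- both[both$tumorGene %in% tumorSet, , drop = FALSE]
  popCols <- populationTable[, c("protein", "population",
                                 "activationStatus"), drop = FALSE]
  out <- merge(both, popCols, by.x = "immuneProtein", by.y = "protein")
  out <- unique(data.frame(tumorGene = out$tumorGene,
                           immuneProtein = out$immuneProtein,
                           population = out$population,
                           activationStatus = out$activationStatus,
                           score = out$score, stringsAsFactors = FALSE))
  out <- out[order(out$tumorGene, out$immuneProtein, out$population), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("no edge survives the filter cascade")
  counts <- table(factor(out$population))
  new("ImmuneNetwork", edges = out,
      populationCounts = setNames(as.integer(counts), names(counts)))
}

#' Summarize an immune network for circular-plot export
#'
#' @param net an \linkS4class{ImmuneNetwork}.
#' @return list with \code{populationCounts} (edges per population; sums
#'   to \code{totalEdges}), \code{tumorGeneCounts} (per tumor gene x
#'   population), \code{populationPairs} (interaction pairs shared by two
#'   populations), \code{totalEdges} and \code{populationDiversity}.
#' @export
networkSummary <- function(net) {
  e <- networkEdges(net)
  if (!nrow(e))
    return(list(populationCounts = integer(0),
                tumorGeneCounts = data.frame(),
                populationPairs = data.frame(),
                totalEdges = 0L, populationDiversity = 0L))
  popCounts <- net@populationCounts
  tg <- as.data.frame(table(tumorGene = e$tumorGene,
                            population = e$population),
                      stringsAsFactors = FALSE)
  tg <- tg[tg$Freq > 0, , drop = FALSE]
  names(tg)[3] <- "edges"
  rownames(tg) <- NULL

  key <- paste(e$tumorGene, e$immuneProtein, sep = "\r")
  popsByEdge <- split(e$population, key)
  pairs <- do.call(rbind, lapply(popsByEdge, function(ps) {
    ps <- sort(unique(ps))
    if (length(ps) < 2L) return(NULL)
    cmb <- utils::combn(ps, 2L)
    data.frame(populationA = cmb[1, ], populationB = cmb[2, ],
               stringsAsFactors = FALSE)
  }))
  pairCounts <- if (is.null(pairs))
    data.frame(populationA = character(), populationB = character(),
               shared = integer(), stringsAsFactors = FALSE)
  else {
    agg <- aggregate(list(shared = rep(1L, nrow(pairs))),
                     by = pairs[c("populationA", "populationB")], FUN = sum)
    agg[order(agg$populationA, agg$populationB), , drop = FALSE]
  }
  rownames(pairCounts) <- NULL
  list(populationCounts = popCounts, tumorGeneCounts = tg,
       populationPairs = pairCounts, totalEdges = nrow(e),
       populationDiversity = sum(popCounts > 0L))
}
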