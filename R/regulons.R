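#' Infer transcriptional regulators of co-expression modules
#'
#' Module-wise over-representation of each transcription factor's target
#' set: hypergeometric upper-tail p over the shared gene universe, BH
#' adjusted across all (TF, module) pairs. A TF significant in at least
#' one module is selected. (The regulon prior is an explicit input; the
#' hypergeometric statistic is the stand-in inference engine and is
#' labeled as such in outputs.)
#'
#' @param assignment named integer vector, gene -> module.
#' @param prior named list, TF -> character vector of targets.
#' @param qThreshold selection cutoff on BH q (default 0.05).
#' @return data.frame (tf, module, overlap, targetsInUniverse, moduleSize,
#'   p, q, selected); attribute \code{selected} carries the selected TF
#'   labels.
#' @export
inferModuleRegulators <- function(assignment, prior, qThreshold = 0.05) {
  if (!length(prior)) stop("empty regulon prior")
  universe <- names(assignment)
  N <- length(universe)
  mods <- sort(unique(assignment[assignment > 0L]))
  rows <- list()
  for (tf in names(prior)) {
    targets <- intersect(prior[[tf]], universe)
    if (!length(targets)) next    # TF with no targets in universe
    for (m in mods) {
      mg <- universe[assignment == m]
      k <- length(intersect(mg, targets))
      p <- phyper(k - 1L, length(targets), N - length(targets),
                  length(mg), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, module = m, overlap = k,
        targetsInUniverse = length(targets), moduleSize = length(mg),
        p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no prior TF has targets in the universe")
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out$selected <- out$q < qThreshold
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "selected") <- unique(out$tf[out$selected])
  out
}

#' Per-sample regulon activity
#'
#' Activity of a regulon is the mean gene-wise z-score of its targets per
#' sample; activity rows are then z-scored across samples. Regulons with
#' fewer than \code{minTargets} targets present in the expression matrix
#' are dropped with a message.
#'
#' @param expr numeric matrix, genes x samples.
#' @param regulons named list, TF -> targets.
#' @param minTargets minimum present targets (default 3).
#' @return regulons x samples activity matrix (rows mean 0, sd 1).
#' @export
regulonActivity <- function(expr, regulons, minTargets = 3L) {
  z <- zscoreRows(expr, warnConstant = FALSE)
  act <- list()
  for (tf in names(regulons)) {
    targets <- intersect(regulons[[tf]], rownames(z))
    if (length(targets) < minTargets) {
      message("regulon '", tf, "' dropped (<", minTargets,
              " targets present)")
      next
    }
    act[[tf]] <- colMeans(z[targets, , drop = FALSE])
  }
  if (!length(act)) stop("no regulon with enough targets in expr")
  a <- do.call(rbind, act)
  colnames(a) <- colnames(expr)
  zscoreRows(a, warnConstant = FALSE)
}

#' Cluster regulons by activity profile
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of the
#' activity rows, cut at \code{k} clusters.
#'
#' @param activity regulons x samples matrix.
#' @param k number of clusters (default 3).
#' @return named integer vector, regulon -> cluster id in 1..k.
#' @export
clusterRegulons <- function(activity, k = 3L) {
  if (nrow(activity) < k) stop("fewer regulons than k")
  hc <- hclust(dist(activity), method = "average")
  cutree(hc, k = k)
}

#' Regulons shared between two cohorts
#'
#' @param regulonsA,regulonsB selection tables from
#'   \code{\link{inferModuleRegulators}} (their \code{selected}
#'   attributes are used) or plain character vectors of TF labels.
#' @return character vector of common TFs; when both inputs are tables, a
#'   data.frame with each cohort's best (module, q) per shared TF is
#'   attached as attribute \code{stats}.
#' @export
consensusRegulons <- function(regulonsA, regulonsB) {
  getTF <- function(x) if (is.character(x)) x else
    attr(x, "selected") %||% unique(x$tf[x$selected])
  common <- intersect(getTF(regulonsA), getTF(regulonsB))
  if (is.data.frame(regulonsA) && is.data.frame(regulonsB) &&
      length(common)) {
    bestOf <- function(x, tf) {
      r <- x[x$tf == tf, , drop = FALSE]
      r[which.min(r$q), c("module", "q"), drop = FALSE]
    }
    stats <- do.call(rbind, lapply(common, function(tf) {
      a <- bestOf(regulonsA, tf); b <- bestOf(regulonsB, tf)
      data.frame(tf = tf, moduleA = a$module, qA = a$q,
                 moduleB = b$module, qB = b$q, stringsAsFactors = FALSE)
    }))
    attr(common, "stats") <- stats
  }
  common
}

#' Cluster patients by regulon activity
#'
#' Hierarchical clustering of samples (columns) by Euclidean distance on
#' the activity matrix; the dendrogram ordering is exported for heatmap
#' display and the cut labels for survival analysis.
#'
#' @param activity regulons x samples matrix.
#' @param k number of patient clusters (default 2).
#' @return list with \code{labels} (named integer per sample) and
#'   \code{order} (sample ordering from the dendrogram).
#' @export
clusterPatientsByRegulon <- function(activity, k = 2L) {
  hc <- hclust(dist(t(activity)), method = "average")
  list(labels = cutree(hc, k = k), order = colnames(activity)[hc$order])
}
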