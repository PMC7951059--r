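#' Signed weighted co-expression adjacency
#'
#' \eqn{a_{ij} = ((1 + cor(x_i, x_j)) / 2)^\beta} with Pearson correlation
#' across samples; the diagonal is 1 and perfectly anti-correlated genes
#' get adjacency 0.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param beta soft-threshold power (default 8).
#' @return symmetric genes x genes adjacency matrix.
#' @export
signedAdjacency <- function(expr, beta = 8) {
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  s <- apply(expr, 1L, sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[s == 0], 10), collapse = ", "))
  a <- ((1 + cor(t(expr))) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap dissimilarity
#'
#' Unsigned TOM on an adjacency matrix:
#' \eqn{\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{\ell_{ij} = \sum_u a_{iu} a_{uj}} over shared neighbors and
#' \eqn{k_i} the connectivity; returned as the dissimilarity
#' \eqn{1 - \omega} with zero diagonal.
#'
#' @param adjacency symmetric adjacency matrix in [0, 1].
#' @return symmetric dissimilarity matrix in [0, 1], zero diagonal.
#' @export
topologicalOverlap <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  omega <- (L + a) / (kmin + 1 - a)
  diag(omega) <- 1
  d <- 1 - omega
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Detect co-expression modules by adaptive branch cutting
#'
#' Average-linkage hierarchical clustering of the dissimilarity, followed
#' by a dynamic branch-cut heuristic that walks the dendrogram from the
#' root. A branch of at least \code{minSize} genes is accepted as a module
#' when (i) it detaches from the rest of the universe - relative gap
#' between its mean outside and mean inside dissimilarity at least
#' \code{detachGap} (a branch spanning the whole input must instead be
#' internally tight, mean dissimilarity at most \code{tightness}) - and
#' (ii) no preferred split exists: its two sub-branches, when both of
#' module size, are not mutually separated by a relative gap of at least
#' \code{splitGap}. A branch that is not accepted is descended into, so
#' late-joining outlier genes and diffuse noise dissolve into unassigned
#' singletons (module 0). Accepted branches are finally pruned: members
#' whose mean dissimilarity to the module sits a relative \code{detachGap}
#' above the module median are released as unassigned. Modules are
#' numbered by decreasing size.
#'
#' @param dissim symmetric dissimilarity matrix (e.g. from
#'   \code{\link{topologicalOverlap}}).
#' @param minSize minimum module size (default 20).
#' @param splitGap,detachGap relative dissimilarity gaps driving the
#'   split preference and the detachment acceptance (defaults 0.15).
#' @param tightness absolute mean-dissimilarity bound accepting a
#'   whole-input branch (default 0.85).
#' @return named integer vector, gene -> module id (0 = unassigned).
#' @export
detectModules <- function(dissim, minSize = 20L, splitGap = 0.15,
                          detachGap = 0.15, tightness = 0.85) {
  n <- nrow(dissim)
  genes <- rownames(dissim) %||% paste0("g", seq_len(n))
  if (n < 2L * minSize)
    warning("fewer than 2*minSize genes; expect a single module or all ",
            "genes unassigned")
  hc <- hclust(as.dist(dissim), method = "average")

  members <- function(node) {
    # leaves of a merge-tree node; negative entries are leaves
    stack <- node
    out <- integer(0)
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      if (x < 0) out <- c(out, -x) else stack <- c(hc$merge[x, ], stack)
    }
    out
  }

  meanBlock <- function(i, j) mean(dissim[i, j, drop = FALSE])
  meanWithin <- function(i) {
    if (length(i) < 2L) return(0)
    sum(dissim[i, i]) / (length(i) * (length(i) - 1L))
  }
  detaches <- function(idx) {
    rest <- setdiff(seq_len(n), idx)
    if (!length(rest)) return(meanWithin(idx) <= tightness)
    mo <- meanBlock(idx, rest)
    mo > 0 && (mo - meanWithin(idx)) / mo >= detachGap
  }

  modules <- list()
  walk <- function(node) {
    idx <- members(node)
    if (length(idx) < minSize) return(invisible(NULL))  # unassigned
    splitPreferred <- FALSE
    if (node > 0) {
      kids <- hc$merge[node, ]
      i1 <- members(kids[1]); i2 <- members(kids[2])
      if (length(i1) >= minSize && length(i2) >= minSize) {
        cross <- meanBlock(i1, i2)
        within <- min(meanWithin(i1), meanWithin(i2))
        splitPreferred <- cross > 0 &&
          (cross - within) / cross >= splitGap
      }
    }
    if (!splitPreferred && detaches(idx)) {
      modules[[length(modules) + 1L]] <<- idx
    } else if (node > 0) {
      kids <- hc$merge[node, ]
      walk(kids[1]); walk(kids[2])
    }
    invisible(NULL)
  }
  walk(nrow(hc$merge))

  # prune weakly attached members: a gene whose mean dissimilarity to its
  # module sits a relative detachGap above the module median is released
  prune <- function(idx) {
    repeat {
      if (length(idx) < minSize) return(integer(0))
      di <- rowSums(dissim[idx, idx, drop = FALSE]) / (length(idx) - 1L)
      med <- median(di)
      drop <- di > med & (di - med) / di >= detachGap
      if (!any(drop)) return(idx)
      idx <- idx[!drop]
    }
  }
  modules <- Filter(length, lapply(modules, prune))

  assignment <- setNames(rep(0L, n), genes)
  if (length(modules)) {
    modules <- modules[order(-lengths(modules))]
    for (m in seq_along(modules)) assignment[modules[[m]]] <- m
  } else if (n >= 2L * minSize) {
    warning("no module satisfied the branch criteria; all genes unassigned")
  }
  assignment
}

#' Module eigengenes
#'
#' First principal component of each module's gene-standardized expression
#' (right singular vector of the z-scored module block), rescaled to unit
#' variance and sign-oriented so that its correlation with the module's
#' mean expression profile is non-negative. A single-gene module's
#' eigengene is that gene's z-score profile.
#'
#' @param expr numeric matrix, genes x samples.
#' @param assignment named integer vector from
#'   \code{\link{detectModules}}.
#' @return modules x samples matrix (rows \code{ME1}, \code{ME2}, ...).
#' @export
moduleEigengenes <- function(expr, assignment) {
  mods <- sort(unique(assignment[assignment > 0L]))
  if (!length(mods)) stop("no non-empty modules")
  out <- t(vapply(mods, function(m) {
    genes <- intersect(names(assignment)[assignment == m], rownames(expr))
    z <- zscoreRows(expr[genes, , drop = FALSE], warnConstant = FALSE)
    e <- if (length(genes) == 1L) as.numeric(z) else
      svd(z, nu = 0, nv = 1)$v[, 1]
    e <- (e - mean(e)) / sd(e)
    if (cor(e, colMeans(z)) < 0) e <- -e
    e
  }, numeric(ncol(expr))))
  dimnames(out) <- list(paste0("ME", mods), colnames(expr))
  out
}

#' Module eigengene similarity
#'
#' @param eigengenes modules x samples matrix.
#' @param threshold absolute correlation display threshold for the edge
#'   list (default 0.5).
#' @return list with \code{correlation} (full Pearson matrix) and
#'   \code{edges} (moduleA, moduleB, r, sign) for \code{|r| >= threshold}.
#' @export
moduleSimilarity <- function(eigengenes, threshold = 0.5) {
  if (nrow(eigengenes) < 2L) stop("need >= 2 modules")
  cc <- cor(t(eigengenes))
  idx <- which(upper.tri(cc) & abs(cc) >= threshold, arr.ind = TRUE)
  edges <- data.frame(moduleA = rownames(cc)[idx[, 1]],
                      moduleB = colnames(cc)[idx[, 2]],
                      r = cc[idx],
                      sign = ifelse(cc[idx] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  list(correlation = cc, edges = edges)
}

#' Z-scored group-mean eigengene profiles (module-trait table)
#'
#' Per module, the mean eigengene value within each group, z-scored across
#' the row of group means.
#'
#' @param eigengenes modules x samples matrix.
#' @param groups grouping vector over samples (e.g. MNA status); every
#'   level must be non-empty.
#' @return modules x groups matrix of z-scores (row means 0).
#' @export
moduleTraitProfile <- function(eigengenes, groups) {
  g <- factor(groups)
  if (any(table(g) == 0L)) stop("every group needs >= 1 sample")
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  means <- t(apply(eigengenes, 1L, function(e) tapply(e, g, mean)))
  t(apply(means, 1L, function(r) (r - mean(r)) / sd(r)))
}

#' Immune-population composition of modules
#'
#' Counts, per immune population, the genes of its surface set falling in
#' each module, then z-scores each population row.
#'
#' @param assignment named integer vector, gene -> module.
#' @param populationSets named list, population -> gene set (or the
#'   data.frame from \code{\link{populationSurfaceSets}}).
#' @return list with \code{counts} and \code{z} (populations x modules);
#'   an all-zero population row gets z = 0 with a warning.
#' @export
modulePopulationComposition <- function(assignment, populationSets) {
  if (is.data.frame(populationSets))
    populationSets <- split(populationSets$protein,
                            populationSets$population)
  mods <- sort(unique(assignment[assignment > 0L]))
  counts <- t(vapply(populationSets, function(gs)
    vapply(mods, function(m)
      sum(names(assignment)[assignment == m] %in% gs), integer(1)),
    integer(length(mods))))
  colnames(counts) <- paste0("M", mods)
  z <- t(apply(counts, 1L, function(r) {
    if (sd(r) == 0) {
      warning("degenerate (constant) population row; z set to 0")
      rep(0, length(r))
    } else (r - mean(r)) / sd(r)
  }))
  dimnames(z) <- dimnames(counts)
  list(counts = counts, z = z)
}

#' Hypergeometric over-representation of gene sets in modules
#'
#' For each (module, set) pair over the clustering gene universe:
#' overlap k, upper-tail hypergeometric p = P(X >= k), BH-adjusted q
#' across all tested pairs. Sets with no background overlap are skipped.
#'
#' @param assignment named integer vector, gene -> module.
#' @param collection named list of gene sets.
#' @param background gene universe (default: all genes in
#'   \code{assignment}).
#' @return data.frame (module, set, overlap, moduleSize, setSize, p, q).
#' @export
moduleEnrichment <- function(assignment, collection,
                             background = names(assignment)) {
  N <- length(background)
  mods <- sort(unique(assignment[assignment > 0L]))
  rows <- list()
  for (nm in names(collection)) {
    set <- intersect(collection[[nm]], background)
    if (!length(set)) next
    for (m in mods) {
      mg <- intersect(names(assignment)[assignment == m], background)
      k <- length(intersect(mg, set))
      p <- phyper(k - 1L, length(set), N - length(set), length(mg),
                  lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = nm, overlap = k, moduleSize = length(mg),
        setSize = length(set), p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no set overlaps the background")
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out[order(out$p), ]
}
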