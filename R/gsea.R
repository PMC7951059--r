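#' Build a ranked gene list from a named statistic vector
#'
#' Sorts decreasingly; ties are broken by gene label so rankings are
#' deterministic.
#'
#' @param stats named numeric vector (gene -> ranking statistic, e.g.
#'   correlation r or moderated t).
#' @return sorted named numeric vector with unique names.
#' @export
rankedList <- function(stats) {
  if (is.null(names(stats)) || anyDuplicated(names(stats)))
    stop("stats must be named with unique gene labels")
  if (any(!is.finite(stats))) stop("ranking statistics must be finite")
  stats[order(-stats, names(stats))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; hits increment the running sum proportionally to
#' \code{|statistic|^exponent}, misses decrement it by \code{1/(N - Nh)}.
#' The ES is the signed maximum deviation of the running sum.
#'
#' @param ranked sorted named statistic vector (see
#'   \code{\link{rankedList}}).
#' @param geneSet character vector of member genes.
#' @param exponent hit-weight exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return list with \code{es}, \code{runningSum} (length N), \code{hits}
#'   (logical length N) and \code{leadingEdge} (genes up to / from the
#'   extremum, depending on sign).
#' @export
enrichmentScore <- function(ranked, geneSet, exponent = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% geneSet
  nh <- sum(hits)
  if (nh == 0L) stop("gene set has no overlap with the ranked list")
  if (nh == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked)^exponent
  w[!hits] <- 0
  tot <- sum(w)
  pHit <- if (tot > 0) cumsum(w) / tot else cumsum(hits) / nh
  pMiss <- cumsum(!hits) / (N - nh)
  running <- pHit - pMiss
  # signed maximum deviation; an exact +/- tie resolves to the positive side
  m1 <- max(running); m2 <- min(running)
  es <- if (m1 >= -m2 - 1e-12) m1 else m2
  i <- if (es >= 0) which.max(running) else which.min(running)
  leading <- if (es >= 0) names(ranked)[seq_len(i)][hits[seq_len(i)]]
  else names(ranked)[i:N][hits[i:N]]
  list(es = unname(es), runningSum = unname(running), hits = hits,
       leadingEdge = leading)
}

# ES from sorted hit positions only, O(k): between hits the running sum
# decays linearly, so extremes occur immediately after a hit (maximum) or
# immediately before one (minimum).
esFromPositions <- function(pos, absStat, N, exponent = 1) {
  k <- length(pos)
  w <- absStat[pos]^exponent
  tot <- sum(w)
  cumw <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  m <- 1 / (N - k)
  atHit <- cumw - (pos - seq_len(k)) * m
  beforeHit <- c(0, cumw[-k]) - (pos - seq_len(k)) * m
  m1 <- max(atHit); m2 <- min(beforeHit)
  if (m1 >= -m2 - 1e-12) m1 else m2
}

#' Preranked gene-set enrichment with permutation FDR
#'
#' Gene-label permutation null: for each set size, \code{nPerm} random
#' same-size gene sets are drawn from the ranked list. NES divides ES by
#' the mean absolute null ES of matching sign; nominal p is one-sided
#' against the matching-sign null; FDR q follows the pooled
#' positive/negative null procedure (null and observed NES tail fractions).
#'
#' @param ranked sorted named statistic vector.
#' @param collection named list of gene sets (e.g. from
#'   \code{\link{readGMT}}).
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param exponent hit-weight exponent (default 1).
#' @param minSize,maxSize set-size bounds after intersection with the
#'   ranked list (defaults 15 / 500); out-of-bound sets are skipped with a
#'   message.
#' @return data.frame (set, size, es, nes, p, q, leadingEdge) sorted by
#'   nes decreasing.
#' @export
prerankedGSEA <- function(ranked, collection, nPerm = 1000L, seed = 1L,
                          exponent = 1, minSize = 15L, maxSize = 500L) {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  N <- length(ranked)
  absStat <- abs(ranked)
  sizes <- vapply(collection, function(s) sum(names(ranked) %in% s),
                  integer(1))
  keep <- sizes >= minSize & sizes <= maxSize
  if (any(!keep))
    message(sum(!keep), " set(s) outside size bounds [", minSize, ", ",
            maxSize, "] skipped")
  collection <- collection[keep]
  sizes <- sizes[keep]
  if (!length(collection)) stop("no sets within size bounds")

  obs <- lapply(collection, function(s)
    enrichmentScore(ranked, s, exponent))
  es <- vapply(obs, `[[`, numeric(1), "es")

  # one permutation null per distinct set size (label permutation depends
  # only on the set size)
  uSizes <- sort(unique(sizes))
  nulls <- withSeed(deriveSeed(seed, "gsea"), {
    out <- vector("list", length(uSizes))
    names(out) <- as.character(uSizes)
    for (k in uSizes) {
      out[[as.character(k)]] <- vapply(seq_len(nPerm), function(i)
        esFromPositions(sort(sample.int(N, k)), absStat, N, exponent),
        numeric(1))
    }
    out
  })

  nes <- p <- numeric(length(es))
  nullNES <- vector("list", length(uSizes))
  names(nullNES) <- as.character(uSizes)
  for (k in uSizes) {
    nk <- nulls[[as.character(k)]]
    mPos <- mean(abs(nk[nk >= 0]))
    mNeg <- mean(abs(nk[nk < 0]))
    nn <- nk
    nn[nk >= 0] <- nk[nk >= 0] / mPos
    nn[nk < 0] <- nk[nk < 0] / mNeg
    nullNES[[as.character(k)]] <- nn
  }
  for (i in seq_along(es)) {
    nk <- nulls[[as.character(sizes[i])]]
    if (es[i] >= 0) {
      same <- nk[nk >= 0]
      nes[i] <- es[i] / mean(abs(same))
      p[i] <- if (length(same)) mean(same >= es[i]) else NA_real_
    } else {
      same <- nk[nk < 0]
      nes[i] <- es[i] / mean(abs(same))
      p[i] <- if (length(same)) mean(same <= es[i]) else NA_real_
    }
  }

  pool <- unlist(nullNES, use.names = FALSE)
  q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  out <- data.frame(set = names(collection), size = sizes, es = es,
                    nes = nes, p = p, q = q,
                    leadingEdge = vapply(obs, function(o)
                      paste(o$leadingEdge, collapse = ","), character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$nes, out$set), ]
}
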